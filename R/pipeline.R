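# Run configuration and the end-to-end pipeline orchestrator.

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end analysis. All random
#' stages derive independent substreams from the single master `seed`
#' (via [substream_seed()]), so changing the replicate count of one
#' stage leaves the others' draws untouched and reruns are
#' bit-reproducible.
#'
#' @param seed master seed.
#' @param n_replicates replicates for null-model and extinction stages.
#' @param n_imputations completed datasets from the imputation stage.
#' @param extinction_probabilities named per-category probabilities.
#' @param dd_mode Data Deficient handling: `"as_LC"`, `"drop"` or
#'   `"fixed_0.277"`.
#' @param draw_mode `"fixed_counts"` (equal totals across scenarios) or
#'   `"bernoulli"`.
#' @param svm_params list: `nu`, `gamma` (`NULL` = adaptive),
#'   `samples_per_point`, `max_samples`, `box_expansion`.
#' @param kde_quantiles HDR mass fractions, strictly in (0, 1).
#' @param diet_axes 1 or 2 diet ordination axes.
#' @param null_models which of the four null models to run.
#' @param impute_iterations chained-equation sweeps.
#' @param impute_donors predictive-mean-matching donor count.
#' @param phylo_eigenvectors eigenvectors per class tree.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       n_replicates = 999,
                       n_imputations = 25,
                       extinction_probabilities =
                         default_extinction_probs(),
                       dd_mode = c("as_LC", "drop", "fixed_0.277"),
                       draw_mode = c("fixed_counts", "bernoulli"),
                       svm_params = list(nu = 0.01, gamma = NULL,
                                         samples_per_point = 500,
                                         max_samples = 5e6,
                                         box_expansion = 0.2),
                       kde_quantiles = c(0.5, 0.95, 0.99),
                       diet_axes = 1,
                       null_models = 1:4,
                       impute_iterations = 10,
                       impute_donors = 5,
                       phylo_eigenvectors = 10) {
  dd_mode <- match.arg(dd_mode)
  draw_mode <- match.arg(draw_mode)
  p <- extinction_probabilities
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  if (any(kde_quantiles <= 0 | kde_quantiles >= 1))
    stop("kde_quantiles must be strictly in (0, 1)")
  if (n_replicates < 1 || n_imputations < 1)
    stop("replicate counts must be >= 1")
  if (!diet_axes %in% c(1, 2)) stop("diet_axes must be 1 or 2")
  structure(list(seed = seed, n_replicates = n_replicates,
                 n_imputations = n_imputations,
                 extinction_probabilities = p, dd_mode = dd_mode,
                 draw_mode = draw_mode, svm_params = svm_params,
                 kde_quantiles = kde_quantiles, diet_axes = diet_axes,
                 null_models = null_models,
                 impute_iterations = impute_iterations,
                 impute_donors = impute_donors,
                 phylo_eigenvectors = phylo_eigenvectors),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Fields mirror the arguments of [run_config()]; missing fields take
#' the defaults.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  if (!is.null(y$extinction_probabilities))
    y$extinction_probabilities <- unlist(y$extinction_probabilities)
  if (!is.null(y$svm_params)) {
    sp <- formals(run_config)$svm_params
    sp <- eval(sp)
    sp[names(y$svm_params)] <- y$svm_params
    y$svm_params <- sp
  }
  do.call(run_config, y)
}

#' Run the whole analysis end to end
#'
#' Stages: diet axis from the compositional diet data; transform and
#' standardize the five traits; chained-equation multiple imputation
#' (skipped when the table is complete and `n_imputations = 1`);
#' strategy surface (per-dataset PCA, ensemble-averaged scores, HDR
#' contours); hypervolumes for the combined set and per class with set
#' operations and packing densities (on one imputed dataset, selected
#' at random from the ensemble); occupation tests against the four
#' null models; projected and randomized extinction ensembles with the
#' comparison statistics and per-trait shift tests.
#'
#' The run is a pure function of `(table, trees, config)`: every stage
#' consumes a named substream of `config$seed`.
#'
#' @param table a [trait_table()].
#' @param config a [run_config()].
#' @param trees optional list of class trees for imputation, see
#'   [impute_traits()].
#' @param out_dir optional directory; when given, result tables are
#'   written as CSV plus a JSON summary.
#' @param quiet suppress stage progress messages.
#' @return object of class `strategy_pipeline` with elements `diet`,
#'   `ensemble`, `surface`, `hypervolumes` (combined/mammal/bird),
#'   `set_operations`, `densities`, `occupation` (list per null
#'   model), `scenarios` (projected/randomized ensembles), `comparison`,
#'   `trait_shifts`, `observed_summary`, `config`.
#' @export
run_pipeline <- function(table, config = run_config(), trees = NULL,
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(table, "trait_table"), inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[strategyspace] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (config$dd_mode == "drop") {
    n_dd <- sum(table$iucn_category == "DD")
    table <- table[table$iucn_category != "DD", , drop = FALSE]
    rownames(table) <- NULL
    class(table) <- c("trait_table", "data.frame")
    say("dd_mode=drop: ", n_dd, " DD species removed up front")
  }
  say("diet axis")
  diet <- stage("diet_axis", diet_axis(table, n_axes = config$diet_axes))
  say("imputation (m = ", config$n_imputations, ")")
  ens <- stage("imputation",
               impute_traits(table, diet, trees = trees,
                             k = config$phylo_eigenvectors,
                             m = config$n_imputations,
                             n_iter = config$impute_iterations,
                             donors = config$impute_donors,
                             seed = substream_seed(config$seed,
                                                   "imputation")))
  say("strategy surface")
  surface <- stage("strategy_surface",
                   strategy_surface(ens,
                                    quantiles = config$kde_quantiles))
  # hypervolumes on a single randomly selected imputed dataset
  pick <- with_seed(substream_seed(config$seed, "member-choice"),
                    sample.int(length(ens$members), 1))
  z <- ens$members[[pick]]
  sp <- config$svm_params
  fit_hv <- function(xx, stream) {
    hypervolume(xx, nu = sp$nu, gamma = sp$gamma,
                samples_per_point = sp$samples_per_point,
                max_samples = sp$max_samples,
                box_expansion = sp$box_expansion,
                seed = substream_seed(config$seed, stream))
  }
  say("hypervolumes")
  hv_all <- stage("hypervolume", fit_hv(unclass(z), "hv-combined"))
  is_m <- table$taxon_class == "mammal"
  hv_m <- if (sum(is_m) >= 7)
    stage("hypervolume", fit_hv(unclass(z)[is_m, ], "hv-mammal"))
  hv_b <- if (sum(!is_m) >= 7)
    stage("hypervolume", fit_hv(unclass(z)[!is_m, ], "hv-bird"))
  setops <- NULL; densities <- NULL
  if (!is.null(hv_m) && !is.null(hv_b)) {
    setops <- stage("set_operations",
                    hv_set_operations(hv_m, hv_b,
                                      seed = substream_seed(config$seed,
                                                            "set-ops")))
    densities <- c(mammal = point_density(hv_m),
                   bird = point_density(hv_b))
  }
  say("null-model occupation (", config$n_replicates, " replicates)")
  occupation <- lapply(config$null_models, function(mid) {
    stage(paste0("null_model_", mid),
          occupation_test(hv_all, mid,
                          n_replicates = config$n_replicates,
                          seed = substream_seed(config$seed, "nulls",
                                                mid)))
  })
  names(occupation) <- paste0("model_", config$null_models)
  say("extinction scenarios (", config$n_replicates, " replicates)")
  run_scen <- function(mode) {
    stage(paste0(mode, "_scenario"),
          scenario_ensemble(z, table$iucn_category, mode = mode,
                            n_replicates = config$n_replicates,
                            draw_mode = config$draw_mode,
                            dd_mode = if (config$dd_mode == "drop")
                              "as_LC" else config$dd_mode,
                            probabilities =
                              config$extinction_probabilities,
                            hv_args = list(
                              nu = sp$nu, gamma = sp$gamma,
                              samples_per_point = sp$samples_per_point,
                              max_samples = sp$max_samples,
                              box_expansion = sp$box_expansion),
                            seed = substream_seed(config$seed,
                                                  "extinction")))
  }
  proj <- run_scen("projected")
  rand <- run_scen("randomized")
  comparison <- stage("comparison",
                      compare_scenarios(rand, proj, hv_all$volume))
  obs_sum <- summarize_traits(invert_standardize(z))
  shifts <- lapply(colnames(proj$trait_means), function(tr)
    stage("trait_shift",
          trait_shift_test(obs_sum$means[[tr]], proj, tr)))
  names(shifts) <- colnames(proj$trait_means)
  mass_red <- 100 * (1 - proj$trait_medians[, "body_mass"] /
                       obs_sum$medians[["body_mass"]])
  out <- structure(list(
    diet = diet, ensemble = ens, surface = surface,
    hypervolumes = list(combined = hv_all, mammal = hv_m, bird = hv_b),
    set_operations = setops, densities = densities,
    occupation = occupation,
    scenarios = list(projected = proj, randomized = rand),
    comparison = comparison, trait_shifts = shifts,
    observed_summary = obs_sum,
    median_mass_reduction = c(mean = mean(mass_red),
                              min = min(mass_red), max = max(mass_red)),
    selected_member = pick, config = config
  ), class = "strategy_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.strategy_pipeline <- function(x, ...) {
  vf <- x$surface$scores$variance_fraction
  cat("Ecological strategy pipeline\n")
  cat(sprintf("  species: %d (PC1+PC2 explain %.0f%% of trait variation)\n",
              nrow(x$surface$scores$scores), 100 * sum(vf[1:2])))
  cat(sprintf("  combined strategy space: %.4g SD^5\n",
              x$hypervolumes$combined$volume))
  if (!is.null(x$set_operations))
    cat(sprintf("  mammal %.4g / bird %.4g SD^5, intersection %.0f%% of union\n",
                x$hypervolumes$mammal$volume, x$hypervolumes$bird$volume,
                100 * x$set_operations$shares[["intersection"]]))
  for (nm in names(x$occupation)) {
    o <- x$occupation[[nm]]
    cat(sprintf("  occupation of null %d: %.0f%% (p = %.3g)\n",
                o$model_id, 100 * o$occupation, o$p_value))
  }
  cat(sprintf("  scenarios: projected mean %.4g vs randomized mean %.4g SD^5 (KS D = %.2f, p = %.3g)\n",
              mean(x$scenarios$projected$volumes),
              mean(x$scenarios$randomized$volumes),
              x$comparison$D, x$comparison$p_value))
  ms <- x$trait_shifts$body_mass
  cat(sprintf("  body mass: %.3g g -> %.3g g (%s, p = %.3g); median mass -%.1f%% (%.1f-%.1f%%)\n",
              ms$observed, ms$scenario_mean, ms$direction, ms$p_value,
              x$median_mass_reduction[["mean"]],
              x$median_mass_reduction[["min"]],
              x$median_mass_reduction[["max"]]))
  invisible(x)
}

# Write the pipeline report bundle: one CSV per result table plus a
# JSON summary of the headline statistics.
write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  sc <- x$surface$scores$scores
  w(data.frame(species_id = rownames(sc), sc, check.names = FALSE),
    "surface_scores.csv")
  w(x$surface$kde$contours, "contours.csv")
  hv <- data.frame(
    set = c("combined", "mammal", "bird"),
    volume = c(x$hypervolumes$combined$volume,
               if (is.null(x$hypervolumes$mammal)) NA else
                 x$hypervolumes$mammal$volume,
               if (is.null(x$hypervolumes$bird)) NA else
                 x$hypervolumes$bird$volume))
  w(hv, "volumes.csv")
  occ <- do.call(rbind, lapply(x$occupation, function(o)
    data.frame(model = o$model_id, occupation = o$occupation,
               mean_null_volume = o$mean_null_volume,
               p_value = o$p_value)))
  w(occ, "occupation.csv")
  sv <- rbind(
    data.frame(scenario = "projected",
               replicate = seq_along(x$scenarios$projected$volumes),
               volume = x$scenarios$projected$volumes),
    data.frame(scenario = "randomized",
               replicate = seq_along(x$scenarios$randomized$volumes),
               volume = x$scenarios$randomized$volumes))
  w(sv, "scenario_volumes.csv")
  sh <- do.call(rbind, lapply(x$trait_shifts, function(s)
    data.frame(trait = s$trait, observed = s$observed,
               scenario_mean = s$scenario_mean, min = s$range[1],
               max = s$range[2], direction = s$direction,
               p_value = s$p_value)))
  w(sh, "trait_shifts.csv")
  summary <- list(
    n_species = nrow(sc),
    pc12_variance_fraction =
      sum(x$surface$scores$variance_fraction[1:2]),
    combined_volume = x$hypervolumes$combined$volume,
    occupation = lapply(x$occupation, `[[`, "occupation"),
    ks_D = x$comparison$D, ks_p = x$comparison$p_value,
    effect_sizes = x$comparison$effect_sizes,
    median_mass_reduction = as.list(x$median_mass_reduction),
    seed = x$config$seed
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
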