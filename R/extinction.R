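# Probabilistic 100-year extinction scenarios: category-weighted
# ("projected") versus trait-blind ("randomized") species loss,
# per-replicate strategy-space volumes, and the statistics comparing
# the two futures.

#' Default 100-year extinction probabilities per IUCN category
#'
#' CR 0.999, EN 0.667, VU 0.1, NT 0.01, LC 0.0001. Data Deficient
#' species are handled separately via `dd_mode`: treated as LC
#' (default), dropped, or assigned the average predicted probability
#' 0.277.
#'
#' @return named numeric vector over CR, EN, VU, NT, LC.
#' @export
default_extinction_probs <- function() {
  c(CR = 0.999, EN = 0.667, VU = 0.1, NT = 0.01, LC = 0.0001)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Expected species losses per IUCN category
#'
#' `loss_c = round(count_c * p_c)` with half-away-from-zero rounding,
#' so non-integer expectations map to the nearest count.
#'
#' @param category_counts named integer vector of species counts per
#'   category.
#' @param probabilities named extinction probabilities covering every
#'   category in `category_counts`.
#' @return named integer vector of losses, with attribute `total`.
#' @export
expected_losses <- function(category_counts,
                            probabilities = default_extinction_probs()) {
  if (any(category_counts < 0)) stop("counts must be non-negative")
  unknown <- setdiff(names(category_counts), names(probabilities))
  if (length(unknown))
    stop("no extinction probability for category: ",
         paste(unknown, collapse = ", "))
  p <- probabilities[names(category_counts)]
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  loss <- round_half_away(category_counts * p)
  structure(as.integer(loss), names = names(category_counts),
            total = as.integer(sum(loss)))
}

# Resolve DD handling: returns effective categories/probabilities and
# the indices kept (dd_mode = "drop" removes DD species up front).
resolve_dd <- function(categories, dd_mode, probabilities) {
  keep <- rep(TRUE, length(categories))
  probs <- probabilities
  if (dd_mode == "drop") {
    keep <- categories != "DD"
  } else if (dd_mode == "as_LC") {
    probs <- c(probs, DD = unname(probabilities[["LC"]]))
  } else if (dd_mode == "fixed_0.277") {
    probs <- c(probs, DD = 0.277)
  } else stop("unknown dd_mode: ", dd_mode)
  list(keep = keep, probs = probs)
}

# Core survivor sampler, shared by simulate_scenario() and
# scenario_ensemble(). Returns indices (into the kept set) of
# survivors.
sample_survivors <- function(categories, mode, draw_mode, probs, seed) {
  n <- length(categories)
  counts <- table(categories)
  losses <- expected_losses(setNames(as.integer(counts), names(counts)),
                            probs)
  if (any(losses > as.integer(counts)))
    stop("expected loss exceeds category count")
  with_seed(seed, {
    if (mode == "projected") {
      if (draw_mode == "fixed_counts") {
        lost <- integer(0)
        for (cat in names(losses)) {
          k <- losses[[cat]]
          if (k > 0) {
            idx <- which(categories == cat)
            lost <- c(lost, idx[sample.int(length(idx), k)])
          }
        }
      } else { # bernoulli
        lost <- which(runif(n) < probs[categories])
      }
    } else { # randomized: same total, blind to identity and traits
      total <- attr(losses, "total")
      lost <- if (total > 0) sample.int(n, total) else integer(0)
    }
    setdiff(seq_len(n), lost)
  })
}

#' Simulate one extinction scenario
#'
#' Removes species from a trait table either according to their IUCN
#' category extinction probabilities ("projected") or uniformly at
#' random with the same total loss ("randomized"). Under
#' `draw_mode = "fixed_counts"` exactly `round(count_c * p_c)` species
#' are lost from each category in every replicate (the species-richness
#' control that makes projected and randomized runs lose identical
#' totals); `"bernoulli"` draws each species' fate independently.
#' Data Deficient species are first treated according to `dd_mode`.
#'
#' @param table a [trait_table()] with a category for every species.
#' @param mode `"projected"` or `"randomized"`.
#' @param draw_mode `"fixed_counts"` or `"bernoulli"`.
#' @param dd_mode `"as_LC"`, `"drop"` or `"fixed_0.277"`.
#' @param probabilities per-category extinction probabilities.
#' @param seed integer seed.
#' @return the surviving `trait_table`; attribute `lost` holds the ids
#'   of the species removed.
#' @export
simulate_scenario <- function(table,
                              mode = c("projected", "randomized"),
                              draw_mode = c("fixed_counts", "bernoulli"),
                              dd_mode = c("as_LC", "drop", "fixed_0.277"),
                              probabilities = default_extinction_probs(),
                              seed = 1) {
  stopifnot(inherits(table, "trait_table"))
  mode <- match.arg(mode); draw_mode <- match.arg(draw_mode)
  dd_mode <- match.arg(dd_mode)
  if (anyNA(table$iucn_category))
    stop("every species needs an IUCN category")
  dd <- resolve_dd(table$iucn_category, dd_mode, probabilities)
  tab <- table[dd$keep, , drop = FALSE]
  surv <- sample_survivors(tab$iucn_category, mode, draw_mode, dd$probs,
                           seed)
  out <- tab[surv, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  attr(out, "lost") <- setdiff(tab$species_id, out$species_id)
  out
}

#' Replicated extinction scenarios with strategy-space volumes
#'
#' Repeats an extinction scenario `n_replicates` times; per replicate
#' the surviving species' rows of the full-set standardized trait
#' matrix are refit with [hypervolume()] (the z-transformation stays
#' fixed to the full observed set, so all volumes are in the same SD^d
#' units) and back-transformed trait summaries are recorded.
#'
#' @param z complete `standardized_traits` matrix of the full species
#'   set (one imputed dataset), carrying transform metadata.
#' @param categories IUCN category per species (aligned with `z` rows).
#' @param mode,draw_mode,dd_mode,probabilities see
#'   [simulate_scenario()].
#' @param n_replicates number of replicates.
#' @param hv_args list of arguments passed on to [hypervolume()]
#'   (e.g. `samples_per_point`).
#' @param seed integer seed; replicate r uses substream
#'   `(seed, "<mode>-scenario", r)`.
#' @return object of class `scenario_ensemble`: `volumes` (one per
#'   replicate), `trait_means` and `trait_medians` (replicate x trait
#'   matrices of back-transformed summaries), `n_lost`, `mode`,
#'   `n_replicates`, `seed`.
#' @export
scenario_ensemble <- function(z, categories,
                              mode = c("projected", "randomized"),
                              n_replicates = 999,
                              draw_mode = c("fixed_counts", "bernoulli"),
                              dd_mode = c("as_LC", "drop", "fixed_0.277"),
                              probabilities = default_extinction_probs(),
                              hv_args = list(), seed = 1) {
  mode <- match.arg(mode); draw_mode <- match.arg(draw_mode)
  dd_mode <- match.arg(dd_mode)
  stopifnot(inherits(z, "standardized_traits"),
            length(categories) == nrow(z), n_replicates >= 1)
  if (anyNA(categories)) stop("every species needs an IUCN category")
  dd <- resolve_dd(categories, dd_mode, probabilities)
  zz <- z[dd$keep, , drop = FALSE]
  attr(zz, "transforms") <- attr(z, "transforms")
  cats <- categories[dd$keep]
  vols <- rep(NA_real_, n_replicates)
  tmeans <- matrix(NA_real_, n_replicates, 5)
  tmedians <- matrix(NA_real_, n_replicates, 5)
  colnames(tmeans) <- colnames(tmedians) <-
    c("body_mass", "litter_clutch_size", "habitat_breadth",
      "generation_length", "diet")
  n_lost <- rep(NA_integer_, n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- substream_seed(seed, paste0(mode, "-scenario"), r)
    surv <- sample_survivors(cats, mode, draw_mode, dd$probs, s)
    n_lost[r] <- nrow(zz) - length(surv)
    zs <- unclass(zz)[surv, , drop = FALSE]
    hv <- tryCatch(
      do.call(hypervolume,
              c(list(x = zs, seed = substream_seed(s, "scenario-mc")),
                hv_args)),
      error = function(e) NULL)
    if (is.null(hv)) {
      warning("replicate ", r, " hypervolume failed and was dropped")
      next
    }
    vols[r] <- hv$volume
    sm <- summarize_traits(invert_standardize(zs, attr(z, "transforms")))
    tmeans[r, ] <- sm$means
    tmedians[r, ] <- sm$medians
  }
  ok <- !is.na(vols)
  if (mean(!ok) >= 0.05) stop("more than 5% of replicates failed")
  structure(list(volumes = vols[ok],
                 trait_means = tmeans[ok, , drop = FALSE],
                 trait_medians = tmedians[ok, , drop = FALSE],
                 n_lost = n_lost[ok], mode = mode,
                 n_replicates = sum(ok), seed = seed),
            class = "scenario_ensemble")
}

#' @export
print.scenario_ensemble <- function(x, ...) {
  cat(sprintf(
    "%s extinction scenario: %d replicates, %d species lost per replicate\n  volume mean = %.4g SD^d (range %.4g-%.4g)\n",
    x$mode, x$n_replicates, x$n_lost[1], mean(x$volumes),
    min(x$volumes), max(x$volumes)))
  invisible(x)
}

#' Back-transformed trait summaries of a species set
#'
#' Means on the transformed scale, reported on the raw scale: geometric
#' means for the log10 traits (body mass, litter/clutch size,
#' generation length), the squared mean square root for habitat
#' breadth, and the arithmetic mean for the diet axis. Medians are
#' reported alongside (the median body mass feeds the percent
#' median-mass-reduction statistic).
#'
#' @param x matrix or data frame of raw-scale traits with columns
#'   body_mass, litter_clutch_size, habitat_breadth, generation_length,
#'   diet (as produced by [invert_standardize()]), all complete.
#' @return list with named numeric vectors `means` and `medians`.
#' @export
summarize_traits <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty table")
  if (anyNA(x)) stop("traits must be complete (post-imputation)")
  cols <- c("body_mass", "litter_clutch_size", "habitat_breadth",
            "generation_length", "diet")
  stopifnot(all(cols %in% colnames(x)))
  means <- c(
    body_mass = 10^mean(log10(x[, "body_mass"])),
    litter_clutch_size = 10^mean(log10(x[, "litter_clutch_size"])),
    habitat_breadth = mean(sqrt(x[, "habitat_breadth"]))^2,
    generation_length = 10^mean(log10(x[, "generation_length"])),
    diet = mean(x[, "diet"])
  )
  medians <- apply(x[, cols, drop = FALSE], 2, median)
  list(means = means, medians = medians)
}

#' Compare two scenario ensembles and the observed volume
#'
#' Two-sample Kolmogorov-Smirnov test between the volume distributions
#' of two ensembles (D is the sup-difference of their empirical CDFs),
#' plus per-ensemble effect sizes: `observed - replicate volume`,
#' summarized as the mean with a 2.5-97.5 percentile interval.
#'
#' @param ens_a,ens_b `scenario_ensemble` objects with at least 5
#'   replicates each.
#' @param observed_volume the observed (no-extinction) volume in the
#'   same SD^d units.
#' @return object of class `scenario_comparison`: `D`, `p_value`,
#'   `effect_sizes` (data frame per ensemble: mean, lower, upper).
#' @export
compare_scenarios <- function(ens_a, ens_b, observed_volume) {
  stopifnot(inherits(ens_a, "scenario_ensemble"),
            inherits(ens_b, "scenario_ensemble"))
  if (length(ens_a$volumes) < 5 || length(ens_b$volumes) < 5)
    stop("need at least 5 replicates per ensemble")
  ks <- suppressWarnings(ks.test(ens_a$volumes, ens_b$volumes))
  eff <- function(e) {
    d <- e$volumes - observed_volume
    c(mean = mean(d), lower = unname(quantile(d, 0.025)),
      upper = unname(quantile(d, 0.975)))
  }
  es <- rbind(eff(ens_a), eff(ens_b))
  rownames(es) <- c(ens_a$mode, ens_b$mode)
  structure(list(D = unname(ks$statistic), p_value = ks$p.value,
                 effect_sizes = as.data.frame(es),
                 observed_volume = observed_volume),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("Scenario comparison: KS D = %.3f, p = %.3g\n", x$D,
              x$p_value))
  cat(sprintf("  observed volume = %.4g SD^d\n", x$observed_volume))
  cat("  effect sizes (scenario - observed), mean [95% interval]:\n")
  for (i in seq_len(nrow(x$effect_sizes))) {
    cat(sprintf("    %-11s %+.4g [%+.4g, %+.4g]\n",
                rownames(x$effect_sizes)[i], x$effect_sizes$mean[i],
                x$effect_sizes$lower[i], x$effect_sizes$upper[i]))
  }
  invisible(x)
}

#' Permutation test of a trait-distribution shift under a scenario
#'
#' Tests whether the back-transformed mean of a trait among scenario
#' survivors differs from the observed (full species set) mean, with
#' the rank-based one-tailed p-value
#' `p = (1 + #\{replicates on the observed side\}) / (n + 1)` in the
#' direction of the observed-vs-replicate-mean difference. Reports the
#' direction and the min-max of the replicate summaries.
#'
#' @param observed_summary observed back-transformed mean of the trait.
#' @param ensemble a `scenario_ensemble`.
#' @param trait one of body_mass, litter_clutch_size, habitat_breadth,
#'   generation_length, diet.
#' @param statistic `"mean"` (default) or `"median"` replicate summary.
#' @return list of class `trait_shift`: `trait`, `direction`
#'   (`"decrease"`/`"increase"` of the trait under the scenario),
#'   `p_value`, `observed`, `scenario_mean`, `range` (min-max across
#'   replicates).
#' @export
trait_shift_test <- function(observed_summary, ensemble, trait,
                             statistic = c("mean", "median")) {
  stopifnot(inherits(ensemble, "scenario_ensemble"))
  statistic <- match.arg(statistic)
  reps <- switch(statistic, mean = ensemble$trait_means,
                 median = ensemble$trait_medians)[, trait]
  if (length(unique(reps)) == 1L)
    stop("replicate summaries are constant; the shift p-value is ",
         "undefined")
  decrease <- mean(reps) < observed_summary
  n <- length(reps)
  p <- if (decrease) (1 + sum(reps >= observed_summary)) / (n + 1)
  else (1 + sum(reps <= observed_summary)) / (n + 1)
  structure(list(trait = trait,
                 direction = if (decrease) "decrease" else "increase",
                 p_value = p, observed = observed_summary,
                 scenario_mean = mean(reps), range = range(reps)),
            class = "trait_shift")
}

#' @export
print.trait_shift <- function(x, ...) {
  cat(sprintf(
    "%s: observed %.4g -> scenario %.4g [%.4g-%.4g], %s, p = %.4g\n",
    x$trait, x$observed, x$scenario_mean, x$range[1], x$range[2],
    x$direction, x$p_value))
  invisible(x)
}
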