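# Four null models of multivariate trait variation, and the
# rank-based permutation test of observed strategy-space occupation.

#' Sample a null trait matrix
#'
#' Generates a matrix of the same shape as the observed standardized
#' trait matrix under one of four null models of trait variation:
#' \describe{
#'   \item{1}{traits independent, each uniform over its observed
#'     min-max range (approximately a hypercube).}
#'   \item{2}{traits independent, each normal with its observed mean
#'     and sd (approximately a hypersphere).}
#'   \item{3}{traits independent, each an independent random
#'     permutation of its observed values (observed margins kept
#'     exactly).}
#'   \item{4}{multivariate normal with the observed mean vector and
#'     covariance matrix (approximately a hyperellipsoid).}
#' }
#'
#' @param model_id 1, 2, 3 or 4.
#' @param observed complete numeric matrix (species x traits).
#' @param seed integer seed.
#' @return numeric matrix of the same dimensions as `observed`.
#' @export
sample_null <- function(model_id, observed, seed = 1) {
  x <- as.matrix(observed)
  if (anyNA(x)) stop("observed matrix must be complete")
  stopifnot(model_id %in% 1:4)
  n <- nrow(x); p <- ncol(x)
  with_seed(seed, {
    out <- switch(as.character(model_id),
      "1" = {
        lo <- apply(x, 2, min); hi <- apply(x, 2, max)
        matrix(runif(n * p, rep(lo, each = n), rep(hi, each = n)), n, p)
      },
      "2" = {
        mu <- colMeans(x); sdev <- apply(x, 2, sd)
        matrix(rnorm(n * p, rep(mu, each = n), rep(sdev, each = n)), n, p)
      },
      "3" = apply(x, 2, sample),
      "4" = {
        mu <- colMeans(x)
        S <- cov(x)
        L <- tryCatch(chol(S), error = function(e) {
          warning("observed covariance not positive definite; ",
                  "using nearest-PSD repair")
          e2 <- eigen(S, symmetric = TRUE)
          v <- pmax(e2$values, max(e2$values) * 1e-10)
          chol(e2$vectors %*% diag(v) %*% t(e2$vectors))
        })
        sweep(matrix(rnorm(n * p), n, p) %*% L, 2, mu, "+")
      })
    colnames(out) <- colnames(x)
    out
  })
}

#' Test strategy-space occupation against a null model
#'
#' Builds `n_replicates` null trait matrices under the chosen null
#' model, fits a hypervolume to each with the same species count and
#' SVM parameters as the observed fit, and compares the observed volume
#' to the null volume distribution. Occupation is reported as
#' `observed volume / mean null volume` (the default convention) or as
#' the mean of per-replicate ratios. The p-value is the one-tailed
#' rank-based permutation probability toward restriction,
#' `p = (1 + #\{V_null <= V_obs\}) / (n_replicates + 1)`, so the
#' smallest attainable value with 999 replicates is 0.001.
#'
#' @param observed a fitted [hypervolume()] (its stored data and
#'   parameters are reused for the null fits).
#' @param model_id null model 1-4, see [sample_null()].
#' @param n_replicates number of Monte-Carlo null replicates.
#' @param seed integer seed (each replicate uses its own substream).
#' @param convention `"obs_over_mean"` or `"mean_of_ratios"`.
#' @return object of class `occupation_test`: `occupation`, `p_value`,
#'   `observed_volume`, `mean_null_volume`, `null_volumes`, `model_id`,
#'   `convention`.
#' @export
occupation_test <- function(observed, model_id, n_replicates = 999,
                            seed = 1,
                            convention = c("obs_over_mean",
                                           "mean_of_ratios")) {
  stopifnot(inherits(observed, "hypervolume"), n_replicates >= 1)
  convention <- match.arg(convention)
  pr <- observed$params
  vols <- rep(NA_real_, n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- substream_seed(seed, sprintf("null-model-%d", model_id), r)
    nullx <- sample_null(model_id, observed$data, seed = s)
    hv <- tryCatch(
      hypervolume(nullx, nu = pr$nu, gamma = pr$gamma,
                  samples_per_point = pr$samples_per_point,
                  max_samples = pr$max_samples,
                  box_expansion = pr$box_expansion,
                  seed = substream_seed(s, "null-mc")),
      error = function(e) NULL)
    if (is.null(hv)) {
      warning("null replicate ", r, " failed and was dropped")
    } else {
      vols[r] <- hv$volume
    }
  }
  ok <- !is.na(vols)
  if (mean(!ok) >= 0.05)
    stop("more than 5% of null replicates failed")
  vols <- vols[ok]
  occ <- switch(convention,
                obs_over_mean = observed$volume / mean(vols),
                mean_of_ratios = mean(observed$volume / vols))
  p <- (1 + sum(vols <= observed$volume)) / (length(vols) + 1)
  structure(list(model_id = model_id, occupation = occ, p_value = p,
                 observed_volume = observed$volume,
                 mean_null_volume = mean(vols), null_volumes = vols,
                 convention = convention),
            class = "occupation_test")
}

#' @export
print.occupation_test <- function(x, ...) {
  cat(sprintf(
    "Null model %d: occupation = %.1f%% (observed %.4g / mean null %.4g SD^d), p = %.4g (%d replicates, %s)\n",
    x$model_id, 100 * x$occupation, x$observed_volume,
    x$mean_null_volume, x$p_value, length(x$null_volumes),
    x$convention))
  invisible(x)
}
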