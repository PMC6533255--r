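# Building the continuous diet axis (Gower distance + principal
# coordinates) and the transformed, standardized five-trait matrix that
# is the coordinate system of every downstream volume ("SD" units).

#' Gower distance between species from quantitative variables
#'
#' Range-normalized mean absolute difference: for each variable the
#' absolute difference is divided by the variable's observed range, and
#' the per-variable terms are averaged over the variables with nonzero
#' range (zero-range variables carry no dissimilarity signal and are
#' excluded from the average). Distances are in `[0, 1]`.
#'
#' @param x numeric matrix or data frame (species x variables), no
#'   missing values.
#' @return symmetric distance matrix with zero diagonal, dimnames from
#'   `rownames(x)`.
#' @export
gower_distance <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric")
  if (anyNA(x)) stop("x must be complete (drop species with missing rows)")
  n <- nrow(x)
  if (n < 2) stop("need at least 2 species")
  rng <- apply(x, 2, function(v) diff(range(v)))
  keep <- which(rng > 0)
  if (length(keep) == 0)
    stop("all variables have zero range: no dissimilarity signal")
  acc <- matrix(0, n, n)
  for (j in keep) {
    acc <- acc + abs(outer(x[, j], x[, j], "-")) / rng[j]
  }
  d <- acc / length(keep)
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centers the matrix of squared distances (`B = -1/2 C d^2 C`),
#' eigendecomposes it, and scales eigenvectors by the square root of
#' their (positive) eigenvalues to obtain species scores. Negative
#' eigenvalues (possible for non-Euclidean dissimilarities such as
#' Gower) are retained in the eigenvalue report but excluded from the
#' scores and from the variance-fraction denominator, which is the sum
#' of positive eigenvalues.
#'
#' @param d symmetric distance matrix.
#' @param n_axes number of axes to return (truncated with a warning if
#'   it exceeds the number of positive eigenvalues).
#' @return object of class `pcoa`: `eigenvalues` (all, descending),
#'   `scores` (species x axes), `variance_fraction` (per returned axis).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  if (n_axes < 1) stop("n_axes must be >= 1")
  n <- nrow(d)
  A <- -0.5 * d^2
  B <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  tol <- max(abs(ev), 0) * 1e-9 + 1e-12
  npos <- sum(ev > tol)
  k <- n_axes
  if (k > npos) {
    warning("only ", npos, " positive eigenvalues; axes truncated")
    k <- npos
  }
  if (k == 0) {
    scores <- matrix(0, n, min(n_axes, 1),
                     dimnames = list(rownames(d), "axis1"))
    vf <- rep(0, ncol(scores))
  } else {
    scores <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(ev[seq_len(k)]), k)
    dimnames(scores) <- list(rownames(d), paste0("axis", seq_len(k)))
    vf <- ev[seq_len(k)] / sum(ev[ev > tol])
  }
  structure(list(eigenvalues = ev, scores = scores,
                 variance_fraction = vf),
            class = "pcoa")
}

#' Derive the continuous diet axis from diet compositions
#'
#' Computes Gower distances between diet-complete species over the ten
#' diet categories, ordinates them by principal coordinates, and
#' returns the first (or first two) axis scores as the species' "diet"
#' trait. The axis is oriented so that the invertebrates category loads
#' positively (the invertivore-to-herbivore gradient). Species without
#' diet data receive no score here; they are filled later by trait
#' imputation on the derived axis.
#'
#' Variable loadings are reported as the projection of each
#' range-normalized, centered diet category onto the unit eigenvector of
#' the axis (a weighted-covariance convention; only relative magnitude
#' and sign are interpretable).
#'
#' @param table a [trait_table()].
#' @param n_axes 1 or 2 diet axes.
#' @return object of class `diet_axis`: `scores` (matrix, diet-complete
#'   species x axes), `loadings` (10 x axes), `variance_fraction`,
#'   `eigenvalues`, `species` (ids of scored species).
#' @export
diet_axis <- function(table, n_axes = 1) {
  stopifnot(inherits(table, "trait_table"), n_axes %in% c(1, 2))
  dm <- as.matrix(table[, diet_categories()])
  rownames(dm) <- table$species_id
  complete <- rowSums(is.na(dm)) == 0
  if (sum(complete) < 3) stop("need at least 3 diet-complete species")
  x <- dm[complete, , drop = FALSE]
  d <- gower_distance(x)
  ord <- pcoa(d, n_axes = n_axes)
  if (n_axes == 2 && ncol(ord$scores) < 2)
    stop("fewer than 2 positive eigenvalues: cannot return 2 diet axes")
  scores <- ord$scores[, seq_len(n_axes), drop = FALSE]
  # orient: invertebrates load positively on axis 1 (and on axis 2 fix
  # an arbitrary but deterministic sign via the largest-range category)
  for (j in seq_len(ncol(scores))) {
    anchor <- if (j == 1) x[, "diet_inv"] else x[, which.max(apply(x, 2, sd))]
    if (stats::cor(anchor, scores[, j]) < 0) scores[, j] <- -scores[, j]
  }
  rng <- apply(x, 2, function(v) diff(range(v)))
  loadings <- matrix(0, ncol(x), ncol(scores),
                     dimnames = list(colnames(x), colnames(scores)))
  for (j in seq_len(ncol(scores))) {
    u <- scores[, j] / sqrt(sum(scores[, j]^2)) # unit eigenvector
    xs <- sweep(x, 2, colMeans(x))
    xs <- sweep(xs, 2, ifelse(rng > 0, rng, 1), "/")
    loadings[, j] <- as.numeric(crossprod(xs, u))
  }
  structure(list(scores = scores, loadings = loadings,
                 variance_fraction = ord$variance_fraction[seq_len(n_axes)],
                 eigenvalues = ord$eigenvalues,
                 species = rownames(scores)),
            class = "diet_axis")
}

transform_names <- function() {
  c(body_mass = "log10", litter_clutch_size = "log10",
    habitat_breadth = "sqrt", generation_length = "log10",
    diet = "identity")
}

trait_matrix_columns <- function() {
  c("log10_body_mass", "log10_litter_clutch_size", "sqrt_habitat_breadth",
    "log10_generation_length", "diet")
}

#' Transform and standardize the five traits
#'
#' Applies the normalizing transforms (log10 for body mass, litter/
#' clutch size and generation length; square root for habitat breadth;
#' the diet axis is already continuous) and z-scores each column to
#' zero mean and unit variance. Missing cells propagate as `NA`;
#' z-parameters are computed from the available values. The pre-z mean
#' and sd and the transform name are kept per column so raw values can
#' be reconstructed (attribute `transforms`).
#'
#' @param table a [trait_table()].
#' @param diet a [diet_axis()] result, or a named numeric vector of
#'   per-species diet scores.
#' @return numeric matrix (species x 5, class `standardized_traits`)
#'   with `transforms` attribute; column order: mass, litter, habitat,
#'   generation length, diet.
#' @export
transform_standardize <- function(table, diet) {
  stopifnot(inherits(table, "trait_table"))
  if (inherits(diet, "diet_axis"))
    diet <- setNames(diet$scores[, 1], diet$species)
  n <- nrow(table)
  raw <- cbind(
    body_mass = table$body_mass,
    litter_clutch_size = table$litter_clutch_size,
    habitat_breadth = table$habitat_breadth,
    generation_length = table$generation_length,
    diet = unname(diet[table$species_id])
  )
  tnames <- transform_names()
  for (tr in c("body_mass", "litter_clutch_size", "generation_length")) {
    bad <- !is.na(raw[, tr]) & raw[, tr] <= 0
    if (any(bad))
      stop("nonpositive ", tr, " under log transform for: ",
           paste(head(table$species_id[bad]), collapse = ", "))
  }
  tf <- raw
  tf[, "body_mass"] <- log10(raw[, "body_mass"])
  tf[, "litter_clutch_size"] <- log10(raw[, "litter_clutch_size"])
  tf[, "habitat_breadth"] <- sqrt(raw[, "habitat_breadth"])
  tf[, "generation_length"] <- log10(raw[, "generation_length"])
  mu <- colMeans(tf, na.rm = TRUE)
  sdev <- apply(tf, 2, sd, na.rm = TRUE)
  if (any(is.na(sdev)) || any(sdev == 0, na.rm = TRUE))
    stop("a trait has zero variance (or no observed values); cannot z-score")
  z <- sweep(sweep(tf, 2, mu), 2, sdev, "/")
  colnames(z) <- trait_matrix_columns()
  rownames(z) <- table$species_id
  transforms <- lapply(seq_along(tnames), function(i) {
    list(trait = names(tnames)[i], transform = unname(tnames[i]),
         mean = unname(mu[i]), sd = unname(sdev[i]))
  })
  names(transforms) <- trait_matrix_columns()
  structure(z, transforms = transforms,
            class = c("standardized_traits", "matrix", "array"))
}

#' Reconstruct raw trait values from a standardized matrix
#'
#' Inverts the z-scoring and the normalizing transform using the
#' metadata stored by [transform_standardize()], returning traits on
#' their original scales (mass in grams, generation length in years,
#' habitat breadth as counts; the diet axis stays on its ordination
#' scale).
#'
#' @param z a `standardized_traits` matrix (or compatible subset of its
#'   rows).
#' @param transforms transform metadata; defaults to the attribute
#'   carried by `z`.
#' @return numeric matrix of raw-scale traits with columns body_mass,
#'   litter_clutch_size, habitat_breadth, generation_length, diet.
#' @export
invert_standardize <- function(z, transforms = attr(z, "transforms")) {
  if (is.null(transforms)) stop("no transform metadata available")
  z <- unclass(z)
  out <- matrix(NA_real_, nrow(z), 5,
                dimnames = list(rownames(z),
                                c("body_mass", "litter_clutch_size",
                                  "habitat_breadth", "generation_length",
                                  "diet")))
  for (j in seq_along(transforms)) {
    tfm <- transforms[[j]]
    v <- z[, j] * tfm$sd + tfm$mean
    out[, j] <- switch(tfm$transform,
                       log10 = 10^v,
                       sqrt = v^2,
                       identity = v)
  }
  out
}

# z-score a transformed-scale matrix and package it with metadata; used
# when rebuilding standardized matrices after imputation.
standardize_transformed <- function(tf, template) {
  transforms <- attr(template, "transforms")
  mu <- colMeans(tf)
  sdev <- apply(tf, 2, sd)
  z <- sweep(sweep(tf, 2, mu), 2, sdev, "/")
  for (j in seq_along(transforms)) {
    transforms[[j]]$mean <- unname(mu[j])
    transforms[[j]]$sd <- unname(sdev[j])
  }
  colnames(z) <- trait_matrix_columns()
  structure(z, transforms = transforms,
            class = c("standardized_traits", "matrix", "array"))
}

# transformed (pre-z) scale values of a standardized matrix
transformed_scale <- function(z, transforms = attr(z, "transforms")) {
  zz <- unclass(z)
  for (j in seq_along(transforms))
    zz[, j] <- zz[, j] * transforms[[j]]$sd + transforms[[j]]$mean
  zz
}
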