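# The 2-D ecological strategy surface: PCA of the five standardized
# traits, species scores averaged across the imputation ensemble, and
# highest-density-region occurrence contours from a bivariate Gaussian
# KDE with a full (unconstrained) bandwidth matrix.

#' PCA of the standardized trait matrix
#'
#' Eigendecomposition of the covariance matrix of the z-scored traits
#' (equivalently their correlation structure). Loadings are unit
#' eigenvectors; scores are the projections `z %*% loadings`. A
#' deterministic sign convention anchors the axes: PC1 is oriented so
#' body mass loads positively and PC2 so the diet axis loads
#' negatively (the small-and-fast to large-and-slow axis, and the
#' invertivore-generalist to herbivore-specialist axis); remaining
#' axes put their largest-magnitude loading positive.
#'
#' @param z a complete `standardized_traits` matrix (one imputed
#'   dataset). Missing values are an error: impute first.
#' @return object of class `pca_surface`: `eigenvalues`, `loadings`
#'   (5 x 5), `scores` (species x 5), `variance_fraction`.
#' @export
pca_surface <- function(z) {
  zz <- unclass(z)
  if (anyNA(zz)) stop("matrix has missing cells; impute first")
  e <- eigen(cov(zz), symmetric = TRUE)
  L <- e$vectors
  dimnames(L) <- list(colnames(zz), paste0("PC", seq_len(ncol(zz))))
  # sign anchors
  if (L["log10_body_mass", 1] < 0) L[, 1] <- -L[, 1]
  if (ncol(L) >= 2 && L["diet", 2] > 0) L[, 2] <- -L[, 2]
  if (ncol(L) > 2) {
    for (j in 3:ncol(L)) {
      i <- which.max(abs(L[, j]))
      if (L[i, j] < 0) L[, j] <- -L[, j]
    }
  }
  scores <- zz %*% L
  structure(list(eigenvalues = e$values, loadings = L, scores = scores,
                 variance_fraction = e$values / sum(e$values)),
            class = "pca_surface")
}

#' Average ordination scores across an imputation ensemble
#'
#' Computes per-species arithmetic means of the PC scores across the
#' ensemble members (each already sign-anchored by the convention of
#' [pca_surface()], which makes the average invariant to axis flips),
#' and averages the variance fractions and loading matrices.
#'
#' @param results list of [pca_surface()] results, one per imputed
#'   dataset, over the same species set.
#' @return object of class `surface_scores`: `scores` (species x axes
#'   mean scores), `variance_fraction`, `loadings`, `n_members`.
#' @export
average_over_imputations <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "pca_surface")))
  ids <- rownames(results[[1]]$scores)
  for (r in results)
    if (!identical(rownames(r$scores), ids))
      stop("inconsistent species sets across ensemble members")
  scores <- Reduce(`+`, lapply(results, `[[`, "scores")) / length(results)
  vf <- Reduce(`+`, lapply(results, `[[`, "variance_fraction")) /
    length(results)
  loadings <- Reduce(`+`, lapply(results, `[[`, "loadings")) /
    length(results)
  structure(list(scores = scores, variance_fraction = vf,
                 loadings = loadings, n_members = length(results)),
            class = "surface_scores")
}

# Normal-scale (normal reference) full bandwidth matrix for a
# bivariate Gaussian KDE: H = (4/(d+2))^(2/(d+4)) n^(-2/(d+4)) * S,
# which in d = 2 reduces to H = n^(-1/3) * S.
normal_scale_bandwidth <- function(x) {
  n <- nrow(x); d <- ncol(x)
  (4 / (d + 2))^(2 / (d + 4)) * n^(-2 / (d + 4)) * cov(x)
}

#' Bivariate KDE with highest-density-region contours
#'
#' Gaussian-kernel density estimate of 2-D ordination scores with a
#' full (unconstrained) bandwidth matrix, evaluated on a grid, plus
#' highest-density regions: for each mass fraction `q` the density
#' level is found such that grid cells with density above it carry
#' total probability mass `q` (the smallest region containing mass
#' `q`). Default bandwidth is the multivariate normal-scale rule
#' `H = n^(-1/3) * S`; any symmetric positive-definite 2 x 2 matrix
#' can be supplied instead.
#'
#' Internally the data are whitened by the bandwidth factor so the
#' kernel is separable on a tensor grid; the grid therefore lives in
#' whitened coordinates and is mapped back linearly for areas and
#' contour polylines. The grid extends 3 kernel standard deviations
#' beyond the data range.
#'
#' @param scores numeric matrix (n x 2) of PC1/PC2 scores, n >= 50.
#' @param quantiles probability masses of the regions, strictly in
#'   (0, 1); default 0.5, 0.95, 0.99.
#' @param bandwidth `"normal-scale"` or a 2 x 2 bandwidth matrix.
#' @param gridsize grid points per axis.
#' @return object of class `kde_hdr`: `levels` (data frame with
#'   quantile, density level, region area, and the empirical mass of
#'   sample points inside), `contours` (data frame of polyline
#'   vertices in score coordinates: quantile, piece, x, y), `H`,
#'   `total_mass` (grid-integral check), and internal grid fields.
#' @export
kde_contours <- function(scores, quantiles = c(0.5, 0.95, 0.99),
                         bandwidth = "normal-scale", gridsize = 151) {
  x <- as.matrix(scores)[, 1:2, drop = FALSE]
  n <- nrow(x)
  if (n < 50) stop("need at least 50 points for a stable surface")
  if (any(quantiles <= 0 | quantiles >= 1))
    stop("quantiles must be strictly inside (0, 1)")
  H <- if (is.character(bandwidth)) {
    bandwidth <- match.arg(bandwidth, "normal-scale")
    normal_scale_bandwidth(x)
  } else {
    bandwidth <- as.matrix(bandwidth)
    stopifnot(all(dim(bandwidth) == 2),
              isTRUE(all.equal(bandwidth, t(bandwidth))))
    bandwidth
  }
  M <- t(chol(H))              # H = M M', whitening y = M^{-1} x
  detM <- prod(diag(M))
  y <- t(forwardsolve(M, t(x)))
  pad <- 3                     # kernel sd is 1 in whitened coordinates
  gx <- seq(min(y[, 1]) - pad, max(y[, 1]) + pad, length.out = gridsize)
  gy <- seq(min(y[, 2]) - pad, max(y[, 2]) + pad, length.out = gridsize)
  ax <- outer(gx, y[, 1], "-")
  ay <- outer(gy, y[, 2], "-")
  dens_y <- tcrossprod(dnorm(ax), dnorm(ay)) / n  # whitened-space density
  cell <- diff(gx)[1] * diff(gy)[1]
  total_mass <- sum(dens_y) * cell
  # HDR levels from cumulative grid mass, highest density first
  ord <- order(dens_y, decreasing = TRUE)
  cmass <- cumsum(dens_y[ord]) * cell
  dens_x_points <- kde_interp(gx, gy, dens_y, y) / detM
  levels <- data.frame(quantile = quantiles, level = NA_real_,
                       area = NA_real_, empirical_mass = NA_real_)
  contours <- list()
  for (i in seq_along(quantiles)) {
    q <- quantiles[i]
    kq <- which(cmass >= q)[1]
    if (is.na(kq)) kq <- length(ord)
    lev_y <- dens_y[ord[kq]]
    levels$level[i] <- lev_y / detM           # density in score units
    levels$area[i] <- kq * cell * detM        # region area in score units
    levels$empirical_mass[i] <- mean(dens_x_points >= lev_y / detM)
    cl <- contourLines(gx, gy, dens_y, levels = lev_y)
    if (length(cl)) {
      pieces <- lapply(seq_along(cl), function(pc) {
        v <- t(M %*% rbind(cl[[pc]]$x, cl[[pc]]$y))
        data.frame(quantile = q, piece = pc, x = v[, 1], y = v[, 2])
      })
      contours[[length(contours) + 1L]] <- do.call(rbind, pieces)
    }
  }
  contours <- if (length(contours)) do.call(rbind, contours)
  else data.frame(quantile = numeric(), piece = integer(),
                  x = numeric(), y = numeric())
  structure(list(levels = levels, contours = contours, H = H,
                 total_mass = total_mass, n = n,
                 grid = list(gx = gx, gy = gy, density = dens_y,
                             map = M)),
            class = "kde_hdr")
}

# Bilinear interpolation of a grid surface at arbitrary points.
kde_interp <- function(gx, gy, z, pts) {
  ix <- findInterval(pts[, 1], gx, all.inside = TRUE)
  iy <- findInterval(pts[, 2], gy, all.inside = TRUE)
  tx <- (pts[, 1] - gx[ix]) / (gx[ix + 1] - gx[ix])
  ty <- (pts[, 2] - gy[iy]) / (gy[iy + 1] - gy[iy])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  z[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    z[cbind(ix + 1, iy)] * tx * (1 - ty) +
    z[cbind(ix, iy + 1)] * (1 - tx) * ty +
    z[cbind(ix + 1, iy + 1)] * tx * ty
}

#' Build the ecological strategy surface
#'
#' Runs [pca_surface()] on each imputed dataset, averages species
#' scores across the ensemble with [average_over_imputations()], and
#' fits occurrence-probability contours on the mean PC1/PC2 scores with
#' [kde_contours()].
#'
#' @param ensemble an `imputed_ensemble` (from [impute_traits()]) or a
#'   single complete `standardized_traits` matrix.
#' @param quantiles HDR mass fractions.
#' @param bandwidth passed to [kde_contours()].
#' @return object of class `strategy_surface`: `scores`
#'   (`surface_scores`), `kde` (`kde_hdr`), `per_member` variance
#'   fractions.
#' @export
strategy_surface <- function(ensemble, quantiles = c(0.5, 0.95, 0.99),
                             bandwidth = "normal-scale") {
  members <- if (inherits(ensemble, "imputed_ensemble")) ensemble$members
  else list(ensemble)
  fits <- lapply(members, pca_surface)
  avg <- average_over_imputations(fits)
  kde <- kde_contours(avg$scores[, 1:2, drop = FALSE],
                      quantiles = quantiles, bandwidth = bandwidth)
  structure(list(scores = avg, kde = kde,
                 per_member = do.call(rbind, lapply(fits, `[[`,
                                                    "variance_fraction"))),
            class = "strategy_surface")
}

#' @export
print.strategy_surface <- function(x, ...) {
  vf <- x$scores$variance_fraction
  cat("Ecological strategy surface (", nrow(x$scores$scores),
      " species, ", x$scores$n_members, " imputed dataset(s))\n", sep = "")
  cat(sprintf("  PC1 %.1f%% + PC2 %.1f%% = %.1f%% of trait variation\n",
              100 * vf[1], 100 * vf[2], 100 * (vf[1] + vf[2])))
  cat("  HDR contours at:",
      paste(x$kde$levels$quantile, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.strategy_surface <- function(x, pch = ".", col = "grey40", ...) {
  s <- x$scores$scores
  plot(s[, 1], s[, 2], pch = pch, col = col, xlab = "PC1", ylab = "PC2",
       ...)
  cc <- x$kde$contours
  for (q in unique(cc$quantile)) {
    for (pc in unique(cc$piece[cc$quantile == q])) {
      v <- cc[cc$quantile == q & cc$piece == pc, ]
      lines(v$x, v$y, col = "firebrick")
    }
  }
  invisible(x)
}
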