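# Chained-equation multiple imputation of missing trait values,
# informed by the other traits and by phylogenetic eigenvectors, plus
# the complete-case filter used for sensitivity analyses.

#' Phylogenetic eigenvectors from a patristic distance matrix
#'
#' Double-centers `-1/2 d^2` and eigendecomposes it (the classical
#' scaling of the patristic distances); the top `k` eigenvectors by
#' eigenvalue are returned as covariates encoding phylogenetic
#' relatedness. Ties are broken by the fixed eigendecomposition order,
#' and each column's sign is set so its largest-magnitude element is
#' positive, making the selection deterministic.
#'
#' @param d symmetric patristic distance matrix with species labels.
#' @param k number of eigenvectors (default 10; must be < number of
#'   species).
#' @return species x k matrix of class `phylo_eigenvectors` with
#'   attribute `eigenvalues`. Columns are zero-mean and mutually
#'   orthogonal.
#' @export
phylo_eigenvectors <- function(d, k = 10) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) stop("k must be smaller than the number of species")
  A <- -0.5 * d^2
  B <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  e <- eigen(B, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(rownames(d), paste0("pev", seq_len(k)))
  structure(V, eigenvalues = e$values[seq_len(k)],
            class = c("phylo_eigenvectors", "matrix", "array"))
}

#' Chained-equation multiple imputation with predictive mean matching
#'
#' Fills missing cells of a traits matrix (transformed, pre-z scale) by
#' iterated univariate regressions: each incomplete trait is regressed
#' on the other traits plus any extra predictors (typically
#' phylogenetic eigenvectors), regression coefficients and the residual
#' variance are drawn from their posterior (normal / scaled
#' inverse-chi-squared under a flat prior), and each missing cell is
#' replaced by the observed value of one of the `donors` nearest
#' observed cases by predicted value (predictive mean matching, so
#' imputations are always actually-observed values). `m` independent
#' chains give `m` completed datasets.
#'
#' @param x numeric matrix (species x traits) with `NA`s, on the
#'   transformed scale.
#' @param predictors optional numeric matrix of complete extra
#'   predictors with the same rows as `x` (rows of all-`NA` are allowed
#'   and are replaced by the column means, i.e. carry no signal).
#' @param m number of completed datasets (chains).
#' @param n_iter sweeps of the chained equations per chain.
#' @param donors donor-pool size for predictive mean matching.
#' @param ridge ridge penalty applied if a design matrix is singular.
#' @param seed integer seed (each chain uses its own substream).
#' @return object of class `imputed_ensemble`: `members` (list of `m`
#'   completed matrices), `miss` (logical matrix of imputed cells),
#'   `diagnostics` (chain x iteration x trait array of imputed-cell
#'   means).
#' @export
chained_impute <- function(x, predictors = NULL, m = 25, n_iter = 10,
                           donors = 5, ridge = 1e-5, seed = 1) {
  x <- as.matrix(x)
  miss <- is.na(x)
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("t", seq_len(p))
  n_obs <- colSums(!miss)
  if (any(n_obs < 30))
    stop("every trait needs at least 30 observed values (",
         paste(colnames(x)[n_obs < 30], collapse = ", "), " below)")
  if (!is.null(predictors)) {
    predictors <- as.matrix(predictors)
    stopifnot(nrow(predictors) == nrow(x))
    for (j in seq_len(ncol(predictors))) {
      nas <- is.na(predictors[, j])
      if (any(nas))
        predictors[nas, j] <- mean(predictors[!nas, j])
    }
  }
  incomplete <- which(colSums(miss) > 0)
  members <- vector("list", m)
  diagnostics <- array(NA_real_, c(m, n_iter, length(incomplete)),
                       dimnames = list(NULL, NULL, colnames(x)[incomplete]))
  for (chain in seq_len(m)) {
    members[[chain]] <- with_seed(substream_seed(seed, "impute-chain", chain), {
      xc <- x
      for (j in incomplete) { # init from observed margins
        xc[miss[, j], j] <- sample(x[!miss[, j], j], sum(miss[, j]),
                                   replace = TRUE)
      }
      for (it in seq_len(n_iter)) {
        for (j in incomplete) {
          X <- cbind(1, xc[, -j, drop = FALSE], predictors)
          yo <- x[!miss[, j], j]
          Xo <- X[!miss[, j], , drop = FALSE]
          Xm <- X[miss[, j], , drop = FALSE]
          fit <- pmm_draw(Xo, yo, Xm, donors = donors, ridge = ridge)
          xc[miss[, j], j] <- fit
          diagnostics[chain, it, colnames(x)[j]] <-
            mean(xc[miss[, j], j])
        }
      }
      xc
    })
  }
  structure(list(members = members, miss = miss,
                 diagnostics = diagnostics),
            class = "imputed_ensemble")
}

# One PMM step: Bayesian draw of (beta, sigma2) under a flat prior,
# predict missing rows with the drawn beta and observed rows with the
# posterior mean, then sample each imputation from the `donors` nearest
# observed values by predicted value.
pmm_draw <- function(Xo, yo, Xm, donors = 5, ridge = 1e-5) {
  p <- ncol(Xo)
  XtX <- crossprod(Xo)
  Xty <- crossprod(Xo, yo)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R)) {
    warning("singular design matrix; applying ridge penalty")
    R <- chol(XtX + diag(ridge * mean(diag(XtX)), p))
  }
  beta_hat <- backsolve(R, forwardsolve(t(R), Xty))
  res <- yo - Xo %*% beta_hat
  df <- max(length(yo) - p, 1)
  sigma2 <- sum(res^2) / rchisq(1, df)
  beta_star <- beta_hat + backsolve(R, rnorm(p)) * sqrt(sigma2)
  pred_obs <- as.numeric(Xo %*% beta_hat)
  pred_mis <- as.numeric(Xm %*% beta_star)
  nmis <- length(pred_mis)
  out <- numeric(nmis)
  ord <- order(pred_obs)
  po <- pred_obs[ord]; yo_ord <- yo[ord]
  k <- min(donors, length(yo))
  for (i in seq_len(nmis)) {
    # donor pool: k observed cases nearest in predicted value
    pos <- findInterval(pred_mis[i], po)
    lo <- max(1, pos - k); hi <- min(length(po), pos + k)
    win <- lo:hi
    d <- abs(po[win] - pred_mis[i])
    pool <- win[order(d)][seq_len(k)]
    out[i] <- yo_ord[pool[sample.int(length(pool), 1)]]
  }
  out
}

#' Impute a trait table into an ensemble of standardized matrices
#'
#' Orchestrates imputation for an analysis set: builds the transformed
#' five-trait matrix (including the derived diet axis), imputes mammals
#' and birds separately (each class with the eigenvectors of its own
#' tree, when supplied), recombines the classes, and re-standardizes
#' each completed dataset over all species so every member is a
#' complete `standardized_traits` matrix in shared global SD units.
#'
#' @param table a [trait_table()].
#' @param diet a [diet_axis()] result (its scores cover diet-complete
#'   species; the remaining species' diet is imputed on the axis scale).
#' @param trees optional named list `list(mammal =, bird =)` of
#'   `ape::phylo` trees or patristic distance matrices.
#' @param k number of phylogenetic eigenvectors per class.
#' @param m,n_iter,donors,seed passed to [chained_impute()].
#' @return object of class `imputed_ensemble` whose `members` are
#'   `standardized_traits` matrices (complete, z-scored over the full
#'   species set).
#' @export
impute_traits <- function(table, diet, trees = NULL, k = 10, m = 25,
                          n_iter = 10, donors = 5, seed = 1) {
  st <- transform_standardize(table, diet)
  tf <- transformed_scale(st)
  miss <- is.na(tf)
  if (!any(miss)) {
    members <- replicate(m, st, simplify = FALSE)
    return(structure(list(members = members, miss = miss,
                          diagnostics = NULL),
                     class = "imputed_ensemble"))
  }
  classes <- split(seq_len(nrow(table)), table$taxon_class)
  completed <- replicate(m, tf, simplify = FALSE)
  for (cl in names(classes)) {
    idx <- classes[[cl]]
    ids <- table$species_id[idx]
    pev <- NULL
    if (!is.null(trees) && !is.null(trees[[cl]])) {
      d <- trees[[cl]]
      if (inherits(d, "phylo")) d <- patristic_distances(d, species = ids)
      kk <- min(k, nrow(d) - 1)
      ev <- phylo_eigenvectors(d, k = kk)
      pev <- matrix(NA_real_, length(idx), kk,
                    dimnames = list(ids, colnames(ev)))
      common <- intersect(ids, rownames(ev))
      pev[common, ] <- ev[common, ]
      if (length(common) < length(ids))
        message(length(ids) - length(common), " ", cl,
                " species absent from the tree; their eigenvector ",
                "rows carry no signal")
    }
    if (!any(miss[idx, ])) next
    ens <- chained_impute(tf[idx, , drop = FALSE], predictors = pev,
                          m = m, n_iter = n_iter, donors = donors,
                          seed = substream_seed(seed, paste0("impute-", cl)))
    for (chain in seq_len(m)) completed[[chain]][idx, ] <- ens$members[[chain]]
  }
  members <- lapply(completed, standardize_transformed, template = st)
  structure(list(members = members, miss = miss, diagnostics = NULL),
            class = "imputed_ensemble")
}

#' Keep only species with all five traits observed
#'
#' The data-deletion (complete-case) filter used for sensitivity
#' comparisons with the imputed analysis.
#'
#' @param table a [trait_table()].
#' @return the filtered `trait_table`.
#' @export
complete_cases <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  keep <- !is.na(table$body_mass) & !is.na(table$litter_clutch_size) &
    !is.na(table$habitat_breadth) & !is.na(table$generation_length) &
    !is.na(table[[diet_categories()[1]]])
  if (!any(keep)) stop("no species with complete traits")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  out
}
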