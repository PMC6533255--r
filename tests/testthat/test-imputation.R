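test_that("phylogenetic eigenvector 1 separates a two-clade tree", {
  # two balanced clades joined by a long stem
  nwk <- "((A:1,B:1,C:1,D:1):10,(E:1,F:1,G:1,H:1):10);"
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines(nwk, path)
  d <- read_tree(path)
  ev <- phylo_eigenvectors(d, k = 3)
  s <- sign(ev[, 1])
  expect_true(all(s[c("A", "B", "C", "D")] == s["A"]))
  expect_true(all(s[c("E", "F", "G", "H")] == -s["A"]))
  # columns zero-mean and orthogonal
  expect_equal(unname(colMeans(ev)), rep(0, 3), tolerance = 1e-8)
  expect_equal(max(abs(crossprod(ev) - diag(diag(crossprod(ev))))), 0,
               tolerance = 1e-8)
})

test_that("star-tree eigenvalues are the closed-form constant spectrum", {
  n <- 6; b <- 2
  d <- matrix(2 * b, n, n); diag(d) <- 0
  rownames(d) <- colnames(d) <- letters[1:n]
  ev <- phylo_eigenvectors(d, k = n - 1)
  # centered -1/2 d^2 of a constant off-diagonal matrix has n-1 equal
  # nonzero eigenvalues 2b^2 and one zero
  expect_equal(unname(attr(ev, "eigenvalues")), rep(2 * b^2, n - 1),
               tolerance = 1e-9)
  # deterministic under the tie-break rule
  ev2 <- phylo_eigenvectors(d, k = n - 1)
  expect_identical(ev, ev2)
  expect_error(phylo_eigenvectors(d, k = n), "smaller")
})

test_that("complete matrices pass through imputation unchanged", {
  tt <- synth_table(120, 103)
  ax <- diet_axis(tt)
  st <- transform_standardize(tt, ax)
  ens <- impute_traits(tt, ax, m = 3, seed = 1)
  expect_length(ens$members, 3)
  for (memb in ens$members)
    expect_equal(unclass(memb), unclass(st), tolerance = 1e-12)
})

test_that("PMM imputations come from the observed donor set and leave observed cells alone", {
  set.seed(31)
  n <- 200
  x <- matrix(rnorm(3 * n), n, 3) %*% chol(matrix(c(1, .6, .3,
                                                    .6, 1, .4,
                                                    .3, .4, 1), 3))
  colnames(x) <- c("a", "b", "c")
  xm <- x
  xm[sample(n, 50), "b"] <- NA
  ens <- chained_impute(xm, m = 4, n_iter = 5, seed = 2)
  obs_b <- x[!is.na(xm[, "b"]), "b"]
  for (memb in ens$members) {
    expect_true(all(memb[is.na(xm[, "b"]), "b"] %in% obs_b))
    expect_equal(memb[!is.na(xm[, "b"]), "b"], x[!is.na(xm[, "b"]), "b"])
  }
  # imputations vary across the ensemble (no degenerate collapse)
  imp <- sapply(ens$members, function(m) m[is.na(xm[, "b"]), "b"])
  expect_gt(mean(apply(imp, 1, var) > 0), 0.5)
})

test_that("chained PMM beats column-mean fill on correlated traits", {
  # small-scale version of the recovery experiment (the acceptance
  # suite runs the full 50-seed comparison)
  set.seed(32)
  R <- matrix(0.6, 5, 5); diag(R) <- 1
  L <- chol(R)
  wins <- 0
  for (s in 1:10) {
    n <- 250
    tf <- matrix(rnorm(n * 5), n, 5) %*% L
    colnames(tf) <- paste0("t", 1:5)
    mask <- matrix(runif(length(tf)) < 0.25, nrow(tf), ncol(tf))
    mask[, 1] <- FALSE # mirrors the always-complete body mass column
    tfm <- tf; tfm[mask] <- NA
    ens <- chained_impute(tfm, m = 15, n_iter = 5, seed = s)
    avg <- Reduce(`+`, ens$members) / length(ens$members)
    rmse_pmm <- sqrt(mean((avg[mask] - tf[mask])^2))
    fill <- tfm
    for (j in 1:ncol(fill)) fill[is.na(fill[, j]), j] <-
        mean(fill[, j], na.rm = TRUE)
    rmse_mean <- sqrt(mean((fill[mask] - tf[mask])^2))
    wins <- wins + (rmse_pmm < rmse_mean)
  }
  expect_gte(wins, 9)
})

test_that("phylogenetic signal in the predictors is used", {
  # trait = clade effect + noise; eigenvectors should sharpen recovery
  set.seed(33)
  n <- 120
  tr <- generate_tree(n, seed = 5)
  d <- patristic_distances(tr)
  ev <- phylo_eigenvectors(d, k = 10)
  clade_signal <- ev[, 1] * 4
  x <- cbind(t1 = rnorm(n), t2 = clade_signal + rnorm(n, sd = 0.5))
  rownames(x) <- rownames(ev)
  mask <- sample(n, 40)
  xm <- x; xm[mask, "t2"] <- NA
  with_ev <- chained_impute(xm, predictors = ev, m = 5, n_iter = 5,
                            seed = 6)
  without <- chained_impute(xm, m = 5, n_iter = 5, seed = 6)
  rmse <- function(e) {
    avg <- Reduce(`+`, e$members) / length(e$members)
    sqrt(mean((avg[mask, "t2"] - x[mask, "t2"])^2))
  }
  expect_lt(rmse(with_ev), rmse(without))
})

test_that("pooled correlations beat complete-case at heavy missingness", {
  set.seed(34)
  tt <- generate_trait_table(synth_spec(n_species = 600), seed = 35)
  ax <- diet_axis(tt)
  st <- transform_standardize(tt, ax)
  tf <- strategyspace:::transformed_scale(st)
  truthR <- cor(tf)
  mask <- matrix(runif(length(tf)) < 0.4, nrow(tf), ncol(tf))
  mask[, 1] <- FALSE
  tfm <- tf; tfm[mask] <- NA
  ens <- chained_impute(tfm, m = 10, n_iter = 5, seed = 36)
  pooledR <- Reduce(`+`, lapply(ens$members, cor)) / 10
  cc <- tfm[rowSums(is.na(tfm)) == 0, ]
  err <- function(R) sqrt(sum((R - truthR)^2))
  expect_lt(err(pooledR), err(cor(cc)))
})

test_that("complete_cases drops exactly the species with gaps", {
  tt <- tiny_table()
  expect_equal(nrow(complete_cases(tt)), 3)
  df <- as.data.frame(tt)
  df$habitat_breadth[2] <- NA
  tt2 <- trait_table(df)
  cc <- complete_cases(tt2)
  expect_equal(cc$species_id, c("sp_a", "sp_c"))
  df$body_mass <- NA_real_
  expect_error(complete_cases(trait_table(df)), "no species")
})

test_that("traits with too few observations are refused", {
  x <- matrix(rnorm(100), 50, 2)
  x[1:25, 2] <- NA
  expect_error(chained_impute(x, m = 1), "at least 30 observed")
})
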