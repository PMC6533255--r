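test_that("Gower distance follows the range-normalized mean rule", {
  # identical rows
  x <- rbind(a = c(50, 50, 0), b = c(50, 50, 0), c = c(0, 100, 0))
  d <- gower_distance(x)
  expect_equal(d["a", "b"], 0)
  # two species, opposite pure diets: two informative variables, each
  # normalized difference 1, zero-range variables excluded
  y <- rbind(c(100, rep(0, 9)), c(rep(0, 9), 100))
  expect_equal(gower_distance(y)[1, 2], 1)
  expect_error(gower_distance(rbind(c(1, 2), c(1, 2))), "zero range")
})

test_that("Gower matches the brute-force double loop to 1e-12", {
  set.seed(21)
  for (rep in 1:3) {
    x <- matrix(rgamma(5 * 10, 1), 5, 10)
    x <- 100 * x / rowSums(x)
    expect_equal(unname(gower_distance(x)), gower_bruteforce(x),
                 tolerance = 1e-12)
  }
})

test_that("PCoA embeds collinear points on a single axis", {
  pts <- c(0, 1, 2, 3)
  d <- as.matrix(dist(pts))
  ord <- pcoa(d, n_axes = 1)
  # axis-1 scores reproduce the spacing up to sign and centering
  s <- ord$scores[, 1]
  if (cor(s, pts) < 0) s <- -s
  expect_equal(unname(diff(s)), diff(pts), tolerance = 1e-9)
  expect_lt(max(abs(ord$eigenvalues[-1])), 1e-9)
})

test_that("PCoA of an all-zero distance matrix is degenerate", {
  d <- matrix(0, 4, 4)
  expect_warning(ord <- pcoa(d, n_axes = 2), "positive eigenvalues")
  expect_equal(max(abs(ord$eigenvalues)), 0, tolerance = 1e-12)
  expect_true(all(ord$scores == 0))
})

test_that("PCoA exactly re-embeds Euclidean configurations", {
  set.seed(22)
  pts <- matrix(rnorm(20 * 2), 20, 2)
  d <- as.matrix(dist(pts))
  ord <- pcoa(d, n_axes = 2)
  expect_equal(as.matrix(dist(ord$scores)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  # agrees with classical scaling as implemented independently in stats
  cs <- cmdscale(d, k = 2, eig = TRUE)
  expect_equal(abs(ord$scores), abs(cs$points), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(ord$eigenvalues[1:2], cs$eig[1:2], tolerance = 1e-8)
})

test_that("PCoA scores are invariant to species ordering", {
  set.seed(23)
  x <- matrix(rgamma(8 * 10, 1), 8, 10)
  rownames(x) <- letters[1:8]
  d <- gower_distance(x)
  perm <- sample(8)
  o1 <- pcoa(d, 1)
  o2 <- pcoa(d[perm, perm], 1)
  s1 <- o1$scores[rownames(o2$scores), 1]
  expect_lt(min(max(abs(s1 - o2$scores[, 1])),
                max(abs(s1 + o2$scores[, 1]))), 1e-9)
  expect_equal(o1$eigenvalues, o2$eigenvalues, tolerance = 1e-9)
})

test_that("the diet axis separates two discrete guilds by sign", {
  # two pure Dirichlet guilds (the generator's continuous blend is
  # fuzzier near the boundary; the separation property is about the
  # guild extremes)
  set.seed(24)
  gp <- strategyspace:::guild_profiles()
  n <- 500
  diet <- t(vapply(seq_len(n), function(i) {
    p <- if (i <= n / 2) gp$invertivore else gp$herbivore
    g <- rgamma(10, shape = 12 * p)
    100 * g / sum(g)
  }, numeric(10)))
  colnames(diet) <- diet_categories()
  df <- data.frame(species_id = sprintf("s%03d", 1:n),
                   taxon_class = "bird", body_mass = 10,
                   litter_clutch_size = 2, habitat_breadth = 2,
                   generation_length = 2, stringsAsFactors = FALSE)
  tt <- trait_table(cbind(df, as.data.frame(diet),
                          iucn_category = "LC"))
  ax <- diet_axis(tt)
  g <- rep(c("invertivore", "herbivore"), each = n / 2)
  pred <- ifelse(ax$scores[, 1] > 0, "invertivore", "herbivore")
  expect_gt(mean(pred == g), 0.95)
  # orientation: invertebrates load positively
  expect_gt(ax$loadings["diet_inv", 1], 0)
  # herbivore-side categories load negatively
  expect_lt(ax$loadings["diet_planto", 1], 0)
  expect_lt(ax$loadings["diet_fruit", 1], 0)
  expect_lt(ax$loadings["diet_seed", 1], 0)
  expect_true(all(ax$variance_fraction >= 0 & ax$variance_fraction <= 1))
})

test_that("identical diet rows get identical scores", {
  tt <- tiny_table()
  df <- as.data.frame(tt)
  df2 <- df[c(1, 1, 2, 3), ]
  df2$species_id <- c("d1", "d2", "d3", "d4")
  tt2 <- trait_table(df2)
  ax <- diet_axis(tt2)
  expect_equal(ax$scores["d1", 1], ax$scores["d2", 1], tolerance = 1e-10)
})

test_that("transforms and z-scoring follow the stated conventions", {
  tt <- tiny_table()
  ax <- diet_axis(tt)
  st <- transform_standardize(tt, ax)
  tfm <- attr(st, "transforms")
  # 1000 g -> 3.0 and habitat 9 -> 3.0 before z-scoring
  expect_equal(st["sp_a", "log10_body_mass"] *
                 tfm$log10_body_mass$sd + tfm$log10_body_mass$mean, 3)
  expect_equal(st["sp_a", "sqrt_habitat_breadth"] *
                 tfm$sqrt_habitat_breadth$sd +
                 tfm$sqrt_habitat_breadth$mean, 3)
  expect_equal(unname(colMeans(st)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(st, 2, sd)), rep(1, 5), tolerance = 1e-10)
})

test_that("standardization is invertible on observed cells", {
  tt <- synth_table(200, 102)
  ax <- diet_axis(tt)
  st <- transform_standardize(tt, ax)
  raw <- invert_standardize(st)
  expect_equal(raw[, "body_mass"], setNames(tt$body_mass, tt$species_id),
               tolerance = 1e-9)
  expect_equal(raw[, "habitat_breadth"],
               setNames(as.numeric(tt$habitat_breadth), tt$species_id),
               tolerance = 1e-9)
  expect_equal(raw[, "generation_length"],
               setNames(tt$generation_length, tt$species_id),
               tolerance = 1e-9)
})

test_that("missing cells propagate and nonpositive values are caught", {
  tt <- tiny_table()
  ax <- diet_axis(tt)
  df <- as.data.frame(tt)
  df$generation_length[2] <- NA
  tt2 <- trait_table(df)
  st <- transform_standardize(tt2, ax)
  expect_true(is.na(st["sp_b", "log10_generation_length"]))
  expect_equal(sum(is.na(st)), 1)
  df$generation_length[2] <- 3
  tt3 <- trait_table(df)
  tt3$body_mass[1] <- 0 # bypass constructor check to hit the transform
  expect_error(transform_standardize(tt3, ax), "sp_a")
})
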