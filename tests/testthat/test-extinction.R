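risk_table <- function(n = 600, seed = 71) {
  generate_trait_table(
    synth_spec(n_species = n,
               risk_trait_coupling = list(trait = "body_mass",
                                          strength = 1.5)),
    seed = seed)
}

std_of <- function(tt) {
  transform_standardize(tt, diet_axis(tt))
}

test_that("expected losses follow round-half-away arithmetic", {
  expect_equal(unname(expected_losses(c(CR = 100))[1]), 100) # 99.9 -> 100
  expect_equal(unname(expected_losses(c(VU = 1250))[1]), 125)
  expect_equal(unname(expected_losses(c(NT = 1250))[1]), 13) # 12.5 up
  l <- expected_losses(c(CR = 0, EN = 0, VU = 0, NT = 0, LC = 0))
  expect_equal(attr(l, "total"), 0L)
  z <- expected_losses(c(CR = 50, LC = 1000),
                       probabilities = c(CR = 0, LC = 0))
  expect_true(all(z == 0))
  expect_error(expected_losses(c(XX = 5)), "XX")
})

test_that("the paper-scale category counts reproduce the printed losses", {
  counts <- c(CR = 380 / 0.999, EN = 576 / 0.667, VU = 1250, NT = 1300,
              LC = 11690)
  counts <- setNames(as.integer(round(counts)), names(counts))
  l <- expected_losses(counts)
  expect_equal(unname(l[c("CR", "EN", "VU", "NT", "LC")]),
               c(380L, 576L, 125L, 13L, 1L))
  expect_equal(attr(l, "total"), 1095L)
})

test_that("fixed-count scenarios lose the exact per-category totals", {
  tt <- risk_table(400, 72)
  counts <- table(ifelse(tt$iucn_category == "DD", "LC",
                         tt$iucn_category))
  expected <- expected_losses(
    setNames(as.integer(counts), names(counts)),
    c(default_extinction_probs()))
  for (s in 1:5) {
    surv <- simulate_scenario(tt, "projected", seed = s)
    expect_equal(nrow(tt) - nrow(surv), attr(expected, "total"))
  }
  # identical seed, identical survivors
  s1 <- simulate_scenario(tt, "projected", seed = 42)
  s2 <- simulate_scenario(tt, "projected", seed = 42)
  expect_identical(s1$species_id, s2$species_id)
})

test_that("randomized loss matches the projected total and is trait-blind", {
  tt <- risk_table(1200, 73)
  surv_p <- simulate_scenario(tt, "projected", seed = 1)
  surv_r <- simulate_scenario(tt, "randomized", seed = 1)
  expect_equal(nrow(surv_p), nrow(surv_r))
  # over many replicates the lost fraction of large-bodied species
  # matches their share of the pool under randomized loss
  big <- tt$species_id[log10(tt$body_mass) >
                         median(log10(tt$body_mass))]
  lost_frac <- vapply(1:400, function(s) {
    lost <- attr(simulate_scenario(tt, "randomized", seed = s), "lost")
    mean(lost %in% big)
  }, numeric(1))
  expect_lt(abs(mean(lost_frac) - 0.5), 0.02)
})

test_that("DD handling modes act before the simulation", {
  tt <- risk_table(500, 74)
  n_dd <- sum(tt$iucn_category == "DD")
  expect_gt(n_dd, 0)
  surv_drop <- simulate_scenario(tt, "projected", dd_mode = "drop",
                                 seed = 2)
  expect_false(any(surv_drop$iucn_category == "DD"))
  # fixed_0.277 loses ~27.7% of DD species on top of the as_LC losses
  surv_lc <- simulate_scenario(tt, "projected", dd_mode = "as_LC",
                               seed = 2)
  surv_277 <- simulate_scenario(tt, "projected", dd_mode = "fixed_0.277",
                                seed = 2)
  extra <- nrow(surv_lc) - nrow(surv_277)
  expect_equal(extra,
               as.integer(round(0.277 * n_dd) - round(0.0001 * n_dd)),
               tolerance = 1)
})

test_that("scenario ensembles are reproducible with fixed totals", {
  tt <- risk_table(300, 75)
  z <- std_of(tt)
  ens <- scenario_ensemble(z, tt$iucn_category, "projected",
                           n_replicates = 9,
                           hv_args = list(samples_per_point = 30),
                           seed = 3)
  expect_length(ens$volumes, 9)
  expect_true(all(ens$n_lost == ens$n_lost[1]))
  ens2 <- scenario_ensemble(z, tt$iucn_category, "projected",
                            n_replicates = 9,
                            hv_args = list(samples_per_point = 30),
                            seed = 3)
  expect_identical(ens$volumes, ens2$volumes)
})

test_that("zero extinction probabilities reproduce the observed volume", {
  tt <- risk_table(250, 76)
  z <- std_of(tt)
  p0 <- c(CR = 0, EN = 0, VU = 0, NT = 0, LC = 0)
  ens <- scenario_ensemble(z, tt$iucn_category, "projected",
                           n_replicates = 3, probabilities = p0,
                           hv_args = list(samples_per_point = 300),
                           seed = 4)
  hv_obs <- hypervolume(unclass(z), samples_per_point = 300, seed = 99)
  # survivors = full set every replicate; only MC noise remains
  expect_true(all(ens$n_lost == 0))
  expect_lt(max(abs(ens$volumes - hv_obs$volume)) / hv_obs$volume, 0.08)
})

test_that("mass-coupled risk contracts the projected space more", {
  tt <- risk_table(800, 77)
  z <- std_of(tt)
  proj <- scenario_ensemble(z, tt$iucn_category, "projected",
                            n_replicates = 19,
                            hv_args = list(samples_per_point = 30),
                            seed = 5)
  rand <- scenario_ensemble(z, tt$iucn_category, "randomized",
                            n_replicates = 19,
                            hv_args = list(samples_per_point = 30),
                            seed = 5)
  expect_lt(mean(proj$volumes), mean(rand$volumes))
})

test_that("KS comparison matches the brute-force ECDF oracle", {
  tt <- risk_table(300, 78)
  z <- std_of(tt)
  mk <- function(mode, seed) scenario_ensemble(
    z, tt$iucn_category, mode, n_replicates = 11,
    hv_args = list(samples_per_point = 30), seed = seed)
  a <- mk("projected", 6); b <- mk("randomized", 7)
  cmp <- compare_scenarios(a, b, observed_volume = 100)
  expect_equal(cmp$D, ks_bruteforce(a$volumes, b$volumes),
               tolerance = 1e-12)
  expect_true(all(cmp$effect_sizes$lower <= cmp$effect_sizes$upper))
  # identical ensembles: D = 0; disjoint supports: D = 1
  expect_equal(compare_scenarios(a, a, 100)$D, 0)
  bb <- b; bb$volumes <- b$volumes + diff(range(a$volumes)) + 1e6
  expect_equal(compare_scenarios(a, bb, 100)$D, 1)
  short <- a; short$volumes <- a$volumes[1:3]
  expect_error(compare_scenarios(short, b, 100), "at least 5")
})

test_that("trait shift tests report rank p-values and directions", {
  tt <- risk_table(800, 79)
  z <- std_of(tt)
  proj <- scenario_ensemble(z, tt$iucn_category, "projected",
                            n_replicates = 19,
                            hv_args = list(samples_per_point = 30),
                            seed = 8)
  obs <- summarize_traits(invert_standardize(z))
  sh <- trait_shift_test(obs$means[["body_mass"]], proj, "body_mass")
  expect_equal(sh$direction, "decrease")
  # with risk coupled to mass the shift is detected at the rank floor
  expect_equal(sh$p_value, 1 / 20)
  expect_true(sh$range[1] <= sh$scenario_mean &&
                sh$scenario_mean <= sh$range[2])
  # constant summaries are undefined
  degen <- proj
  degen$trait_means[, "diet"] <- 1
  expect_error(trait_shift_test(1, degen, "diet"), "constant")
})

test_that("the shift test is calibrated under exchangeability", {
  # The rank-based p is uniform when the tested summary is
  # exchangeable with the replicate summaries: here the "observed"
  # value is an independent draw of the same trait-blind scenario, so
  # rejecting at alpha should happen at about rate alpha. (Against
  # the full-pool mean the projected-scenario test is conditional on
  # which species carry the threatened categories and is not expected
  # to be uniform; see the methods vignette.)
  rejections <- 0
  n_runs <- 60
  for (i in seq_len(n_runs)) {
    tt <- generate_trait_table(synth_spec(n_species = 150), seed = 900 + i)
    draws <- vapply(1:20, function(r) {
      s <- simulate_scenario(tt, "randomized", seed = 1000 * i + r)
      mean(log10(s$body_mass))
    }, numeric(1))
    ens <- structure(list(
      trait_means = matrix(10^draws[1:19],
                           dimnames = list(NULL, "body_mass")),
      trait_medians = matrix(10^draws[1:19],
                             dimnames = list(NULL, "body_mass")),
      mode = "randomized", n_replicates = 19),
      class = "scenario_ensemble")
    p <- trait_shift_test(10^draws[20], ens, "body_mass")$p_value
    rejections <- rejections + (p <= 0.05)
  }
  expect_gte(rejections / n_runs, 0.01)
  expect_lte(rejections / n_runs, 0.2)
})

test_that("geometric-mean trait summaries back-transform correctly", {
  x <- cbind(body_mass = c(10, 1000), litter_clutch_size = c(2, 8),
             habitat_breadth = c(1, 9), generation_length = c(1, 4),
             diet = c(-1, 1))
  s <- summarize_traits(x)
  expect_equal(unname(s$means["body_mass"]), 100) # geometric mean
  expect_equal(unname(s$means["litter_clutch_size"]), 4)
  expect_equal(unname(s$means["habitat_breadth"]), 4) # ((1+3)/2)^2
  expect_equal(unname(s$means["generation_length"]), 2)
  expect_equal(unname(s$means["diet"]), 0)
  expect_equal(unname(s$medians["body_mass"]), 505)
  expect_error(summarize_traits(x[0, ]), "empty")
  one <- x[1, , drop = FALSE]; one[] <- c(1000, 2, 4, 3, 0)
  expect_equal(unname(summarize_traits(one)$means["body_mass"]), 1000)
})

test_that("median mass reduction is computed from medians", {
  tt <- risk_table(500, 80)
  z <- std_of(tt)
  proj <- scenario_ensemble(z, tt$iucn_category, "projected",
                            n_replicates = 9,
                            hv_args = list(samples_per_point = 30),
                            seed = 9)
  obs_med <- summarize_traits(invert_standardize(z))$medians[["body_mass"]]
  red <- 100 * (1 - proj$trait_medians[, "body_mass"] / obs_med)
  # with mass-coupled risk the median shrinks in every replicate
  expect_true(all(red > 0))
})
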