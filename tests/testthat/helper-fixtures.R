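# Shared fixtures, built in code.

# A tiny hand-written, fully observed trait table.
tiny_table <- function() {
  df <- data.frame(
    species_id = c("sp_a", "sp_b", "sp_c"),
    taxon_class = c("mammal", "mammal", "bird"),
    body_mass = c(1000, 20, 150),
    litter_clutch_size = c(1, 4.5, 2),
    habitat_breadth = c(9, 3, 1),
    generation_length = c(8, 1.5, 3),
    stringsAsFactors = FALSE
  )
  diet <- rbind(c(0, 0, 0, 0, 0, 0, 50, 0, 20, 30),
                c(80, 0, 5, 0, 0, 0, 10, 0, 5, 0),
                c(30, 0, 0, 0, 0, 0, 40, 10, 10, 10))
  colnames(diet) <- diet_categories()
  df <- cbind(df, as.data.frame(diet))
  df$iucn_category <- c("EN", "LC", "VU")
  trait_table(df)
}

# A mid-sized complete synthetic community, cached per session.
synth_table <- local({
  cache <- NULL
  function(n = 500, seed = 101, coupling = NULL) {
    key <- paste(n, seed, is.null(coupling))
    if (!is.null(cache) && cache$key == key) return(cache$tt)
    tt <- generate_trait_table(
      synth_spec(n_species = n, risk_trait_coupling = coupling), seed)
    cache <<- list(key = key, tt = tt)
    tt
  }
})

# Fast hypervolume settings for tests where MC precision is secondary.
fast_hv <- function(x, seed = 1, ...) {
  hypervolume(x, samples_per_point = 50, max_samples = 2e5, seed = seed,
              ...)
}

# Brute-force double-loop Gower oracle (independent of the
# implementation: plain loops, explicit zero-range exclusion).
gower_bruteforce <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  rng <- numeric(p)
  for (j in seq_len(p)) rng[j] <- max(x[, j]) - min(x[, j])
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    s <- 0; m <- 0
    for (j in seq_len(p)) {
      if (rng[j] > 0) {
        s <- s + abs(x[i, j] - x[k, j]) / rng[j]
        m <- m + 1
      }
    }
    d[i, k] <- s / m
  }
  d
}

# Brute-force two-sample KS statistic: sup over pooled points of the
# empirical CDF difference.
ks_bruteforce <- function(a, b) {
  g <- sort(unique(c(a, b)))
  Fa <- vapply(g, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(g, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}
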