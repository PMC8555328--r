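# Shared fixtures. The default simulated population is expensive enough to
# be worth computing once per test run; helpers are loaded before all test
# files, so the cache is shared across them.
sim_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(sim_cache$default)) {
    sim_cache$default <- simulate_population(sim_config())
  }
  sim_cache$default
}

# A lighter population for property loops where the full default would be
# wastefully slow.
small_sim <- function(seed = 1) {
  simulate_population(sim_config(
    n_linkage_groups = 2, lg_length = 60, n_markers_per_lg = 40,
    n_founders = 6, n_generations = 4, n_samples = 150, seed = seed
  ))
}

# Build a genotype matrix from a plain matrix, filling in dimnames.
gm <- function(calls, sample_ids = NULL, marker_ids = NULL) {
  m <- as.matrix(calls)
  rownames(m) <- sample_ids %||% sprintf("s%02d", seq_len(nrow(m)))
  colnames(m) <- marker_ids %||% sprintf("m%02d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

toy_map <- function() {
  tibble::tibble(
    marker_id = c("a1", "a2", "a3", "a4"),
    linkage_group = c("LG1", "LG1", "LG2", "LG2"),
    position = c(0, 10, 5, 20)
  )
}

# Independent textbook Pearson-squared oracle: raw-sum formula, no shared
# code with the package implementation.
oracle_r2 <- function(x, y, min_complete = 10) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < max(2, min_complete)) return(NA_real_)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  num <- (n * sum(x * y) - sum(x) * sum(y))^2
  den <- (n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2)
  if (den <= 0) return(NA_real_)
  num / den
}
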