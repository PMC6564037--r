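# Shared fixtures.  Small design: 4 categories x 3 exemplars x 4 runs
# (48 trials) keeps unit tests fast; the full default design is built once
# and cached for the acceptance checks.

small_config <- function(seed = 1L, ...) {
  mtl_config(n_units_per_region = c(AM = 6L, HC = 6L),
             n_categories = 4L, n_exemplars = 3L, n_runs = 4L,
             rng_seed = seed, ...)
}

# trial-support filter scaled to the 4-run design (strict > 2 of 4)
small_screening <- function(...) {
  screening_config(min_trials_with_spike = 2L, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

default_tuned_session <- function() {
  cached("tuned_session", generate_population(mtl_config(rng_seed = 20L)))
}

default_tuned_screening <- function() {
  cached("tuned_screening", screen_session(default_tuned_session()))
}

# Hand-built population matrix (stimulus level unless stated otherwise).
make_pop <- function(values, category_id, level = "stimulus",
                     stimulus_id = NULL) {
  n <- nrow(values)
  if (is.null(stimulus_id)) stimulus_id <- sprintf("s%02d", seq_len(n))
  rownames(values) <- stimulus_id
  labels <- data.frame(stimulus_id = stimulus_id, category_id = category_id,
                       stringsAsFactors = FALSE)
  if (level == "trial")
    labels <- data.frame(trial_index = seq_len(n) - 1L,
                         stimulus_id = stimulus_id,
                         category_id = category_id,
                         stringsAsFactors = FALSE)
  structure(list(values = values, row_labels = labels,
                 units = data.frame(unit_id = colnames(values) %||%
                                      sprintf("u%02d", seq_len(ncol(values)))),
                 level = level, dropped_units = character(0)),
            class = "population_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent exact one-sided rank-sum oracle: enumerates every subset of
# size n1 by bitmask (different code path from the package's combn-based
# enumeration).
ranksum_oracle_greater <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  obs <- sum(r[seq_len(n1)])
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    if (sum(bits) != n1) next
    total <- total + 1L
    if (sum(r[bits == 1L]) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / total
}

# Independent exact partition-shuffle oracle for the within/between tests.
partition_oracle <- function(values, within, alternative = "less") {
  r <- rank(values)
  k <- sum(within); n <- length(values)
  obs <- sum(r[within])
  stat <- combn(n, k, function(idx) sum(r[idx]))
  if (alternative == "less") mean(stat <= obs + 1e-9)
  else mean(stat >= obs - 1e-9)
}

# Two-sided Fisher oracle: sums hypergeometric point probabilities not
# exceeding that of the observed table.
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  kk <- max(0, k - n):min(k, m)
  pk <- dhyper(kk, m, n, k)
  p0 <- dhyper(a, m, n, k)
  sum(pk[pk <= p0 * (1 + 1e-7)])
}
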