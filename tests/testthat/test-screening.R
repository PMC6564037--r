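test_that("response bins are 19 overlapping half-open 100 ms windows", {
  b <- response_bins()
  expect_equal(nrow(b), 19L)
  expect_true(all(abs(b[, 2] - b[, 1] - 0.1) < 1e-12))
  expect_true(all(b >= 0 & b <= 1))
  # two interleaved families stepping by 50 ms
  expect_equal(b[, 1], seq(0, 0.9, by = 0.05))
})

test_that("bin counts match direct enumeration with half-open bins", {
  spikes <- c(10.050, 10.120)
  bc <- bin_spike_counts(spikes, onsets = 10)
  b <- response_bins()
  expected <- vapply(seq_len(nrow(b)),
                     function(j) sum(spikes - 10 >= b[j, 1] &
                                     spikes - 10 < b[j, 2]), numeric(1))
  expect_equal(as.vector(bc$bins), expected)
  expect_equal(sum(expected[abs(b[, 1] - 0.00) < 1e-9]), 1)  # [0,100)
  expect_equal(sum(expected[abs(b[, 1] - 0.05) < 1e-9]), 2)  # [50,150)
  expect_equal(sum(expected[abs(b[, 1] - 0.10) < 1e-9]), 1)  # [100,200)
  expect_equal(bc$baseline, 0)
  expect_equal(bc$resp_spikes, 2)
  # spike exactly at a boundary belongs to the bin starting there
  bc2 <- bin_spike_counts(c(10.1), onsets = 10)
  expect_equal(bc2$bins[1, 1], 0)
  expect_equal(bc2$bins[1, 3], 1)
  # no spikes near onset: everything zero
  bc3 <- bin_spike_counts(c(100, 200), onsets = 10)
  expect_true(all(bc3$bins == 0) && bc3$baseline == 0)
  expect_error(bin_spike_counts(spikes, onsets = 0.2), "baseline")
  expect_error(bin_spike_counts(c(3, 1, 2), onsets = 10), "ascending")
})

test_that("rank-sum p-values match exhaustive enumeration and wilcox.test", {
  set.seed(31)
  for (rep in 1:8) {
    x <- rpois(sample(3:5, 1), 2)
    y <- rpois(sample(3:5, 1), 1)
    got <- ranksum_test(x, y)$p.value
    expect_equal(got, ranksum_oracle_greater(x, y))
  }
  # large-sample path agrees with the tie-corrected normal approximation
  x <- rpois(10, 2); y <- rpois(200, 1)
  expect_equal(ranksum_test(x, y)$p.value,
               suppressWarnings(wilcox.test(x, y, alternative = "greater",
                                            exact = FALSE,
                                            correct = TRUE)$p.value))
  expect_error(ranksum_test(numeric(0), y), "empty")
})

test_that("Simes rule rejects iff some sorted p-value clears its threshold", {
  alpha <- 0.001
  p <- rep(0.9, 19); expect_false(mtlpop:::simes_reject(p, alpha))
  p[7] <- 4e-5  # < alpha/19
  expect_true(mtlpop:::simes_reject(p, alpha))
  # boundary: p_(i) exactly at i*alpha/m counts as rejection
  p_exact <- (1:19) * alpha / 19
  expect_true(mtlpop:::simes_reject(p_exact, alpha))
  # all p-values just above their thresholds: no rejection
  expect_false(mtlpop:::simes_reject((1:19) * alpha / 19 + 1e-9, alpha))
  # brute-force cross-check against direct sorted comparison on random input
  set.seed(8)
  for (rep in 1:20) {
    pr <- runif(19, 0, 0.01)
    expect_equal(mtlpop:::simes_reject(pr, alpha),
                 any(sort(pr) <= (1:19) * alpha / 19))
  }
})

test_that("trial-support and rate filters gate the response decision", {
  base <- rep(0L, 40)
  strong <- matrix(5L, nrow = 10, ncol = 19)  # clear increase in every bin
  # all filters pass
  r <- binwise_response_test(strong, base, resp_spikes = rep(5L, 10),
                             resp_rate_hz = rep(5, 10))
  expect_true(r$simes && r$response)
  # spikes in exactly 5 of 10 trials: strict > 5 fails
  r5 <- binwise_response_test(strong, base,
                              resp_spikes = rep(c(5L, 0L), each = 5),
                              resp_rate_hz = rep(5, 10))
  expect_false(r5$trials_ok)
  expect_false(r5$response)
  # mean rate at exactly 2 Hz fails the strict > 2 Hz filter
  r2 <- binwise_response_test(strong, base, resp_spikes = rep(5L, 10),
                              resp_rate_hz = rep(2, 10))
  expect_false(r2$rate_ok && r2$response)
  # response distribution identical to baseline: no response
  same <- matrix(rep(c(0L, 1L), 5), nrow = 10, ncol = 19)
  rn <- binwise_response_test(same, rep(c(0L, 1L), 20),
                              resp_spikes = rep(1L, 10),
                              resp_rate_hz = rep(3, 10))
  expect_false(rn$simes)
  expect_false(rn$response)
})

test_that("raising all response counts never destroys a response", {
  set.seed(77)
  base <- rpois(100, 1)
  for (rep in 1:10) {
    resp <- matrix(rpois(10 * 19, 2), 10, 19)
    r0 <- binwise_response_test(resp, base, resp_spikes = rep(6L, 10),
                                resp_rate_hz = rep(3, 10))
    r1 <- binwise_response_test(resp + 2L, base, resp_spikes = rep(6L, 10),
                                resp_rate_hz = rep(5, 10))
    if (r0$response) expect_true(r1$response)
  }
})

test_that("screening a session flags tuned units and spares silent ones", {
  cfg <- small_config(seed = 15, supra_gain = 15)
  ses <- generate_population(cfg)
  # silence one unit entirely
  ses$spikes[[1]] <- numeric(0)
  scr <- screen_session(ses, small_screening())
  expect_false(any(scr$response[1, ]))
  # flags, where present, should sit on high-gain stimuli
  if (any(scr$response)) {
    idx <- which(scr$response, arr.ind = TRUE)
    gains <- ses$ground_truth$gains[idx]
    expect_gt(mean(gains), 1)
  }
  sel <- selectivity_distribution(scr)
  expect_equal(sel$n_responses, rowSums(scr$response))
  expect_equal(sel$n_responses[1], 0)
})

test_that("response probabilities follow the per-category convention", {
  # hand-built screening: 1 unit, 5 categories x 10 stimuli, 2 flags in cat A
  stimuli <- data.frame(
    stimulus_id = sprintf("s%02d", 1:50),
    category_id = rep(LETTERS[1:5], each = 10),
    stringsAsFactors = FALSE)
  resp <- matrix(FALSE, 1, 50)
  resp[1, 1:2] <- TRUE
  scr <- structure(list(response = resp,
                        units = data.frame(unit_id = "u1", region = "AM",
                                           stringsAsFactors = FALSE),
                        stimuli = stimuli),
                   class = "mtl_screening")
  expect_warning(rp <- response_probability(scr, n_subsamples = 50),
                 "subsample size reduced")
  expect_equal(rp$rp[rp$category_id == "A"], 20)  # 2 / (1 unit x 10 stimuli)
  expect_equal(rp$rp[rp$category_id == "B"], 0)
  expect_equal(rp$ci_low[rp$category_id == "B"], 0)
  expect_equal(rp$ci_high[rp$category_id == "B"], 0)
  # total-stimulus normalisation: 2 / (1 x 50)
  expect_warning(rp_tot <- response_probability(scr, n_subsamples = 10,
                                                normalisation = "total"))
  expect_equal(rp_tot$rp[rp_tot$category_id == "A"], 4)
})

test_that("category preference test matches hypergeometric enumeration", {
  # 10 units, 5 categories x 10 stimuli; 8/100 responses in category A,
  # 10/400 elsewhere: the spec's 2x2 table [[8,92],[10,390]]
  stimuli <- data.frame(
    stimulus_id = sprintf("s%02d", 1:50),
    category_id = rep(LETTERS[1:5], each = 10),
    stringsAsFactors = FALSE)
  resp <- matrix(FALSE, 10, 50)
  resp[1, 1:8] <- TRUE                      # 8 responses in category A
  resp[2, 11:20] <- TRUE                    # 10 responses in category B
  scr <- structure(list(response = resp,
                        units = data.frame(unit_id = sprintf("u%02d", 1:10),
                                           region = rep("AM", 10),
                                           stringsAsFactors = FALSE),
                        stimuli = stimuli),
                   class = "mtl_screening")
  out <- category_preference_test(scr)
  rowA <- out[out$category_id == "A", ]
  expect_equal(unlist(rowA[c("responses_in", "n_in", "responses_out",
                             "n_out")], use.names = FALSE),
               c(8, 100, 10, 400))
  expect_equal(rowA$fisher_p,
               fisher_oracle(matrix(c(8, 92, 10, 390), 2, byrow = TRUE)))
  expect_equal(rowA$alpha_corrected, 0.05 / 5)
  # equal response rates in and out of category give p = 1
  resp_eq <- matrix(FALSE, 10, 50)
  resp_eq[1, seq(1, 50, by = 10)] <- TRUE   # one response per category
  scr$response <- resp_eq
  out_eq <- category_preference_test(scr)
  expect_true(all(out_eq$fisher_p == 1))
})

test_that("elevated food-category gain in amygdala units is recovered", {
  w <- setNames(rep(1, 10), rownames(default_semantic_geometry()))
  w[c("manmade_food", "fruit")] <- 8
  cfg <- mtl_config(n_units_per_region = c(AM = 60L), rng_seed = 21L,
                    region_profiles = list(AM = list(category_weights = w)))
  scr <- screen_session(generate_population(cfg))
  out <- category_preference_test(scr)
  food <- out[out$category_id %in% c("manmade_food", "fruit"), ]
  expect_true(any(food$significant))
})
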