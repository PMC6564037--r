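# Minimal hand-built session: spike counts placed to give known baseline
# and response rates.
session_from_counts <- function(base_counts, resp_counts, ioi = 10) {
  n_tr <- length(base_counts)
  onsets <- seq(1, by = ioi, length.out = n_tr)
  spikes <- numeric(0)
  for (t in seq_len(n_tr)) {
    if (base_counts[t] > 0)
      spikes <- c(spikes, onsets[t] - 0.5 +
                    seq_len(base_counts[t]) * 0.4 / base_counts[t])
    if (resp_counts[t] > 0)
      spikes <- c(spikes, onsets[t] +
                    seq_len(resp_counts[t]) * 0.9 / resp_counts[t])
  }
  stimuli <- data.frame(stimulus_id = c("sA", "sB"),
                        category_id = c("A", "B"),
                        stringsAsFactors = FALSE)
  structure(list(
    units = data.frame(unit_id = "u1", region = "AM", unit_class = "single",
                       stringsAsFactors = FALSE),
    spikes = list(u1 = sort(spikes)),
    events = data.frame(trial_index = seq_len(n_tr) - 1L,
                        run_index = rep(0L, n_tr),
                        stimulus_id = rep(c("sA", "sB"), length.out = n_tr),
                        category_id = rep(c("A", "B"), length.out = n_tr),
                        onset_s = onsets, stringsAsFactors = FALSE),
    stimuli = stimuli, ground_truth = NULL, config = NULL,
    duration_s = max(onsets) + 5), class = "mtl_session")
}

test_that("z-scores equal (rate - baseline mean) / baseline sd", {
  base <- c(1L, 1L, 3L, 3L)   # baseline rates 2,2,6,6 Hz
  resp <- c(5L, 2L, 5L, 2L)   # response rates 5,2,5,2 Hz
  ses <- session_from_counts(base, resp)
  pm <- zscore_responses(ses, "trial")
  mu <- mean(c(2, 2, 6, 6)); sg <- sd(c(2, 2, 6, 6))
  expect_equal(as.vector(pm$values), (resp - mu) / sg)
  # stimulus level averages trials of a stimulus before z-scoring
  pm_s <- zscore_responses(ses, "stimulus")
  expect_equal(as.vector(pm_s$values),
               (c(mean(c(5, 5)), mean(c(2, 2))) - mu) / sg)
  expect_equal(rownames(pm_s$values), c("sA", "sB"))
})

test_that("zero-baseline-SD units are dropped (or floored on request)", {
  ses <- session_from_counts(c(2L, 2L, 2L, 2L), c(3L, 1L, 3L, 1L))
  expect_message(pm <- zscore_responses(ses, "trial"), "zero baseline SD")
  expect_equal(ncol(pm$values), 0L)
  expect_equal(pm$dropped_units, "u1")
  pm_f <- zscore_responses(ses, "trial", sigma_zero = "floor")
  expect_equal(ncol(pm_f$values), 1L)
  expect_true(all(is.finite(pm_f$values)))
})

test_that("a homogeneous Poisson unit has near-zero mean z-score", {
  ses <- generate_null_population(small_config(seed = 30))
  pm <- zscore_responses(ses, "stimulus")
  expect_lt(abs(mean(pm$values)), 0.4)
})

test_that("dissimilarity is 1 - Pearson R with hand-checked values", {
  x <- rbind(a = c(1, 0, 1), b = c(0, 1, 1), c = c(1, 0, 1))
  d <- dissimilarity(x)
  expect_equal(d$values["a", "b"], 1.5)  # R = -0.5
  expect_equal(d$values["a", "c"], 0)    # identical rows
  anti <- rbind(u = c(1, 2, 3), v = c(-2, -4, -6))
  expect_equal(dissimilarity(anti)$values["u", "v"], 2)  # R = -1
})

test_that("dissimilarity matrices are symmetric, bounded and affine-invariant", {
  set.seed(12)
  for (rep in 1:5) {
    x <- matrix(rnorm(8 * 6), 8, 6)
    d <- dissimilarity(x)$values
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 2 + 1e-12))
    # common positive affine transform of the z-scores leaves 1-R unchanged
    d2 <- dissimilarity(1.7 * x + 0.3)$values
    expect_equal(d, d2)
  }
})

test_that("constant rows get distance 1 with a message", {
  x <- rbind(a = c(1, 2, 3), b = c(2, 2, 2), c = c(3, 2, 1))
  expect_message(d <- dissimilarity(x), "constant row")
  expect_equal(d$values["a", "b"], 1)
  expect_equal(d$values["b", "c"], 1)
  expect_equal(d$values["a", "c"], 2)
  expect_equal(diag(d$values), c(a = 0, b = 0, c = 0))
})

test_that("UPGMA merge heights match hand computation and blocks separate", {
  d3 <- matrix(c(0, 1, 4,
                 1, 0, 5,
                 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- cluster_dendrogram(d3)
  expect_equal(tree$height, c(1, 4.5))  # average linkage: mean(4, 5)
  # two well-separated blocks: the root split recovers them
  blocks <- matrix(3, 6, 6) + diag(6) * -3
  blocks[1:3, 1:3] <- 0.1; blocks[4:6, 4:6] <- 0.1; diag(blocks) <- 0
  dimnames(blocks) <- list(letters[1:6], letters[1:6])
  tb <- cluster_dendrogram(blocks)
  expect_false(is.unsorted(tb$height))
  grp <- cutree(tb, k = 2)
  expect_equal(length(unique(grp[1:3])), 1L)
  expect_equal(length(unique(grp[4:6])), 1L)
  expect_false(grp[1] == grp[4])
})

test_that("leaf contiguity counts unbroken category blocks", {
  blocks <- matrix(3, 6, 6)
  blocks[1:3, 1:3] <- 0.1; blocks[4:6, 4:6] <- 0.1; diag(blocks) <- 0
  tree <- cluster_dendrogram(blocks)
  expect_equal(leaf_category_contiguity(tree, rep(c("x", "y"), each = 3)), 2L)
  # interleaved labels on the same tree cannot all be contiguous
  expect_lte(leaf_category_contiguity(tree, rep(c("x", "y"), 3)), 1L)
  # a single category is trivially contiguous
  expect_equal(leaf_category_contiguity(tree, rep("x", 6)), 1L)
})

test_that("classical MDS recovers planar configurations up to rigid motion", {
  # two points at distance d embed at distance d
  d2 <- matrix(c(0, 3, 3, 0), 2, 2)
  xy <- mds_embed(d2, dims = 2)
  expect_equal(dim(xy), c(2L, 2L))
  expect_equal(as.numeric(dist(xy)), 3)
  # known planar points: Procrustes error ~ 0
  set.seed(4)
  pts <- matrix(rnorm(14), 7, 2)
  rec <- mds_embed(as.matrix(dist(pts)), dims = 2)
  pr <- vegan::procrustes(pts, rec)
  expect_lt(pr$ss / sum(scale(pts, scale = FALSE)^2), 1e-10)
  # zero matrix: coincident points
  expect_true(all(mds_embed(matrix(0, 4, 4), dims = 2) == 0))
})

test_that("partition permutation p matches exhaustive enumeration", {
  set.seed(9)
  # 5 items -> 10 pairs; enumeration over all C(10, n_within) partitions
  vals <- matrix(rnorm(25), 5, 5); vals <- vals + t(vals); diag(vals) <- 0
  labs <- c("a", "a", "b", "b", "b")
  exact <- within_between_permutation(vals, labs, exact = TRUE)
  ut <- upper.tri(vals)
  same <- outer(labs, labs, "==")
  expect_equal(exact$p.value, partition_oracle(vals[ut], same[ut], "less"))
  # Monte Carlo approximates the exact answer
  mc <- within_between_permutation(vals, labs, n_perm = 20000, seed = 2)
  expect_lt(abs(mc$p.value - exact$p.value), 0.02)
})

test_that("perfect within/between separation gives the minimal p", {
  # all within distances below all between distances
  v <- matrix(2, 6, 6)
  v[1:3, 1:3] <- 0.1; v[4:6, 4:6] <- 0.1; diag(v) <- 0
  labs <- rep(c("a", "b"), each = 3)
  r <- within_between_permutation(v, labs, n_perm = 1000, seed = 1)
  expect_lte(r$p.value, 1 / 1000)
  expect_error(within_between_permutation(v, rep("a", 6)), "degenerate")
})

test_that("permutation p is roughly uniform under the null", {
  set.seed(44)
  ps <- replicate(200, {
    v <- matrix(rnorm(36), 6, 6); v <- v + t(v); diag(v) <- 0
    within_between_permutation(v, rep(c("a", "b"), each = 3),
                               exact = TRUE)$p.value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(mean(ps <= 0.25), 0.1)
  expect_lt(mean(ps <= 0.25), 0.45)
})

test_that("the stricter stimulus-label null agrees directionally", {
  # 2 x 5 items: 126 distinct label partitions, so the attainable minimum
  # p under label shuffling is 1/126
  v <- matrix(2, 10, 10)
  v[1:5, 1:5] <- 0.1; v[6:10, 6:10] <- 0.1; diag(v) <- 0
  labs <- rep(c("a", "b"), each = 5)
  r <- within_between_permutation(v, labs, n_perm = 2000, seed = 5,
                                  null = "stimulus-label")
  expect_lte(r$p.value, 0.02)
  # null data: unremarkable under the label-shuffling null
  set.seed(46)
  vn <- matrix(rnorm(100), 10, 10); vn <- vn + t(vn); diag(vn) <- 0
  rn <- within_between_permutation(vn, labs, n_perm = 2000, seed = 6,
                                   null = "stimulus-label")
  expect_gt(rn$p.value, 0.001)
})
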