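#' Configuration of the neuronal response screening criterion
#'
#' A unit x stimulus pair is flagged as a response when (i) at least one of 19
#' one-sided rank-sum tests (spike counts in overlapping 100 ms response bins
#' against baseline counts of all session trials) survives the Simes
#' procedure at `alpha`, (ii) more than `min_trials_with_spike` trials of the
#' stimulus contain at least one spike in the response window, and (iii) the
#' mean firing rate across the stimulus' trials in the response window
#' exceeds `min_response_rate_hz`.  Only firing-rate increases are
#' considered.
#'
#' @param alpha Significance level of the Simes-corrected binwise test.
#' @param min_trials_with_spike Trial-support filter: required number of
#'   trials with >= 1 response-window spike, strict inequality (default 5,
#'   i.e. more than 5 of the 10 trials).
#' @param min_response_rate_hz Rate filter on the mean response-window rate.
#' @param baseline_window,response_window Windows in seconds relative to
#'   stimulus onset; baseline default (-0.5, 0), response default (0, 1).
#' @param bin_width_s,bin_step_s Width and step of the two overlapping
#'   response-bin families.
#' @return Object of class `screening_config`.
#' @export
screening_config <- function(alpha = 0.001,
                             min_trials_with_spike = 5L,
                             min_response_rate_hz = 2,
                             baseline_window = c(-0.5, 0),
                             response_window = c(0, 1),
                             bin_width_s = 0.1,
                             bin_step_s = 0.1) {
  stopifnot(alpha > 0, alpha < 1,
            baseline_window[1] < baseline_window[2],
            response_window[1] < response_window[2])
  cfg <- list(alpha = alpha,
              min_trials_with_spike = as.integer(min_trials_with_spike),
              min_response_rate_hz = min_response_rate_hz,
              baseline_window = baseline_window,
              response_window = response_window,
              bin_width_s = bin_width_s,
              bin_step_s = bin_step_s)
  class(cfg) <- "screening_config"
  cfg
}

#' Response-bin windows of the screening test
#'
#' Two interleaved families of 100 ms windows covering the 0--1000 ms
#' response period: edges at 0, 100, ..., 1000 ms (10 bins) and at 50, 150,
#' ..., 950 ms (9 bins), i.e. 19 overlapping bins in total.  All bins are
#' half-open `[start, end)`.
#'
#' @param config A [screening_config()].
#' @return Two-column matrix (start_s, end_s) with one row per bin.
#' @export
response_bins <- function(config = screening_config()) {
  w <- config$bin_width_s
  s <- config$bin_step_s
  r <- config$response_window
  starts <- sort(c(seq(r[1], r[2] - w, by = s),
                   seq(r[1] + w / 2, r[2] - 3 * w / 2, by = s)))
  cbind(start_s = starts, end_s = starts + w)
}

#' Per-trial spike counts in response bins and baseline window
#'
#' @param spike_times Ascending spike times in seconds.
#' @param onsets Stimulus onset times in seconds.
#' @param config A [screening_config()].
#' @param duration_s Optional recording span; onsets whose analysis windows
#'   fall outside `[0, duration_s]` raise an error.
#' @return List with `bins` (trials x 19 count matrix), `baseline` (counts in
#'   the baseline window), `resp_spikes` (counts in the full response
#'   window) and `resp_rate_hz` (per-trial response-window rate).
#' @export
bin_spike_counts <- function(spike_times, onsets, config = screening_config(),
                             duration_s = NULL) {
  if (is.unsorted(spike_times)) stop("spike_times must be ascending")
  bw <- config$baseline_window
  if (any(onsets + bw[1] < 0))
    stop("onset before recording start: baseline window undefined")
  bins <- response_bins(config)
  if (!is.null(duration_s) && any(onsets + max(bins[, 2]) > duration_s))
    stop("onset too close to recording end: response bins undefined")
  n_trials <- length(onsets)
  # count in [a, b) = #(spikes < b) - #(spikes < a)
  nlt <- function(x) findInterval(x, spike_times, left.open = TRUE)
  edges_lo <- outer(onsets, c(bins[, 1], bw[1], config$response_window[1]), "+")
  edges_hi <- outer(onsets, c(bins[, 2], bw[2], config$response_window[2]), "+")
  cnt <- matrix(nlt(as.vector(edges_hi)) - nlt(as.vector(edges_lo)),
                nrow = n_trials)
  nb <- nrow(bins)
  list(bins = cnt[, seq_len(nb), drop = FALSE],
       baseline = cnt[, nb + 1L],
       resp_spikes = cnt[, nb + 2L],
       resp_rate_hz = cnt[, nb + 2L] / diff(config$response_window))
}

#' One-sided Mann-Whitney rank-sum test for increased counts
#'
#' Tests whether values in `x` are stochastically larger than values in `y`
#' using the rank-sum statistic with mid-ranks for ties.  Small samples
#' (combined n <= 20 and at most `exact_limit` subsets) are evaluated by
#' exhaustive permutation enumeration conditional on the observed values;
#' larger samples use the normal approximation with tie correction and
#' continuity correction.
#'
#' @param x,y Numeric vectors (response and reference counts).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   `NULL` chooses by size.
#' @param exact_limit Maximum number of subsets enumerated.
#' @return List with `statistic` (rank-sum of `x`) and `p.value` for the
#'   alternative "x greater".
#' @export
ranksum_test <- function(x, y, exact = NULL, exact_limit = 2e5) {
  if (!length(x) || !length(y)) stop("empty input to rank-sum test")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  use_exact <- if (is.null(exact)) n <= 20 && choose(n, n1) <= exact_limit
               else exact
  if (use_exact) {
    if (choose(n, n1) > exact_limit)
      stop("exact enumeration infeasible for this sample size")
    subsets <- utils::combn(n, n1)
    wdist <- colSums(matrix(r[subsets], nrow = n1))
    p <- mean(wdist >= w - 1e-9)
  } else {
    ties <- table(r)
    mu <- n1 * (n + 1) / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    p <- if (sigma2 <= 0) 1
         else stats::pnorm((w - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  list(statistic = w, p.value = p)
}

# Batch rank-sum p-values (alternative: greater) of each column of the
# response count matrix against a fixed baseline count vector, using
# tabulated count frequencies; the baseline tabulation is shared across
# columns.  Counts must be non-negative integers.
ranksum_batch_greater <- function(resp, baseline) {
  n1 <- nrow(resp); n2 <- length(baseline); n <- n1 + n2
  if (!n1 || !n2) stop("empty input to rank-sum test")
  if (n <= 20 && choose(n, n1) <= 2e5)
    return(apply(resp, 2, function(x) ranksum_test(x, baseline)$p.value))
  m1 <- max(resp, baseline) + 1L
  fb <- tabulate(baseline + 1L, m1)
  fr <- vapply(seq_len(ncol(resp)),
               function(j) tabulate(resp[, j] + 1L, m1), integer(m1))
  fr <- matrix(fr, nrow = m1)
  f <- fr + fb
  cum <- matrix(apply(f, 2, cumsum), nrow = m1)
  midrank <- rbind(0, cum[-m1, , drop = FALSE]) + (f + 1) / 2
  w <- colSums(fr * midrank)
  mu <- n1 * (n + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - colSums(f^3 - f) / (n * (n - 1)))
  p <- rep(1, ncol(resp))
  ok <- sigma2 > 0
  p[ok] <- stats::pnorm((w[ok] - mu - 0.5) / sqrt(sigma2[ok]),
                        lower.tail = FALSE)
  p
}

# Simes global test: reject if any sorted p-value p_(i) <= i * alpha / m.
simes_reject <- function(p, alpha) {
  m <- length(p)
  any(sort(p) <= seq_len(m) * alpha / m)
}

#' Binwise response test for one unit x stimulus pair
#'
#' @param resp_counts Trials x 19 matrix of response-bin spike counts.
#' @param baseline_counts Baseline-window counts of all session trials.
#' @param resp_spikes Per-trial spike counts in the full response window
#'   (trial-support filter).
#' @param resp_rate_hz Per-trial response-window rates (rate filter uses
#'   their mean).
#' @param config A [screening_config()].
#' @return List with the 19 one-sided p-values, the Simes decision and the
#'   two filter outcomes, plus the final `response` flag.
#' @export
binwise_response_test <- function(resp_counts, baseline_counts, resp_spikes,
                                  resp_rate_hz, config = screening_config()) {
  p <- ranksum_batch_greater(resp_counts, baseline_counts)
  simes <- simes_reject(p, config$alpha)
  trials_ok <- sum(resp_spikes > 0) > config$min_trials_with_spike
  rate_ok <- mean(resp_rate_hz) > config$min_response_rate_hz
  list(p = p, simes = simes, trials_ok = trials_ok, rate_ok = rate_ok,
       response = simes && trials_ok && rate_ok)
}

#' Screen every unit x stimulus pair of a session
#'
#' Applies the binwise rank-sum criterion to all units and stimuli of a
#' session.  Baseline counts are pooled across all session trials per unit,
#' as in the screening criterion's definition.
#'
#' @param session An `mtl_session`.
#' @param config A [screening_config()].
#' @return Object of class `mtl_screening`: `decisions` (data.frame with one
#'   row per unit x stimulus: p_min, n_trials_with_spike, mean_rate_hz,
#'   response), `pvalues` (units x stimuli x 19 array), plus unit/stimulus
#'   tables and the config.
#' @export
screen_session <- function(session, config = screening_config()) {
  units <- session$units
  stimuli <- session$stimuli
  onsets <- session$events$onset_s
  stim_trials <- split(seq_along(onsets),
                       factor(session$events$stimulus_id,
                              levels = stimuli$stimulus_id))
  n_u <- nrow(units); n_s <- nrow(stimuli)
  nb <- nrow(response_bins(config))
  pvals <- array(NA_real_, c(n_u, n_s, nb),
                 dimnames = list(units$unit_id, stimuli$stimulus_id, NULL))
  resp <- matrix(FALSE, n_u, n_s)
  nspk <- matrix(0L, n_u, n_s)
  mrate <- matrix(0, n_u, n_s)
  for (i in seq_len(n_u)) {
    bc <- bin_spike_counts(session$spikes[[i]], onsets, config,
                           duration_s = session$duration_s)
    for (s in seq_len(n_s)) {
      tr <- stim_trials[[s]]
      res <- binwise_response_test(bc$bins[tr, , drop = FALSE], bc$baseline,
                                   bc$resp_spikes[tr], bc$resp_rate_hz[tr],
                                   config)
      pvals[i, s, ] <- res$p
      resp[i, s] <- res$response
      nspk[i, s] <- sum(bc$resp_spikes[tr] > 0)
      mrate[i, s] <- mean(bc$resp_rate_hz[tr])
    }
  }
  decisions <- data.frame(
    unit_id = rep(units$unit_id, times = n_s),
    region = rep(units$region, times = n_s),
    stimulus_id = rep(stimuli$stimulus_id, each = n_u),
    category_id = rep(stimuli$category_id, each = n_u),
    p_min = as.vector(apply(pvals, c(1, 2), min)),
    n_trials_with_spike = as.vector(nspk),
    mean_rate_hz = as.vector(mrate),
    response = as.vector(resp),
    stringsAsFactors = FALSE)
  structure(list(decisions = decisions, pvalues = pvals,
                 response = resp, units = units, stimuli = stimuli,
                 config = config),
            class = "mtl_screening")
}

#' @export
print.mtl_screening <- function(x, ...) {
  n_resp_units <- sum(rowSums(x$response) > 0)
  cat("mtl_screening:", nrow(x$units), "units x", nrow(x$stimuli),
      "stimuli;", sum(x$response), "responses in", n_resp_units,
      "responsive units\n")
  invisible(x)
}

#' Distribution of response selectivity across units
#'
#' Counts the number of response-eliciting stimuli per unit (selectivity) and
#' its cumulative distribution per region, as used to compare selectivity
#' profiles across MTL regions.
#'
#' @param screening An `mtl_screening`.
#' @return data.frame with unit_id, region, and n_responses per unit.
#' @export
selectivity_distribution <- function(screening) {
  data.frame(unit_id = screening$units$unit_id,
             region = screening$units$region,
             n_responses = rowSums(screening$response),
             stringsAsFactors = FALSE)
}

#' Response probabilities per region and category with subsampling CIs
#'
#' The response probability (RP) of a region/category cell is the number of
#' flagged unit x stimulus pairs divided by (number of units in the region x
#' number of stimuli), expressed in percent.  By default the per-category
#' stimulus count is used as denominator so that categories are directly
#' comparable; `normalisation = "total"` divides by the full stimulus-set
#' size instead.  Confidence intervals come from repeatedly subsampling units
#' without replacement within each region.
#'
#' @param screening An `mtl_screening`.
#' @param n_subsamples Number of unit subsamples (default 2000).
#' @param subsample_size Units per subsample (default 700); if a region has
#'   fewer units the size is reduced to 80% of the available units with a
#'   warning.
#' @param normalisation "category" (default) or "total".
#' @param conf_level Confidence level of the percentile interval.
#' @return data.frame with region, category_id, n_responses, rp (percent),
#'   ci_low, ci_high.
#' @export
response_probability <- function(screening, n_subsamples = 2000L,
                                 subsample_size = 700L,
                                 normalisation = c("category", "total"),
                                 conf_level = 0.95) {
  normalisation <- match.arg(normalisation)
  stimuli <- screening$stimuli
  cats <- unique(stimuli$category_id)
  n_stim_denom <- if (normalisation == "category")
    as.vector(table(factor(stimuli$category_id, levels = cats)))
  else rep(nrow(stimuli), length(cats))
  cat_of_stim <- factor(stimuli$category_id, levels = cats)
  # per-unit response counts per category
  unit_cat_counts <- t(apply(screening$response, 1, function(fl)
    tapply(fl, cat_of_stim, sum)))
  qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  out <- list()
  for (reg in unique(screening$units$region)) {
    rows <- which(screening$units$region == reg)
    cc <- unit_cat_counts[rows, , drop = FALSE]
    ss <- subsample_size
    if (length(rows) < subsample_size) {
      ss <- max(1L, floor(0.8 * length(rows)))
      warning(sprintf(
        "region %s has %d units (< %d); subsample size reduced to %d",
        reg, length(rows), subsample_size, ss))
    }
    denom <- length(rows) * n_stim_denom
    rp <- 100 * colSums(cc) / denom
    sub_rp <- vapply(seq_len(n_subsamples), function(k) {
      idx <- sample.int(length(rows), ss)
      100 * colSums(cc[idx, , drop = FALSE]) / (ss * n_stim_denom)
    }, numeric(length(cats)))
    ci <- apply(matrix(sub_rp, nrow = length(cats)), 1, stats::quantile,
                probs = qs, names = FALSE)
    out[[reg]] <- data.frame(region = reg, category_id = cats,
                             n_responses = colSums(cc),
                             rp = rp, ci_low = ci[1, ], ci_high = ci[2, ],
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Fisher exact test of category preference per region
#'
#' For every region x category cell, tests whether the rate of flagged
#' responses to that category differs from the rate in all other categories
#' (2 x 2 contingency table of responses vs non-responses, exact
#' hypergeometric test), Bonferroni-corrected across all region x category
#' cells (0.05 / 40 at the default 4 x 10 design).
#'
#' @param screening An `mtl_screening`.
#' @param alpha Family-wise level before Bonferroni division.
#' @return data.frame with region, category_id, responses in/out of category,
#'   fisher_p, alpha_corrected and significance flag.
#' @export
category_preference_test <- function(screening, alpha = 0.05) {
  stimuli <- screening$stimuli
  cats <- unique(stimuli$category_id)
  cat_of_stim <- factor(stimuli$category_id, levels = cats)
  regions <- unique(screening$units$region)
  m <- length(regions) * length(cats)
  out <- list()
  for (reg in regions) {
    rows <- which(screening$units$region == reg)
    fl <- screening$response[rows, , drop = FALSE]
    n_units <- length(rows)
    for (ct in cats) {
      in_cat <- cat_of_stim == ct
      r_in <- sum(fl[, in_cat]); n_in <- n_units * sum(in_cat)
      r_out <- sum(fl[, !in_cat]); n_out <- n_units * sum(!in_cat)
      tab <- matrix(c(r_in, n_in - r_in, r_out, n_out - r_out), 2,
                    byrow = TRUE)
      p <- stats::fisher.test(tab)$p.value
      out[[paste(reg, ct)]] <- data.frame(
        region = reg, category_id = ct,
        responses_in = r_in, n_in = n_in,
        responses_out = r_out, n_out = n_out,
        fisher_p = p, alpha_corrected = alpha / m,
        significant = p < alpha / m,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
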