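#' Generate a synthetic recording session with semantic tuning structure
#'
#' Simulates a full session of the screening paradigm: every stimulus is shown
#' once per run in pseudorandom order (`n_categories * n_exemplars` stimuli,
#' `n_runs` runs; 1,000 trials at the default 100 x 10 design).  Each unit
#' fires as a piecewise-constant-rate Poisson process (generated by thinning):
#' rate = baseline everywhere except the 0--1000 ms response window of each
#' trial, where rate = baseline * (1 + gain(stimulus)).  For tuned units the
#' gain is a graded function of the semantic distance between the stimulus
#' category and the unit's preferred point in the category embedding (a
#' semantic tuning curve), plus an exemplar-specific component shared across
#' trials and, for some units, a few strongly driven (supra-threshold)
#' exemplars of the preferred category.
#'
#' Ground-truth tuning parameters are stored in the returned session for
#' validation purposes only; no analysis function in this package reads them.
#'
#' @param config An [mtl_config()].
#' @return Object of class `mtl_session`: list with `units` (data.frame:
#'   unit_id, region, unit_class), `spikes` (named list of ascending spike
#'   times in seconds), `events` (data.frame: trial_index, run_index,
#'   stimulus_id, category_id, onset_s), `stimuli` (data.frame: stimulus_id,
#'   category_id), `ground_truth` (tuning table + unit x stimulus gain
#'   matrix), `config`, `duration_s`.
#' @export
generate_population <- function(config) {
  validate_config(config)
  set.seed(config$rng_seed)

  stimuli <- stimulus_table(config)
  events <- build_events(config, stimuli)
  duration_s <- max(events$onset_s) + 2

  regions <- rep(names(config$n_units_per_region),
                 times = config$n_units_per_region)
  n_units <- length(regions)
  units <- data.frame(
    unit_id = sprintf("u%04d", seq_len(n_units)),
    region = regions,
    unit_class = ifelse(stats::runif(n_units) < config$p_single_unit,
                        "single", "multi"),
    stringsAsFactors = FALSE)

  tun <- draw_tuning(config, units, stimuli)
  onsets <- events$onset_s
  stim_idx <- match(events$stimulus_id, stimuli$stimulus_id)
  rw <- config$timing$response_window_s

  spikes <- vector("list", n_units)
  names(spikes) <- units$unit_id
  for (i in seq_len(n_units)) {
    spikes[[i]] <- thinned_spike_train(
      baseline_hz = tun$baseline_hz[i],
      gains = tun$gains[i, ],
      onsets = onsets, stim_idx = stim_idx,
      response_window_s = rw, duration_s = duration_s)
  }

  structure(list(units = units,
                 spikes = spikes,
                 events = events,
                 stimuli = stimuli,
                 ground_truth = list(
                   tuning = data.frame(unit_id = units$unit_id,
                                       tuned = tun$tuned,
                                       has_supra = tun$has_supra,
                                       pref_category = tun$pref_category,
                                       baseline_hz = tun$baseline_hz,
                                       stringsAsFactors = FALSE),
                   gains = tun$gains),
                 config = config,
                 duration_s = duration_s),
            class = "mtl_session")
}

#' Generate a null session (no tuning anywhere)
#'
#' Identical to [generate_population()] but with every gain forced to zero:
#' all units are homogeneous Poisson at their baseline rate throughout.  Used
#' to calibrate the false-positive behaviour of the screening criterion and
#' the null behaviour of the permutation tests.
#'
#' @inheritParams generate_population
#' @return An `mtl_session` whose ground-truth gain matrix is all zero.
#' @export
generate_null_population <- function(config) {
  config$p_responsive <- 0
  config$category_gain <- 0
  generate_population(config)
}

stimulus_table <- function(config) {
  cats <- rownames(config$semantic_geometry)
  data.frame(
    stimulus_id = as.vector(t(outer(cats, seq_len(config$n_exemplars),
                                    function(c, e) sprintf("%s_%02d", c, e)))),
    category_id = rep(cats, each = config$n_exemplars),
    stringsAsFactors = FALSE)
}

build_events <- function(config, stimuli) {
  n_stim <- nrow(stimuli)
  tm <- config$timing
  order_idx <- unlist(lapply(seq_len(config$n_runs),
                             function(r) sample.int(n_stim)))
  n_trials <- n_stim * config$n_runs
  gaps <- stats::runif(n_trials, tm$gap_range_s[1], tm$gap_range_s[2])
  # inter-onset interval: response window + post-window + gap + fixation
  ioi <- tm$response_window_s + tm$post_window_s + gaps + tm$fixation_s
  onsets <- 1 + cumsum(c(0, ioi[-n_trials]))
  data.frame(trial_index = seq_len(n_trials) - 1L,
             run_index = rep(seq_len(config$n_runs) - 1L, each = n_stim),
             stimulus_id = stimuli$stimulus_id[order_idx],
             category_id = stimuli$category_id[order_idx],
             onset_s = onsets,
             stringsAsFactors = FALSE)
}

draw_tuning <- function(config, units, stimuli) {
  geom <- config$semantic_geometry
  cats <- rownames(geom)
  n_units <- nrow(units)
  n_stim <- nrow(stimuli)
  stim_cat <- match(stimuli$category_id, cats)

  baseline_hz <- stats::rlnorm(n_units,
                               config$baseline_rate[["meanlog"]],
                               config$baseline_rate[["sdlog"]])
  tuned <- stats::runif(n_units) < config$p_responsive
  pref_category <- rep(NA_character_, n_units)
  has_supra <- rep(FALSE, n_units)
  gains <- matrix(0, n_units, n_stim,
                  dimnames = list(units$unit_id, stimuli$stimulus_id))

  for (i in seq_len(n_units)) {
    prof <- config$region_profiles[[units$region[i]]]
    if (is.null(prof)) prof <- list()
    gain_scale <- prof$gain_scale %||% 1
    n_supra <- prof$n_supra_exemplars %||% config$n_supra_exemplars
    supra_gain <- prof$supra_gain %||% config$supra_gain
    w <- prof$category_weights %||% rep(1, length(cats))

    if (!tuned[i]) next
    pc <- sample.int(length(cats), 1L, prob = w)
    pref_category[i] <- cats[pc]
    pref_pt <- geom[pc, ] + stats::rnorm(2, 0, config$pref_jitter_sd)
    d2 <- colSums((t(geom) - pref_pt)^2)
    g_cat <- config$category_gain * gain_scale *
      exp(-d2 / (2 * config$tuning_width^2))
    g <- g_cat[stim_cat] + stats::rnorm(n_stim, 0, config$exemplar_gain_sd)
    k <- min(stats::rpois(1, n_supra), config$n_exemplars)
    if (k > 0) {
      has_supra[i] <- TRUE
      cand <- which(stim_cat == pc)
      sel <- sample(cand, k)
      g[sel] <- g[sel] + supra_gain
    }
    gains[i, ] <- pmax(g, -0.9)
  }
  list(baseline_hz = baseline_hz, tuned = tuned, has_supra = has_supra,
       pref_category = pref_category, gains = gains)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Piecewise-constant-rate Poisson spike train by thinning a homogeneous
# process at the maximum rate.
thinned_spike_train <- function(baseline_hz, gains, onsets, stim_idx,
                                response_window_s, duration_s) {
  rmax <- baseline_hz * max(1, 1 + max(gains))
  n <- stats::rpois(1, rmax * duration_s)
  t_cand <- sort(stats::runif(n, 0, duration_s))
  if (n == 0) return(numeric(0))
  # locate each candidate relative to trial onsets
  trial <- findInterval(t_cand, onsets)
  in_resp <- trial >= 1 &
    (t_cand - onsets[pmax(trial, 1)]) < response_window_s
  rate <- rep(baseline_hz, n)
  idx <- which(in_resp)
  if (length(idx))
    rate[idx] <- baseline_hz * (1 + gains[stim_idx[trial[idx]]])
  t_cand[stats::runif(n) < rate / rmax]
}

#' @export
print.mtl_session <- function(x, ...) {
  cat("mtl_session:", nrow(x$units), "units (",
      paste(names(table(x$units$region)), table(x$units$region),
            collapse = ", "), "),",
      nrow(x$events), "trials of", nrow(x$stimuli), "stimuli;",
      round(x$duration_s), "s\n")
  invisible(x)
}

#' Generate a labelled synthetic grey-scale image set
#'
#' Builds one smooth random template per category and adds independent pixel
#' noise to obtain the exemplars, so that within- versus between-category
#' pixel similarity is controllable.  Serves as the fixture for the
#' image-similarity control analyses; intensities are on a declared 0--255
#' scale.
#'
#' @param config An [mtl_config()]; supplies category labels, exemplar count
#'   and the seed.
#' @param size Image side length in pixels.
#' @param noise_sd SD of the per-pixel within-category noise (0 makes all
#'   exemplars of a category identical).
#' @return List with `images` (named list of `size x size` matrices),
#'   `labels` (data.frame: image_id, category_id), and `intensity_range`.
#' @export
generate_images <- function(config, size = 32L, noise_sd = 10) {
  set.seed(config$rng_seed)
  cats <- rownames(config$semantic_geometry)
  stimuli <- stimulus_table(config)
  templates <- lapply(cats, function(ct) smooth_template(size))
  names(templates) <- cats
  images <- vector("list", nrow(stimuli))
  names(images) <- stimuli$stimulus_id
  for (i in seq_len(nrow(stimuli))) {
    img <- templates[[stimuli$category_id[i]]]
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(size * size, 0, noise_sd), size, size)
    images[[i]] <- img
  }
  list(images = images,
       labels = data.frame(image_id = stimuli$stimulus_id,
                           category_id = stimuli$category_id,
                           stringsAsFactors = FALSE),
       intensity_range = c(0, 255))
}

# Smooth random field: white noise low-passed by a separable moving average,
# rescaled to mean 128, sd 40 on the 0..255 scale.
smooth_template <- function(size, kernel_width = 9L) {
  z <- matrix(stats::rnorm((size + kernel_width) ^ 2),
              size + kernel_width, size + kernel_width)
  k <- rep(1 / kernel_width, kernel_width)
  z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  z <- t(apply(t(z), 2, function(col) stats::filter(col, k, sides = 2)))
  z <- z[seq_len(size) + (kernel_width %/% 2),
         seq_len(size) + (kernel_width %/% 2)]
  128 + 40 * (z - mean(z)) / stats::sd(z)
}
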