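#' Default semantic geometry for the ten stimulus categories
#'
#' Places the ten superordinate categories in a two-dimensional semantic
#' embedding.  The horizontal axis separates man-made (negative) from natural
#' (positive) objects; the two food categories (man-made food, fruit) sit next
#' to each other across that divide, and the three animal categories (wild
#' animals, birds, insects) form a cluster, mirroring the higher-order
#' structure seen in MTL population activity.  Distances in this embedding
#' drive how strongly a tuned unit's category gain spills over to
#' semantically neighbouring categories.
#'
#' @param n_categories Number of categories.  For 10 (the default design) the
#'   curated embedding is returned; for any other number categories are placed
#'   uniformly on a circle, with the first half labelled man-made and the rest
#'   natural.
#' @return Numeric matrix with one row per category, two columns, rownames =
#'   category ids, and attribute `superordinate` ("manmade"/"natural").
#' @export
default_semantic_geometry <- function(n_categories = 10L) {
  if (n_categories == 10L) {
    coords <- rbind(
      clothes      = c(-1.0,  0.8),
      computer     = c(-1.2,  0.4),
      furniture    = c(-1.1,  0.0),
      instruments  = c(-0.9, -0.4),
      manmade_food = c(-0.4, -1.0),
      fruit        = c( 0.4, -1.0),
      flowers      = c( 0.9, -0.3),
      insects      = c( 1.0,  0.3),
      birds        = c( 1.1,  0.7),
      wild_animals = c( 0.9,  1.0))
    sup <- rep(c("manmade", "natural"), each = 5L)
  } else {
    ang <- 2 * pi * (seq_len(n_categories) - 1L) / n_categories
    coords <- cbind(cos(ang), sin(ang))
    rownames(coords) <- sprintf("cat%02d", seq_len(n_categories))
    sup <- ifelse(seq_len(n_categories) <= ceiling(n_categories / 2),
                  "manmade", "natural")
  }
  colnames(coords) <- c("d1", "d2")
  attr(coords, "superordinate") <- stats::setNames(sup, rownames(coords))
  coords
}

#' Configuration for the synthetic spike-train generator
#'
#' Defines the stimulus design (categories x exemplars x runs), the firing
#' model and the semantic tuning structure used by [generate_population()].
#' Defaults emulate the recorded design: 10 categories of 10 exemplars, 10
#' runs (1,000 trials), four MTL regions, lognormal baseline rates with a
#' median of 2 Hz, and graded category gains that decay with distance in a
#' fixed semantic embedding (a "semantic tuning curve"), plus a small number
#' of strongly driven (supra-threshold) exemplars per tuned unit.
#'
#' @param n_units_per_region Named integer vector, units per region label.
#' @param baseline_rate `c(meanlog=, sdlog=)` of the lognormal baseline rate
#'   distribution in Hz.
#' @param p_responsive Probability that a unit carries semantic tuning at all
#'   (graded sub-threshold gains; a subset additionally receives
#'   supra-threshold exemplar responses).
#' @param category_gain Multiplicative rate gain at the centre of a tuned
#'   unit's preferred category (rate = baseline * (1 + gain) in the 0--1000 ms
#'   response window).
#' @param exemplar_gain_sd SD of the additive per-exemplar gain component
#'   around the category gain (shared across trials of an exemplar).
#' @param n_supra_exemplars Expected (Poisson) number of strongly driven
#'   exemplars in the preferred category of a tuned unit.
#' @param supra_gain Additional gain applied to supra-threshold exemplars.
#' @param tuning_width Length scale (in embedding units) of the Gaussian decay
#'   of category gain with semantic distance from the preferred point.
#' @param pref_jitter_sd SD of the jitter of a unit's preferred point around
#'   its preferred category's embedding coordinates.
#' @param p_single_unit Probability a unit is a single unit (vs multi-unit).
#' @param semantic_geometry Category embedding; see
#'   [default_semantic_geometry()].
#' @param region_profiles Named list of per-region overrides; recognised
#'   fields: `gain_scale`, `n_supra_exemplars`, `supra_gain`,
#'   `category_weights` (sampling weights of the preferred category).
#'   Defaults encode the recorded regional physiology: amygdala-profile units
#'   preferentially tuned to food categories, parahippocampal-profile units
#'   less selective (weaker, broader responses over more exemplars).
#' @param n_categories,n_exemplars,n_runs Stimulus design counts.
#' @param timing List with `fixation_s`, `gap_range_s` (uniform inter-trial
#'   blank), `response_window_s`, `post_window_s` (baseline-rate viewing time
#'   after the modulated window).
#' @param rng_seed Integer seed; identical seeds give bit-identical sessions.
#' @return Object of class `mtl_config` (a validated list).
#' @export
mtl_config <- function(n_units_per_region = c(AM = 80L, HC = 80L, EC = 80L, PHC = 80L),
                       baseline_rate = c(meanlog = log(2), sdlog = 0.6),
                       p_responsive = 0.6,
                       category_gain = 1.0,
                       exemplar_gain_sd = 0.15,
                       n_supra_exemplars = 1.0,
                       supra_gain = 12,
                       tuning_width = 0.7,
                       pref_jitter_sd = 0.15,
                       p_single_unit = 0.4,
                       semantic_geometry = NULL,
                       region_profiles = NULL,
                       n_categories = 10L,
                       n_exemplars = 10L,
                       n_runs = 10L,
                       timing = list(fixation_s = 0.3,
                                     gap_range_s = c(0.2, 0.4),
                                     response_window_s = 1.0,
                                     post_window_s = 0.2),
                       rng_seed = 1L) {
  if (is.null(semantic_geometry))
    semantic_geometry <- default_semantic_geometry(n_categories)
  if (is.null(region_profiles))
    region_profiles <- default_region_profiles(names(n_units_per_region),
                                               rownames(semantic_geometry))
  cfg <- list(n_units_per_region = n_units_per_region,
              baseline_rate = baseline_rate,
              p_responsive = p_responsive,
              category_gain = category_gain,
              exemplar_gain_sd = exemplar_gain_sd,
              n_supra_exemplars = n_supra_exemplars,
              supra_gain = supra_gain,
              tuning_width = tuning_width,
              pref_jitter_sd = pref_jitter_sd,
              p_single_unit = p_single_unit,
              semantic_geometry = semantic_geometry,
              region_profiles = region_profiles,
              n_categories = as.integer(n_categories),
              n_exemplars = as.integer(n_exemplars),
              n_runs = as.integer(n_runs),
              timing = timing,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "mtl_config"
  validate_config(cfg)
  cfg
}

default_region_profiles <- function(regions, categories) {
  profs <- stats::setNames(
    replicate(length(regions), list(gain_scale = 1), simplify = FALSE),
    regions)
  # amygdala-profile: preference for food categories
  if ("AM" %in% regions) {
    w <- stats::setNames(rep(1, length(categories)), categories)
    w[intersect(c("manmade_food", "fruit"), categories)] <- 3
    profs$AM$category_weights <- w
  }
  # parahippocampal-profile: lower selectivity, broader weaker responses
  if ("PHC" %in% regions)
    profs$PHC <- list(gain_scale = 0.7, n_supra_exemplars = 2.5, supra_gain = 9)
  profs
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$n_units_per_region),
            all(cfg$n_units_per_region >= 0),
            !is.null(names(cfg$n_units_per_region)))
  if (!is.finite(cfg$baseline_rate[["meanlog"]]) ||
      cfg$baseline_rate[["sdlog"]] < 0)
    stop("invalid baseline_rate parameters", call. = FALSE)
  if (cfg$p_responsive < 0 || cfg$p_responsive > 1)
    stop("p_responsive must be in [0, 1]", call. = FALSE)
  if (cfg$category_gain < 0)
    stop("category_gain must be non-negative", call. = FALSE)
  if (nrow(cfg$semantic_geometry) != cfg$n_categories)
    stop("semantic_geometry must have one row per category", call. = FALSE)
  if (cfg$tuning_width <= 0)
    stop("tuning_width must be positive", call. = FALSE)
  if (any(cfg$timing$gap_range_s <= 0) ||
      cfg$timing$gap_range_s[1] > cfg$timing$gap_range_s[2])
    stop("invalid inter-trial gap range", call. = FALSE)
  # baseline window (-500..0 ms) must fall in the unmodulated pre-onset span
  if (cfg$timing$fixation_s + cfg$timing$gap_range_s[1] < 0.5)
    stop("fixation + minimum gap must cover the 500 ms baseline window",
         call. = FALSE)
  invisible(cfg)
}

#' @export
print.mtl_config <- function(x, ...) {
  cat("mtl_config:",
      sum(x$n_units_per_region), "units in",
      length(x$n_units_per_region), "regions;",
      x$n_categories, "categories x", x$n_exemplars, "exemplars x",
      x$n_runs, "runs;",
      "p_responsive =", x$p_responsive,
      "category_gain =", x$category_gain, "\n")
  invisible(x)
}
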