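#' Baseline z-scored population response matrix
#'
#' Expresses each unit's response-window firing rate (0--1000 ms after onset)
#' as a z-score relative to the mean and standard deviation of its
#' baseline-window rates (-500--0 ms) across all session trials.  At the
#' stimulus level rows are the per-stimulus mean rates across that stimulus'
#' trials (N_S x N_U); at the trial level rows are individual trials
#' (N_T x N_U).
#'
#' Units with zero baseline standard deviation carry no usable z-scale; they
#' are excluded from the matrix with a message (default) or retained with an
#' epsilon floor on the SD.
#'
#' @param session An `mtl_session`.
#' @param level "stimulus" or "trial".
#' @param config A [screening_config()] (supplies the windows).
#' @param units Optional character vector of unit ids to include (e.g. only
#'   non-responsive units); default all.
#' @param sigma_zero "drop" (default) or "floor".
#' @param epsilon SD floor used when `sigma_zero = "floor"`.
#' @return Object of class `population_matrix`: `values` (rows = stimuli or
#'   trials, columns = units), `row_labels` (data.frame), `units`
#'   (data.frame), `level`, `dropped_units`.
#' @export
zscore_responses <- function(session, level = c("stimulus", "trial"),
                             config = screening_config(),
                             units = NULL,
                             sigma_zero = c("drop", "floor"),
                             epsilon = 1e-6) {
  level <- match.arg(level)
  sigma_zero <- match.arg(sigma_zero)
  keep <- if (is.null(units)) session$units$unit_id
          else intersect(session$units$unit_id, units)
  onsets <- session$events$onset_s
  bw <- config$baseline_window
  rw <- config$response_window
  nlt <- function(sp, x) findInterval(x, sp, left.open = TRUE)
  n_tr <- length(onsets)

  zmat <- matrix(NA_real_, n_tr, length(keep))
  sigma0 <- logical(length(keep))
  for (j in seq_along(keep)) {
    sp <- session$spikes[[keep[j]]]
    base_rate <- (nlt(sp, onsets + bw[2]) - nlt(sp, onsets + bw[1])) /
      diff(bw)
    resp_rate <- (nlt(sp, onsets + rw[2]) - nlt(sp, onsets + rw[1])) /
      diff(rw)
    mu <- mean(base_rate); sg <- stats::sd(base_rate)
    if (sg == 0) {
      sigma0[j] <- TRUE
      if (sigma_zero == "floor") sg <- epsilon else next
    }
    zmat[, j] <- (resp_rate - mu) / sg
  }
  dropped <- keep[sigma0 & sigma_zero == "drop"]
  if (length(dropped))
    message(length(dropped),
            " unit(s) with zero baseline SD excluded from population matrix")
  sel <- !(sigma0 & sigma_zero == "drop")
  zmat <- zmat[, sel, drop = FALSE]
  unit_tab <- session$units[match(keep[sel], session$units$unit_id), ,
                            drop = FALSE]
  colnames(zmat) <- keep[sel]

  if (level == "trial") {
    row_labels <- session$events[, c("trial_index", "stimulus_id",
                                     "category_id")]
  } else {
    stim <- factor(session$events$stimulus_id,
                   levels = session$stimuli$stimulus_id)
    zmat <- apply(zmat, 2, function(col) tapply(col, stim, mean))
    zmat <- matrix(zmat, nrow = nlevels(stim),
                   dimnames = list(levels(stim), keep[sel]))
    row_labels <- session$stimuli
  }
  structure(list(values = zmat, row_labels = row_labels, units = unit_tab,
                 level = level, dropped_units = dropped),
            class = "population_matrix")
}

#' @export
print.population_matrix <- function(x, ...) {
  cat("population_matrix (", x$level, " level): ", nrow(x$values), " x ",
      ncol(x$values), " (rows x units)\n", sep = "")
  invisible(x)
}

#' Representational dissimilarity matrix (1 - Pearson R)
#'
#' Pairwise dissimilarity between the rows of a population matrix, computed
#' as one minus the Pearson correlation of the two row vectors.  Rows with
#' zero variance have no defined correlation; their pairwise distances are
#' set to 1 (correlation treated as 0) with a message, keeping the matrix
#' complete while marking those rows as uninformative.
#'
#' @param x A `population_matrix` or a plain numeric matrix (rows = items).
#' @param labels Optional data.frame of row labels (taken from the
#'   `population_matrix` when available).
#' @return Object of class `mtl_dissim`: symmetric `values` matrix with zero
#'   diagonal and entries in `[0, 2]`, plus `labels`.
#' @export
dissimilarity <- function(x, labels = NULL) {
  if (inherits(x, "population_matrix")) {
    labels <- x$row_labels
    x <- x$values
  }
  sds <- apply(x, 1, stats::sd)
  d <- matrix(1, nrow(x), nrow(x), dimnames = list(rownames(x), rownames(x)))
  ok <- sds > 0
  if (any(!ok))
    message(sum(!ok), " constant row(s): pairwise distances set to 1")
  if (sum(ok) >= 2)
    d[ok, ok] <- 1 - stats::cor(t(x[ok, , drop = FALSE]))
  diag(d) <- 0
  structure(list(values = d, labels = labels), class = "mtl_dissim")
}

#' @export
print.mtl_dissim <- function(x, ...) {
  cat("mtl_dissim:", nrow(x$values), "items; mean distance",
      round(mean(x$values[upper.tri(x$values)]), 3), "\n")
  invisible(x)
}

#' UPGMA dendrogram of a dissimilarity matrix
#'
#' Unweighted average-linkage (UPGMA) agglomerative clustering on the
#' correlation distances.  Merge heights are checked for monotonicity (a
#' UPGMA property on these inputs) and any violation is reported.
#'
#' @param dissim An `mtl_dissim` or symmetric distance matrix.
#' @return An [stats::hclust] tree.
#' @export
cluster_dendrogram <- function(dissim) {
  v <- if (inherits(dissim, "mtl_dissim")) dissim$values else dissim
  tree <- stats::hclust(stats::as.dist(v), method = "average")
  if (is.unsorted(tree$height))
    warning("non-monotone merge heights in UPGMA tree")
  tree
}

#' Count categories whose exemplars are contiguous in dendrogram leaf order
#'
#' Quantifies the qualitative observation that all exemplars of a category
#' line up next to one another on the dendrogram axis: a category is
#' contiguous when its exemplars occupy an unbroken block of leaf positions.
#'
#' @param tree An [stats::hclust] tree.
#' @param labels Category label per leaf, in the original item order.
#' @return Integer count of contiguous categories.
#' @export
leaf_category_contiguity <- function(tree, labels) {
  ord_labels <- labels[tree$order]
  pos <- split(seq_along(ord_labels), ord_labels)
  sum(vapply(pos, function(p) diff(range(p)) + 1L == length(p), logical(1)))
}

#' Classical (Torgerson) MDS embedding of a dissimilarity matrix
#'
#' @param dissim An `mtl_dissim` or symmetric distance matrix.
#' @param dims Number of embedding dimensions.
#' @return Items x dims coordinate matrix (zero-padded when fewer positive
#'   eigenvalues exist than requested dimensions).
#' @export
mds_embed <- function(dissim, dims = 2L) {
  v <- if (inherits(dissim, "mtl_dissim")) dissim$values else dissim
  n <- nrow(v)
  if (n < 2) return(matrix(0, n, dims))
  # degenerate inputs (e.g. all-zero distances) have fewer positive
  # eigenvalues than requested dimensions; missing axes are zero-padded
  xy <- suppressWarnings(stats::cmdscale(stats::as.dist(v),
                                         k = min(dims, n - 1)))
  if (ncol(xy) < dims) {
    pad <- matrix(0, nrow(xy), dims - ncol(xy))
    xy <- cbind(xy, pad)
  }
  xy
}

# Rank-sum permutation machinery shared by the RSA and confusion tests:
# the observed statistic is the rank-sum (mid-ranks) of the values in the
# "within" cell of the partition; the null redistributes the within/between
# partition over the same value multiset (cell sizes preserved).
perm_partition_ranksum <- function(values, within, n_perm, seed = NULL,
                                   alternative = c("less", "greater"),
                                   exact = NULL, exact_limit = 2e5,
                                   plus_one = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(length(values) == length(within))
  if (!is.null(seed)) set.seed(seed)
  r <- rank(values)
  k <- sum(within)
  n <- length(values)
  if (k == 0 || k == n)
    stop("degenerate partition: need both within and between pairs")
  obs <- sum(r[within])
  use_exact <- if (is.null(exact)) choose(n, k) <= exact_limit else exact
  if (use_exact) {
    if (choose(n, k) > exact_limit)
      stop("exact enumeration infeasible")
    subsets <- utils::combn(n, k)
    null_stats <- colSums(matrix(r[subsets], nrow = k))
    n_eff <- length(null_stats)
  } else {
    null_stats <- vapply(seq_len(n_perm),
                         function(i) sum(r[sample.int(n, k)]), numeric(1))
    n_eff <- n_perm
  }
  extreme <- if (alternative == "less") sum(null_stats <= obs + 1e-9)
             else sum(null_stats >= obs - 1e-9)
  p <- if (plus_one) (extreme + 1) / (n_eff + 1) else extreme / n_eff
  structure(list(statistic = obs, p.value = p, n_perm = n_eff,
                 n_within = k, n_between = n - k,
                 alternative = alternative, exact = use_exact),
            class = "mtl_perm")
}

#' @export
print.mtl_perm <- function(x, ...) {
  cat("partition permutation test (", x$alternative, "): rank-sum = ",
      x$statistic, ", p = ", format(x$p.value), " (",
      if (x$exact) "exact, " else "", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Within- versus between-category permutation test on dissimilarities
#'
#' Tests the hypothesis that within-category dissimilarity is lower than
#' between-category dissimilarity.  The observed statistic is the
#' Mann-Whitney rank-sum of the within-category distances among all
#' upper-triangle distances; the null distribution is obtained by shuffling
#' the assignment of matrix cells to the within/between partition (cell
#' counts preserved) and the reported p-value is the percentile of the
#' observed statistic within the null distribution.  Only the upper triangle
#' is used since dissimilarity matrices are symmetric.
#'
#' @param dissim An `mtl_dissim` or symmetric matrix.
#' @param category_labels Category per row (taken from `labels$category_id`
#'   of the `mtl_dissim` when omitted).
#' @param n_perm Number of shuffles (default 1e5).
#' @param seed Optional seed for the shuffle generator.
#' @param exact `NULL` (auto), `TRUE` to force exhaustive enumeration of all
#'   partitions (small instances only), `FALSE` to force Monte Carlo.
#' @param plus_one Apply the (b+1)/(n+1) correction (off by default,
#'   matching the percentile convention).
#' @param null "pair-partition" (default) shuffles the within/between
#'   assignment of matrix cells exactly as described for the original
#'   procedure; "stimulus-label" permutes the category labels of the
#'   stimuli instead, a stricter null that preserves the pair-dependence
#'   structure of the distance matrix.
#' @return An `mtl_perm` result.
#' @export
within_between_permutation <- function(dissim, category_labels = NULL,
                                       n_perm = 1e5, seed = NULL,
                                       exact = FALSE, plus_one = FALSE,
                                       null = c("pair-partition",
                                                "stimulus-label")) {
  null <- match.arg(null)
  v <- if (inherits(dissim, "mtl_dissim")) dissim$values else dissim
  if (is.null(category_labels) && inherits(dissim, "mtl_dissim"))
    category_labels <- dissim$labels$category_id
  stopifnot(!is.null(category_labels), length(category_labels) == nrow(v),
            isSymmetric(unname(v)))
  ut <- upper.tri(v)
  same <- outer(category_labels, category_labels, "==")
  if (null == "pair-partition")
    return(perm_partition_ranksum(v[ut], same[ut], n_perm = n_perm,
                                  seed = seed, alternative = "less",
                                  exact = exact))
  # stricter null: permute stimulus labels, keeping the matrix intact
  if (!is.null(seed)) set.seed(seed)
  r <- rank(v[ut])
  obs <- sum(r[same[ut]])
  n_items <- nrow(v)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    pm <- sample.int(n_items)
    sum(r[same[pm, pm][ut]])
  }, numeric(1))
  p <- if (plus_one) (sum(null_stats <= obs + 1e-9) + 1) / (n_perm + 1)
       else mean(null_stats <= obs + 1e-9)
  structure(list(statistic = obs, p.value = p, n_perm = n_perm,
                 n_within = sum(same[ut]), n_between = sum(!same[ut]),
                 alternative = "less", exact = FALSE),
            class = "mtl_perm")
}
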