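#' Decoding scheme: targets, splits and classifier settings
#'
#' @param target "category" (generalisation to unseen exemplars: train on
#'   half the stimuli per category, test on the other half) or "identity"
#'   (single-trial stimulus identity: train on half the trials per stimulus).
#' @param n_splits Number of pseudorandom divisions into training and test
#'   set (default 100).
#' @param holdout Fraction held out for testing (default 0.5).
#' @param cost Soft-margin constant of the linear max-margin classifiers
#'   (inputs are already z-scored).
#' @param chance "marginal" computes Cohen's chance agreement P_C from the
#'   confusion-matrix marginals (standard); "uniform" uses 1/K.
#' @param seed Seed for the split generator.
#' @return Object of class `decoding_scheme`.
#' @export
decoding_scheme <- function(target = c("category", "identity"),
                            n_splits = 100L, holdout = 0.5, cost = 1,
                            chance = c("marginal", "uniform"),
                            seed = 1L) {
  target <- match.arg(target)
  chance <- match.arg(chance)
  stopifnot(holdout > 0, holdout < 1, n_splits >= 1, cost > 0)
  structure(list(target = target, n_splits = as.integer(n_splits),
                 holdout = holdout, cost = cost, chance = chance,
                 seed = as.integer(seed)),
            class = "decoding_scheme")
}

# One-vs-all linear max-margin multiclass model: one binary hinge-loss
# classifier per class (positive vs rest), prediction by maximal decision
# value, ties broken by lowest class index.
ova_train <- function(X, y, cost, tol = 1e-3, max_epochs = 200L) {
  classes <- levels(y)
  Xa <- cbind(X, bias = 1)
  tX <- t(Xa)
  W <- vapply(seq_along(classes), function(k) {
    yk <- ifelse(as.integer(y) == k, 1, -1)
    svm_dcd_train(tX, yk, C = cost, max_epochs = max_epochs, tol = tol,
                  seed = 12345 + k)
  }, numeric(ncol(Xa)))
  list(W = W, classes = classes)
}

ova_predict <- function(model, X) {
  scores <- cbind(X, bias = 1) %*% model$W
  factor(model$classes[max.col(scores, ties.method = "first")],
         levels = model$classes)
}

# Stratified 50% holdout decoding loop shared by both targets.
decode_ova <- function(X, y, strata, scheme) {
  y <- factor(y)
  strata <- factor(strata)
  grp <- split(seq_along(y), strata)
  if (any(lengths(grp) < 2))
    stop("every stratum needs at least 2 instances to split")
  K <- nlevels(y)
  conf <- matrix(0L, K, K, dimnames = list(true = levels(y),
                                           predicted = levels(y)))
  per_split <- data.frame(split = seq_len(scheme$n_splits),
                          accuracy = NA_real_, kappa = NA_real_)
  set.seed(scheme$seed)
  for (s in seq_len(scheme$n_splits)) {
    train <- unlist(lapply(grp, function(idx)
      sample(idx, max(1L, round(length(idx) * (1 - scheme$holdout))))))
    test <- setdiff(seq_along(y), train)
    model <- ova_train(X[train, , drop = FALSE], y[train], scheme$cost)
    pred <- ova_predict(model, X[test, , drop = FALSE])
    tab <- table(true = y[test], predicted = pred)
    conf <- conf + tab
    per_split$accuracy[s] <- mean(pred == y[test])
    per_split$kappa[s] <- cohen_kappa(tab, chance = scheme$chance)
  }
  structure(list(target = scheme$target, confusion = conf,
                 per_split = per_split,
                 accuracy = sum(diag(conf)) / sum(conf),
                 kappa = cohen_kappa(conf, chance = scheme$chance),
                 scheme = scheme),
            class = "mtl_decoding")
}

#' Decode superordinate category with generalisation to unseen exemplars
#'
#' Trains one-vs-all linear max-margin classifiers on the stimulus-level
#' population matrix (N_S x N_U) using half of the exemplars of every
#' category and tests on the held-out exemplars, over `n_splits` pseudorandom
#' divisions.  Above-chance performance therefore requires generalisation of
#' the category code to stimuli never seen in training.
#'
#' @param pop A stimulus-level `population_matrix`.
#' @param scheme A [decoding_scheme()] with target "category".
#' @return Object of class `mtl_decoding` with the aggregated confusion
#'   matrix (rows: correct label, columns: predicted label), per-split
#'   accuracy and kappa, and aggregate Cohen's kappa.
#' @export
decode_category <- function(pop, scheme = decoding_scheme("category")) {
  stopifnot(inherits(pop, "population_matrix"), pop$level == "stimulus",
            scheme$target == "category")
  y <- pop$row_labels$category_id
  if (any(table(y) < 2))
    stop("every category needs at least 2 exemplars")
  decode_ova(pop$values, y, strata = y, scheme = scheme)
}

#' Decode stimulus identity from single trials
#'
#' Trains one-vs-all linear max-margin classifiers on the trial-level
#' population matrix (N_T x N_U) using half of the trials of every stimulus
#' and tests on the held-out trials, over `n_splits` pseudorandom divisions.
#'
#' @param pop A trial-level `population_matrix`.
#' @param scheme A [decoding_scheme()] with target "identity".
#' @return Object of class `mtl_decoding`.
#' @export
decode_identity <- function(pop, scheme = decoding_scheme("identity")) {
  stopifnot(inherits(pop, "population_matrix"), pop$level == "trial",
            scheme$target == "identity")
  y <- pop$row_labels$stimulus_id
  if (any(table(y) < 2))
    stop("every stimulus needs at least 2 trials")
  decode_ova(pop$values, y, strata = y, scheme = scheme)
}

#' @export
print.mtl_decoding <- function(x, ...) {
  cat("mtl_decoding (", x$target, "): ", nrow(x$confusion), " classes, ",
      nrow(x$per_split), " splits; median accuracy ",
      round(100 * stats::median(x$per_split$accuracy), 1),
      "%, aggregate kappa ", round(x$kappa, 3), "\n", sep = "")
  invisible(x)
}

#' Cohen's kappa of a confusion matrix
#'
#' kappa = (P_O - P_C) / (1 - P_C), where P_O is the observed agreement
#' (diagonal fraction) and P_C the chance agreement, computed from the
#' row/column marginals by default or as 1/K with `chance = "uniform"`.
#'
#' @param confusion Square count matrix (rows: true, columns: predicted).
#' @param chance "marginal" or "uniform".
#' @return Numeric kappa.
#' @export
cohen_kappa <- function(confusion, chance = c("marginal", "uniform")) {
  chance <- match.arg(chance)
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  n <- sum(confusion)
  if (n == 0) return(NA_real_)
  p_o <- sum(diag(confusion)) / n
  p_c <- if (chance == "marginal")
    sum(rowSums(confusion) * colSums(confusion)) / n^2
  else 1 / nrow(confusion)
  if (p_c == 1) return(NA_real_)
  (p_o - p_c) / (1 - p_c)
}

#' Within- versus between-category permutation test on a confusion matrix
#'
#' Tests whether stimuli are confused more often within than between
#' superordinate categories.  All off-diagonal cells of the (asymmetric)
#' confusion matrix are partitioned into within- and between-category
#' confusions; diagonal cells are correct classifications, not confusions,
#' and are excluded.  The observed statistic is the rank-sum of the
#' within-category cells, and the null shuffles the partition assignment
#' over the full off-diagonal matrix.
#'
#' @param confusion Square confusion matrix whose rows/columns are stimuli.
#' @param category_labels Category of each stimulus, in row order.
#' @param n_perm Number of shuffles (default 1e5).
#' @param seed Optional seed.
#' @param exact Force/forbid exhaustive partition enumeration (see
#'   [within_between_permutation()]).
#' @return An `mtl_perm` result (alternative: within confusions greater).
#' @export
confusion_within_between_test <- function(confusion, category_labels,
                                          n_perm = 1e5, seed = NULL,
                                          exact = FALSE) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion),
            length(category_labels) == nrow(confusion))
  off <- !diag(nrow(confusion))
  same <- outer(category_labels, category_labels, "==")
  perm_partition_ranksum(confusion[off], same[off], n_perm = n_perm,
                         seed = seed, alternative = "greater", exact = exact)
}
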