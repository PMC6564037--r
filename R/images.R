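#' Pairwise pixel-level image similarity measures
#'
#' Computes, for every unordered pair of equal-sized grey-scale images, the
#' Euclidean distance, the mean squared error (MSE), the peak
#' signal-to-noise ratio (PSNR) and the structural similarity index (SSIM).
#' PSNR and SSIM are similarities; they are also returned as distances
#' (`max(psnr) - psnr`, `max(ssim) - ssim`).  PSNR of identical images is
#' infinite: such pairs are excluded from the `max(psnr)` reference and
#' assigned distance 0.
#'
#' @param images Named list of numeric matrices of equal dimensions, or the
#'   list returned by [generate_images()].
#' @param intensity_range Declared intensity range; its width is the PSNR
#'   peak value and the SSIM dynamic range.
#' @return Object of class `image_distances`: `pairs` (data.frame with
#'   euclidean, mse, psnr, ssim, psnr_distance, ssim_distance per pair) and
#'   a named list `matrices` of symmetric zero-diagonal distance matrices
#'   (euclidean, mse, psnr, ssim).
#' @export
image_distances <- function(images, intensity_range = NULL) {
  if (!is.null(images$images)) {
    if (is.null(intensity_range)) intensity_range <- images$intensity_range
    images <- images$images
  }
  if (is.null(intensity_range)) intensity_range <- c(0, 255)
  dims <- vapply(images, dim, integer(2))
  if (any(dims != dims[, 1])) stop("images must have identical dimensions")
  n <- length(images)
  ids <- names(images) %||% sprintf("img%03d", seq_len(n))
  L <- diff(intensity_range)
  n_px <- prod(dims[, 1])

  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  eu <- mse <- ssim <- numeric(nrow(pr))
  for (k in seq_len(nrow(pr))) {
    a <- images[[pr[k, 1]]]; b <- images[[pr[k, 2]]]
    dd <- a - b
    mse[k] <- mean(dd^2)
    eu[k] <- sqrt(sum(dd^2))
    ssim[k] <- ssim_index(a, b, L = L)
  }
  psnr <- ifelse(mse > 0, 10 * log10(L^2 / mse), Inf)
  psnr_ref <- if (any(is.finite(psnr))) max(psnr[is.finite(psnr)]) else 0
  psnr_dist <- ifelse(is.finite(psnr), psnr_ref - psnr, 0)
  ssim_dist <- if (length(ssim)) max(ssim) - ssim else numeric(0)

  as_mat <- function(v, diag_val = 0) {
    m <- matrix(diag_val, n, n, dimnames = list(ids, ids))
    m[pr] <- v; m[pr[, 2:1, drop = FALSE]] <- v
    diag(m) <- diag_val
    m
  }
  structure(list(
    pairs = data.frame(id_a = ids[pr[, 1]], id_b = ids[pr[, 2]],
                       euclidean = eu, mse = mse, psnr = psnr, ssim = ssim,
                       psnr_distance = psnr_dist, ssim_distance = ssim_dist,
                       stringsAsFactors = FALSE),
    matrices = list(euclidean = as_mat(eu), mse = as_mat(mse),
                    psnr = as_mat(psnr_dist), ssim = as_mat(ssim_dist)),
    n_pixels = n_px, intensity_range = intensity_range),
    class = "image_distances")
}

#' Structural similarity index of two grey-scale images
#'
#' Standard windowed luminance-contrast-structure product with constants
#' K1 = 0.01, K2 = 0.03 and an 8 x 8 uniform window; the global index is the
#' mean of the local SSIM map.  Equals 1 for identical images.
#'
#' @param a,b Equal-sized numeric matrices.
#' @param L Dynamic range of the intensities.
#' @param window Side length of the uniform window.
#' @param K1,K2 Stabilisation constants.
#' @return Scalar SSIM in (-1, 1].
#' @export
ssim_index <- function(a, b, L = 255, window = 8L, K1 = 0.01, K2 = 0.03) {
  stopifnot(all(dim(a) == dim(b)))
  w <- min(window, dim(a))
  npx <- w * w
  wsum <- function(m) {
    nr <- nrow(m) - w + 1L; nc <- ncol(m) - w + 1L
    out <- matrix(0, nr, nc)
    for (di in seq_len(w) - 1L)
      for (dj in seq_len(w) - 1L)
        out <- out + m[di + seq_len(nr), dj + seq_len(nc)]
    out
  }
  mu_a <- wsum(a) / npx
  mu_b <- wsum(b) / npx
  var_a <- wsum(a * a) / npx - mu_a^2
  var_b <- wsum(b * b) / npx - mu_b^2
  cov_ab <- wsum(a * b) / npx - mu_a * mu_b
  c1 <- (K1 * L)^2; c2 <- (K2 * L)^2
  smap <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  mean(smap)
}

#' Feed an image-similarity measure into the representational analyses
#'
#' Wraps one of the pairwise image-distance matrices as a dissimilarity
#' object so the clustering, MDS and within/between-category permutation
#' machinery of the neuronal analyses can be applied unchanged to pixel-level
#' similarity.
#'
#' @param dists An [image_distances()] result.
#' @param measure Which distance to use.
#' @param labels Optional data.frame with image_id and category_id (e.g. the
#'   `labels` element of [generate_images()]).
#' @return An `mtl_dissim`.
#' @export
image_rsa <- function(dists, measure = c("euclidean", "mse", "psnr", "ssim"),
                      labels = NULL) {
  measure <- match.arg(measure)
  v <- dists$matrices[[measure]]
  if (!is.null(labels)) {
    stopifnot(nrow(labels) == nrow(v))
    labels <- data.frame(stimulus_id = labels[[1]],
                         category_id = labels$category_id,
                         stringsAsFactors = FALSE)
  }
  structure(list(values = v, labels = labels), class = "mtl_dissim")
}
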