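# evaluate `code` under a fixed RNG seed, restoring caller RNG state
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || !is.finite(seed)) stop("a finite seed is required")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Rank-based AUC of a score map against a truth mask
#'
#' Area under the ROC curve computed from ranks (the Mann-Whitney
#' statistic): the probability that a randomly chosen positive pixel scores
#' higher than a randomly chosen negative one, with ties counting 1/2.
#'
#' @param scores Numeric vector/matrix of scores.
#' @param positive Logical vector/matrix of the same length: truth labels.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, positive) {
  s <- as.vector(scores); p <- as.vector(positive)
  keep <- !is.na(s) & !is.na(p)
  s <- s[keep]; p <- as.logical(p[keep])
  n1 <- sum(p); n0 <- sum(!p)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative pixels")
  r <- rank(s)
  (sum(r[p]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Jaccard overlap of two masks
#'
#' @param a,b Logical matrices of identical shape.
#' @return `|a & b| / |a | b|`; 1 if both masks are empty.
#' @export
jaccard_index <- function(a, b) {
  stopifnot(is.logical(a), is.logical(b), identical(dim(a), dim(b)))
  u <- sum(a | b, na.rm = TRUE)
  if (u == 0L) return(1)
  sum(a & b, na.rm = TRUE) / u
}

#' Median filter a map
#'
#' Square-window median filter (NA-aware), the standard despeckling step for
#' ratiometric optode and derivative-band maps before thresholding.
#'
#' @param m Numeric matrix or `scalar_image`.
#' @param size Odd window size in pixels (default 3).
#' @return Same type as the input.
#' @export
median_filter <- function(m, size = 3) {
  if (inherits(m, "scalar_image")) {
    return(scalar_image(median_filter(m$data, size), units = m$units))
  }
  stopifnot(is.matrix(m), size %% 2 == 1)
  h <- size %/% 2
  n <- nrow(m); p <- ncol(m)
  out <- m
  for (i in seq_len(n)) {
    ri <- max(1, i - h):min(n, i + h)
    for (j in seq_len(p)) {
      out[i, j] <- stats::median(m[ri, max(1, j - h):min(p, j + h)],
                                 na.rm = TRUE)
    }
  }
  out
}

#' Half-maximum-above-background hotspot mask
#'
#' Thresholds a map at `background + 0.5 * (peak - background)` (the FWHM
#' convention), with the background taken as the median and the peak as a
#' high quantile (robust to isolated noise spikes).
#'
#' @param m Numeric matrix or `scalar_image`.
#' @param peak_quantile Quantile used as the robust peak (default 0.995).
#' @return Logical matrix; `NA` pixels are `FALSE`.
#' @export
halfmax_mask <- function(m, peak_quantile = 0.995) {
  if (inherits(m, "scalar_image")) m <- m$data
  bg <- stats::median(m, na.rm = TRUE)
  pk <- stats::quantile(m, peak_quantile, na.rm = TRUE, names = FALSE)
  sel <- m > bg + 0.5 * (pk - bg)
  sel[is.na(sel)] <- FALSE
  sel
}

#' Box (mean) filter a map
#'
#' NA-aware square moving average. Averaging the delta-ratio image before
#' the logarithmic calibration inversion reduces the noise-induced (Jensen)
#' bias that otherwise inflates recovered O2 near the calibration asymptote.
#' Masked pixels stay masked.
#'
#' @param m Numeric matrix or `scalar_image`.
#' @param size Odd window size in pixels.
#' @return Same type as the input.
#' @export
box_filter <- function(m, size = 3) {
  if (inherits(m, "scalar_image")) {
    out <- scalar_image(box_filter(m$data, size), units = m$units)
    for (a in c("t", "light", "reference_t")) attr(out, a) <- attr(m, a)
    return(out)
  }
  stopifnot(is.matrix(m), size %% 2 == 1)
  h <- size %/% 2
  n <- nrow(m); p <- ncol(m)
  out <- m
  for (i in seq_len(n)) {
    ri <- max(1, i - h):min(n, i + h)
    for (j in seq_len(p)) {
      if (is.na(m[i, j])) next
      out[i, j] <- mean(m[ri, max(1, j - h):min(p, j + h)], na.rm = TRUE)
    }
  }
  out
}
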