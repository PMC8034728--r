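#' Otsu threshold of a numeric sample
#'
#' Exact Otsu thresholding on raw (continuous) values rather than a histogram:
#' every midpoint between consecutive sorted unique values is a candidate, and
#' the threshold returned maximizes the between-class variance
#' `w1 * w2 * (m1 - m2)^2` of the induced two-class split. Used both to
#' binarize red-channel frames and to separate apoptotic from basal
#' caspase-reporter traces pooled over all tracks of a video.
#'
#' @param x Numeric vector (NAs dropped). Needs at least two distinct values.
#' @return The scalar threshold; classify as `x > threshold`.
#' @examples
#' otsu_threshold(c(rep(0, 90), rep(2, 10)))
#' @export
otsu_threshold <- function(x) {
  x <- x[!is.na(x)]
  ux <- sort(unique(x))
  if (length(ux) < 2L)
    abort("Otsu threshold needs at least two distinct values.",
          class = "apoptomap_degenerate_error")
  xs <- sort(x)
  n <- length(xs)
  # class split after position k (k = 1 .. n-1); candidate thresholds are the
  # midpoints between distinct consecutive order statistics
  cs <- cumsum(xs)
  k <- seq_len(n - 1L)
  w1 <- k / n
  m1 <- cs[k] / k
  m2 <- (cs[n] - cs[k]) / (n - k)
  bcv <- w1 * (1 - w1) * (m1 - m2)^2
  valid <- xs[k] < xs[k + 1L]          # only splits between distinct values
  bcv[!valid] <- -Inf
  kbest <- which.max(bcv)
  (xs[kbest] + xs[kbest + 1L]) / 2
}
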