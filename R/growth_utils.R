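#' Caliper tumor volume
#'
#' Volume from three orthogonal caliper measurements as
#' `0.5 * length * width * height`, in cubic input units. Symmetric in
#' its arguments.
#'
#' @param length,width,height Positive dimensions (vectorized).
#' @return Numeric volume(s).
#' @examples
#' tumor_volume(2, 3, 4)  # 12
#' @export
tumor_volume <- function(length, width, height) {
  dims <- cbind(length, width, height)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("all dimensions must be positive", call. = FALSE)
  0.5 * length * width * height
}

#' Maximum growth rate from a confluency/volume time series
#'
#' The instantaneous exponential rate is estimated as the least-squares
#' slope of `log(size)` versus time over a sliding window of consecutive
#' points; the maximum over all windows is returned (units: 1/time). On an
#' exact exponential `size = A * exp(r * t)` every window recovers `r`.
#' The windowed slope is robust to the noise typical of confluency and
#' caliper series; the default window of 3 points is the smallest that
#' smooths single-point jitter.
#'
#' @param time Strictly increasing measurement times.
#' @param size Positive sizes (confluency, volume, cell count).
#' @param window Number of consecutive points per window (>= 2).
#' @return Maximum windowed log-linear slope.
#' @examples
#' t <- 0:9
#' max_growth_rate(t, exp(0.3 * t))  # 0.3
#' @export
max_growth_rate <- function(time, size, window = 3L) {
  window <- as.integer(window)
  stopifnot(window >= 2)
  if (length(time) != length(size))
    stop("time and size must have equal length", call. = FALSE)
  if (length(time) < window)
    stop("need at least ", window, " points for a window of ", window,
         call. = FALSE)
  if (any(diff(time) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(!is.finite(size)) || any(size <= 0))
    stop("sizes must be positive", call. = FALSE)
  ls <- log(size)
  n <- length(time)
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    tt <- time[idx]; yy <- ls[idx]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))
  max(slopes)
}
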