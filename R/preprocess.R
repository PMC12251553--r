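#' Spike-suppressing moving-average filter
#'
#' Online sensor cleaning used before feature construction. At each sample
#' the innovation relative to the previous filtered value is compared with
#' the threshold `D`: if it is within the threshold, the output is the mean
#' of the last `m` (accepted) raw samples; if it exceeds the threshold, the
#' sample is treated as an outlier, replaced by the previous filtered value
#' plus a step of exactly `D` in the direction of the innovation (innovation
#' clamping, which preserves the signal level), and the window mean is
#' recomputed with the replacement. The first `min(m, k)` samples are
#' averaged over the history available so far.
#'
#' @param x numeric vector of raw samples.
#' @param D positive outlier threshold (channel units).
#' @param m moving-average window length (samples, >= 1).
#' @return Numeric vector of filtered samples, same length as `x`.
#' @export
#' @examples
#' moving_average_filter(c(0, 0, 0, 0, 100), D = 1, m = 2)
moving_average_filter <- function(x, D, m) {
  if (!is.numeric(D) || length(D) != 1L || D <= 0)
    stop("D must be a positive scalar")
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("m must be a positive integer")
  n <- length(x)
  if (n == 0L) return(numeric(0))
  buf <- numeric(n)   # accepted (possibly clamped) samples
  out <- numeric(n)
  buf[1] <- x[1]
  out[1] <- x[1]
  for (k in seq_len(n)[-1]) {
    innov <- x[k] - out[k - 1]
    buf[k] <- if (abs(innov) < D) x[k] else out[k - 1] + D * sign(innov)
    lo <- max(1L, k - m + 1L)
    out[k] <- mean(buf[lo:k])
  }
  out
}

#' Five-point numerical differentiation
#'
#' High-order finite-difference derivative of a uniformly sampled series.
#' Interior points use the centred five-point stencil (fourth-order
#' accurate, exact through degree-4 polynomials); the two points at each
#' boundary use one-sided five-point stencils of matching order.
#'
#' @param x numeric vector of samples (length >= 5).
#' @param h positive uniform sample spacing.
#' @param order derivative order, 1 or 2.
#' @return Numeric vector of derivative estimates at every sample.
#' @export
five_point_derivative <- function(x, h, order = 1L) {
  n <- length(x)
  if (n < 5L) stop("five-point differentiation needs at least 5 points")
  if (h <= 0) stop("sample spacing h must be positive")
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  d <- numeric(n)
  i <- 3:(n - 2)
  if (order == 1L) {
    d[i] <- (-x[i + 2] + 8 * x[i + 1] - 8 * x[i - 1] + x[i - 2]) / (12 * h)
    d[1] <- sum(c(-25, 48, -36, 16, -3) * x[1:5]) / (12 * h)
    d[2] <- sum(c(-3, -10, 18, -6, 1) * x[1:5]) / (12 * h)
    d[n - 1] <- -sum(c(-3, -10, 18, -6, 1) * x[n:(n - 4)]) / (12 * h)
    d[n] <- -sum(c(-25, 48, -36, 16, -3) * x[n:(n - 4)]) / (12 * h)
  } else {
    d[i] <- (-x[i + 2] + 16 * x[i + 1] - 30 * x[i] + 16 * x[i - 1] - x[i - 2]) /
      (12 * h^2)
    d[1] <- sum(c(35, -104, 114, -56, 11) * x[1:5]) / (12 * h^2)
    d[2] <- sum(c(11, -20, 6, 4, -1) * x[1:5]) / (12 * h^2)
    d[n - 1] <- sum(c(11, -20, 6, 4, -1) * x[n:(n - 4)]) / (12 * h^2)
    d[n] <- sum(c(35, -104, 114, -56, 11) * x[n:(n - 4)]) / (12 * h^2)
  }
  d
}

#' Channel normalisation with frozen statistics
#'
#' Maps each column of a numeric matrix/data frame to a common scale:
#' `"minmax"` to \[0, 1\] or `"zscore"` to mean 0, sd 1. The offsets and
#' scales are returned so they can be frozen on training data and re-applied
#' to test or online data without leakage. Degenerate (constant) channels
#' get scale 1 with a warning.
#'
#' @param x numeric matrix or data frame (rows = samples).
#' @param method `"minmax"` or `"zscore"`.
#' @param stats optional previously computed statistics to apply instead of
#'   estimating new ones.
#' @return List with `data` (normalised matrix) and `stats` (class
#'   `norm_stats`: per-channel `offset`, `scale`, `method`).
#' @export
normalize_channels <- function(x, method = c("minmax", "zscore"),
                               stats = NULL) {
  xm <- as.matrix(x)
  if (is.null(stats)) {
    method <- match.arg(method)
    if (method == "minmax") {
      offset <- apply(xm, 2, min)
      scale <- apply(xm, 2, max) - offset
    } else {
      offset <- colMeans(xm)
      scale <- apply(xm, 2, stats::sd)
    }
    if (any(scale <= 0 | !is.finite(scale))) {
      warning("degenerate channel(s): ",
              paste(colnames(xm)[scale <= 0 | !is.finite(scale)],
                    collapse = ", "), "; using scale 1")
      scale[scale <= 0 | !is.finite(scale)] <- 1
    }
    stats <- structure(list(offset = offset, scale = scale, method = method),
                       class = "norm_stats")
  } else {
    if (!inherits(stats, "norm_stats")) stop("stats must be a norm_stats object")
    if (ncol(xm) != length(stats$offset))
      stop("channel count does not match the stored normalisation statistics")
  }
  out <- sweep(sweep(xm, 2, stats$offset, "-"), 2, stats$scale, "/")
  list(data = out, stats = stats)
}

#' Invert a channel normalisation
#'
#' @param x normalised matrix.
#' @param stats a `norm_stats` object from [normalize_channels()].
#' @return Matrix on the original physical scale.
#' @export
denormalize_channels <- function(x, stats) {
  if (!inherits(stats, "norm_stats")) stop("stats must be a norm_stats object")
  xm <- as.matrix(x)
  sweep(sweep(xm, 2, stats$scale, "*"), 2, stats$offset, "+")
}

#' Align offline assay samples onto a target time grid
#'
#' Offline assays (e.g. 4-hourly wet-weight or HPLC measurements) are
#' brought onto the feature time grid by sliding-window local least
#' squares: for each target time the nearest `window` offline points are
#' fitted with a polynomial of the given degree and the fit is evaluated at
#' the target time. This smooths assay noise, unlike plain linear
#' interpolation. Extrapolation outside the offline time span is refused.
#'
#' @param t_offline offline sample times (h), strictly increasing.
#' @param y_offline offline sample values.
#' @param t_target target times (h), all within `range(t_offline)`.
#' @param window number of offline points per local fit (default 5).
#' @param degree polynomial degree of the local fit (default 2).
#' @return Numeric vector of aligned values at `t_target`.
#' @export
align_offline_samples <- function(t_offline, y_offline, t_target,
                                  window = 5L, degree = 2L) {
  if (length(t_offline) != length(y_offline))
    stop("t_offline and y_offline must have equal length")
  if (any(diff(t_offline) <= 0)) stop("t_offline must be strictly increasing")
  n <- length(t_offline)
  window <- min(as.integer(window), n)
  if (window < degree + 1L)
    stop("window must contain at least degree + 1 offline points")
  if (any(t_target < t_offline[1] - 1e-9) ||
      any(t_target > t_offline[n] + 1e-9))
    stop("extrapolation outside the offline time span is not supported")
  vapply(t_target, function(tt) {
    i0 <- which.min(abs(t_offline - tt))
    lo <- max(1L, min(i0 - window %/% 2L, n - window + 1L))
    idx <- lo:(lo + window - 1L)
    tc <- t_offline[idx] - tt   # centre so the intercept is the value at tt
    Xd <- outer(tc, 0:degree, `^`)
    stats::lm.fit(Xd, y_offline[idx])$coefficients[1]
  }, numeric(1))
}
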