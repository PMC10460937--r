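#' Count time series
#'
#' Assembles the per-frame mode counts of a trajectory into one time series
#' per mode and computes the summary statistics reported for such data: the
#' arithmetic mean count `mu` over all frames, the standard deviation of the
#' counts, and the Pearson correlation `C_{x-y} = <dCx dCy> /
#' sqrt(<dCx^2><dCy^2>)` between two modes, with `dCi = Ci - mu_i`.
#'
#' @name count_series
NULL

#' Build mode count time series from per-frame counts
#'
#' @param per_frame list of named count vectors as returned by
#'   [count_modes()] (attributes `step`, `time`), one per frame, in frame
#'   order.
#' @return object of class `count_series`: list with `steps`, `times`,
#'   `modes`, and an integer matrix `counts` (frames x modes).
#' @export
build_series <- function(per_frame) {
  if (!length(per_frame)) stop("structural error: no per-frame counts")
  modes <- names(per_frame[[1L]])
  if (is.null(modes) || !length(modes))
    stop("structural error: counts must be named by mode")
  for (i in seq_along(per_frame))
    if (!identical(names(per_frame[[i]]), modes))
      stop("structural error: inconsistent mode keys across frames (frame ",
           i, ")")
  counts <- do.call(rbind, lapply(per_frame, as.integer))
  colnames(counts) <- modes
  steps <- vapply(per_frame, function(x) {
    s <- attr(x, "step"); if (is.null(s)) NA_integer_ else as.integer(s)
  }, integer(1))
  times <- vapply(per_frame, function(x) {
    t <- attr(x, "time"); if (is.null(t)) NA_real_ else as.numeric(t)
  }, numeric(1))
  if (anyNA(times)) times <- as.numeric(seq_along(per_frame) - 1L)
  if (anyNA(steps)) steps <- seq_along(per_frame) - 1L
  structure(list(steps = steps, times = times, modes = modes,
                 counts = counts),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat(sprintf("<count_series> %d frames x %d modes, t = %g..%g ps\n",
              nrow(x$counts), length(x$modes), min(x$times), max(x$times)))
  invisible(x)
}

.sd_div <- function(v, divisor) {
  mu <- mean(v)
  ss <- sum((v - mu)^2)
  den <- if (divisor == "N") length(v) else max(length(v) - 1L, 1L)
  sqrt(ss / den)
}

#' Mean and deviation of each mode series
#'
#' @param series a [build_series()] object.
#' @param divisor `"N"` (population standard deviation, default) or
#'   `"N-1"` (sample).
#' @return data.frame with columns `mode`, `mean`, `deviation`.
#' @export
summarize_series <- function(series, divisor = c("N", "N-1")) {
  stopifnot(inherits(series, "count_series"))
  divisor <- match.arg(divisor)
  data.frame(mode = series$modes,
             mean = colMeans(series$counts),
             deviation = apply(series$counts, 2L, .sd_div, divisor = divisor),
             row.names = NULL)
}

#' Pearson correlation of two count series
#'
#' Returns `NA` (an explicit undefined marker, not 0) when either series is
#' constant; exactly 1 for a non-constant series against itself.
#'
#' @param x,y numeric vectors of equal length `>= 2`.
#' @return correlation in `[-1, 1]`, or `NA`.
#' @export
correlate_series <- function(x, y) {
  if (length(x) != length(y))
    stop("structural error: series lengths differ")
  if (length(x) < 2L) stop("need at least 2 frames to correlate")
  dx <- x - mean(x)
  dy <- y - mean(y)
  vx <- sum(dx * dx)
  vy <- sum(dy * dy)
  if (vx == 0 || vy == 0) return(NA_real_)
  r <- sum(dx * dy) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Mode-mode correlation matrix
#'
#' Symmetric matrix of pairwise Pearson correlations in the mode-set order;
#' the diagonal is exactly 1 for non-constant series and `NA` (undefined)
#' for constant ones.
#'
#' @param series a [build_series()] object.
#' @return numeric matrix with mode names on both dimensions.
#' @export
correlation_matrix <- function(series) {
  stopifnot(inherits(series, "count_series"))
  m <- length(series$modes)
  out <- matrix(NA_real_, m, m, dimnames = list(series$modes, series$modes))
  for (i in seq_len(m)) {
    ci <- series$counts[, i]
    out[i, i] <- if (all(ci == ci[1L])) NA_real_ else 1
    if (i < m) for (j in (i + 1L):m) {
      r <- correlate_series(ci, series$counts[, j])
      out[i, j] <- r
      out[j, i] <- r
    }
  }
  out
}
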