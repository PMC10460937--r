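#' CSV outputs
#'
#' Machine-readable exports of the pipeline: per-frame counts, per-mode
#' summary (mean and deviation), and the mode-mode correlation matrix.
#' Column headers carry the DANAI statements verbatim.  Report rounding
#' follows the published tables: 3 decimals for means and correlations,
#' 6 for deviations; `counts.csv` is exact integers.
#'
#' @name csv_io
NULL

#' @rdname csv_io
#' @param series a [build_series()] object.
#' @param path output file.
#' @export
write_counts_csv <- function(series, path) {
  stopifnot(inherits(series, "count_series"))
  df <- data.frame(step = series$steps, time_ps = series$times,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(series$counts, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname csv_io
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("step", "time_ps") %in% names(df)))
    stop("structural error: counts CSV needs 'step' and 'time_ps' columns")
  modes <- setdiff(names(df), c("step", "time_ps"))
  if (!length(modes)) stop("structural error: counts CSV has no mode columns")
  counts <- as.matrix(df[, modes, drop = FALSE])
  storage.mode(counts) <- "integer"
  structure(list(steps = as.integer(df$step), times = as.numeric(df$time_ps),
                 modes = modes, counts = counts),
            class = "count_series")
}

#' @rdname csv_io
#' @param divisor passed to [summarize_series()].
#' @export
write_summary_csv <- function(series, path, divisor = c("N", "N-1")) {
  sm <- summarize_series(series, divisor = match.arg(divisor))
  sm$mean <- round(sm$mean, 3L)
  sm$deviation <- round(sm$deviation, 6L)
  names(sm) <- c("mode", "average_count", "deviation")
  utils::write.csv(sm, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname csv_io
#' @export
write_correlation_csv <- function(series, path) {
  cm <- round(correlation_matrix(series), 3L)
  df <- data.frame(mode = rownames(cm), check.names = FALSE)
  df <- cbind(df, as.data.frame(cm, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "undefined")
  invisible(path)
}
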