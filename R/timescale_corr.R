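# Multi-timescale input-output correlation: resample the input to the output
# time axis, take differences of consecutive window means at several window
# widths, standardize, and correlate each compound against the input per
# width.

#' Resample a signal or trace onto a target time axis
#'
#' Linear interpolation between known points, exact at shared time points.
#' For a [step_signal()] the known points are the step boundary times and
#' their values, matching how a discretely tabulated input program is
#' interpolated onto a measured time axis.
#'
#' @param x A `step_signal`, or a list/data frame with numeric `times` and
#'   `values`.
#' @param target_times Times (seconds) at which to evaluate; must lie within
#'   the span of `x` (no extrapolation).
#' @return Numeric vector of interpolated values at `target_times`.
#' @export
resample_to <- function(x, target_times) {
  if (inherits(x, "step_signal")) {
    times <- x$step_times
    values <- x$values
  } else {
    times <- x$times
    values <- x$values
    if (is.null(times) || is.null(values))
      stop("`x` must be a step_signal or have `times` and `values`",
           call. = FALSE)
  }
  if (any(target_times < min(times) | target_times > max(times)))
    stop("target times extend beyond the signal span (extrapolation refused)",
         call. = FALSE)
  stats::approx(times, values, xout = target_times, method = "linear",
                ties = "ordered")$y
}

#' Windowed differential of a time trace
#'
#' Partitions the time axis into consecutive non-overlapping windows of width
#' `window_width` starting at the first sample time, averages the samples in
#' each window, and returns the first differences of those means: one value
#' per window transition, measuring how the signal changes on average at that
#' timescale. A trailing window not fully covered by the span is dropped.
#' With `stride` smaller than `window_width` the windows overlap (sliding
#' mode) and differences are taken between means one full window apart.
#'
#' @param values Numeric trace values.
#' @param times Sample times in seconds (same length, strictly increasing).
#' @param window_width Window width in seconds; the span must cover at least
#'   two windows.
#' @param stride Window start spacing in seconds; default `window_width`
#'   (consecutive tiling windows).
#' @return Object of class `differential_vector`: numeric differences with
#'   attributes `window_width`, `stride` and `window_means`.
#' @examples
#' windowed_differential(c(1, 2, 4, 4, 6, 8), seq(0, 150, 30), 60)
#' @export
windowed_differential <- function(values, times, window_width,
                                  stride = window_width) {
  if (length(values) != length(times))
    stop("`values` and `times` must have equal length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  span <- times[length(times)] - times[1] + (times[2] - times[1])
  if (span < 2 * window_width)
    stop("trace span must cover at least two windows", call. = FALSE)
  t0 <- times[1]
  starts <- seq(t0, by = stride,
                length.out = floor((span - window_width) / stride) + 1)
  counts <- vapply(starts, function(s) {
    sum(times >= s & times < s + window_width)
  }, numeric(1))
  # trailing windows left empty by sampling-grid drift are dropped; an empty
  # window in the interior of the span is an error
  n_keep <- length(counts)
  while (n_keep > 0 && counts[n_keep] == 0) n_keep <- n_keep - 1L
  if (n_keep < length(counts)) {
    message(sprintf("dropping %d trailing empty window(s) of width %g s",
                    length(counts) - n_keep, window_width))
    starts <- starts[seq_len(n_keep)]
    counts <- counts[seq_len(n_keep)]
  }
  if (any(counts == 0)) {
    s <- starts[which(counts == 0)[1]]
    stop(sprintf("window [%g, %g) contains no samples", s, s + window_width),
         call. = FALSE)
  }
  means <- vapply(starts, function(s) {
    mean(values[times >= s & times < s + window_width])
  }, numeric(1))
  lag <- max(1L, as.integer(round(window_width / stride)))
  if (length(means) <= lag)
    stop("not enough windows to form a differential", call. = FALSE)
  diffs <- means[seq(lag + 1, length(means))] - means[seq_len(length(means) - lag)]
  structure(diffs, class = "differential_vector",
            window_width = window_width, stride = stride,
            window_means = means)
}

#' Standardize a differential vector
#'
#' Mean-centres and scales by the population standard deviation (divisor
#' `n`), yielding a dimensionless vector with mean 0 and SD 1.
#'
#' @param x A `differential_vector` or numeric vector with at least two
#'   distinct values.
#' @return Numeric vector of z-scores (class `normalized_differential`,
#'   attribute `window_width` preserved when present).
#' @export
normalize_differential <- function(x) {
  v <- as.numeric(x)
  s <- pop_sd(v)
  if (s == 0)
    stop("differential is constant; normalization undefined", call. = FALSE)
  structure((v - mean(v)) / s, class = "normalized_differential",
            window_width = attr(x, "window_width"))
}

#' Per-timescale Pearson correlation of compound traces against the input
#'
#' For each window width, the input signal is resampled onto the trace time
#' axis, both input and compound traces are reduced to standardized windowed
#' differentials, and the Pearson correlation between the input and each
#' compound differential is computed. Positive values mean the compound moves
#' with the input at that timescale; negative values mean it moves against
#' it.
#'
#' @param input A `step_signal` (e.g. the implied Ca(OH)2 inlet program) or a
#'   `times`/`values` list covering the trace time axis.
#' @param traces A `trace_set` (see [trace_set()]).
#' @param window_widths Window widths in seconds (default
#'   `c(30, 60, 90, 120, 150)`).
#' @param stride Optional window stride for overlapping (sliding) windows;
#'   default consecutive tiling.
#' @return A matrix of class `correlation_map`: compounds in rows, window
#'   widths in columns, Pearson r in `[-1, 1]`.
#' @export
timescale_correlations <- function(input, traces,
                                   window_widths = c(30, 60, 90, 120, 150),
                                   stride = NULL) {
  stopifnot(inherits(traces, "trace_set"))
  times <- traces$times
  v_in_raw <- resample_to(input, times)
  m <- traces$concentrations
  r <- matrix(NA_real_, nrow(m), length(window_widths),
              dimnames = list(rownames(m), as.character(window_widths)))
  for (wi in seq_along(window_widths)) {
    w <- window_widths[wi]
    st <- if (is.null(stride)) w else stride
    v_in <- normalize_differential(
      windowed_differential(v_in_raw, times, w, stride = st))
    for (ci in seq_len(nrow(m))) {
      v_out <- tryCatch(
        normalize_differential(
          windowed_differential(m[ci, ], times, w, stride = st)),
        error = function(e) {
          stop(sprintf("compound %s, window %g s: %s",
                       rownames(m)[ci], w, conditionMessage(e)),
               call. = FALSE)
        }
      )
      # both vectors are z-scores, so Pearson r is their mean product
      r[ci, wi] <- min(max(mean(v_in * v_out), -1), 1)
    }
  }
  class(r) <- c("correlation_map", "matrix")
  r
}

#' Write a correlation map to CSV
#'
#' Rows are compounds, columns are window widths in seconds.
#'
#' @param cmap A `correlation_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_correlation_map <- function(cmap, path) {
  df <- data.frame(compound = rownames(cmap), unclass(cmap),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
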