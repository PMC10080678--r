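# GC-MS-style quantification: quadratic peak-area calibration, averaged
# calibration fallback for uncalibrated compounds, and largest-peak selection.
# A forward model (concentrations -> synthetic peak areas) is included so the
# whole pipeline can be exercised end to end without chromatograms.

#' Quadratic calibration curve
#'
#' Maps a peak integral `A` to a concentration `a A^2 + b A + c` (mM). The
#' curve must be monotone increasing over its working range `[0, A_max]`;
#' non-monotone curves are rejected at construction rather than silently
#' used.
#'
#' @param compound_id Compound identifier.
#' @param a,b,c Quadratic coefficients.
#' @param A_max Upper end of the working peak-integral range (default 100).
#' @param averaged Logical flag: `TRUE` when built as the mean of similar-
#'   weight calibrations (see [averaged_curve()]).
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(compound_id, a, b, c = 0, A_max = 100,
                              averaged = FALSE) {
  if (A_max <= 0) stop("`A_max` must be positive", call. = FALSE)
  # derivative 2aA + b must stay positive on [0, A_max]
  if (min(b, 2 * a * A_max + b) <= 0)
    stop(sprintf("curve for %s is not monotone increasing on [0, %g]",
                 compound_id, A_max), call. = FALSE)
  structure(
    list(compound_id = compound_id, a = a, b = b, c = c, A_max = A_max,
         averaged = averaged),
    class = "calibration_curve"
  )
}

#' Evaluate a calibration curve
#' @param curve A `calibration_curve`.
#' @param A Peak integral(s).
#' @return Concentration(s) in mM.
#' @export
apply_curve <- function(curve, A) {
  curve$a * A^2 + curve$b * A + curve$c
}

# invert a monotone quadratic on [0, A_max]: find A with a A^2 + b A + c = conc
invert_curve <- function(curve, conc) {
  vapply(conc, function(y) {
    if (curve$a == 0) {
      A <- (y - curve$c) / curve$b
    } else {
      disc <- curve$b^2 - 4 * curve$a * (curve$c - y)
      if (disc < 0)
        stop(sprintf("curve for %s is not invertible at %.4g mM",
                     curve$compound_id, y), call. = FALSE)
      # increasing branch of the parabola
      A <- (-curve$b + sqrt(disc)) / (2 * curve$a)
    }
    if (is.na(A) || A < -1e-9 || A > curve$A_max * (1 + 1e-9))
      stop(sprintf(
        "concentration %.4g mM maps outside the working range of %s",
        y, curve$compound_id), call. = FALSE)
    max(A, 0)
  }, numeric(1))
}

#' Average calibration curves of compounds with similar molecular weight
#'
#' Coefficient-wise arithmetic mean of two or more curves; used when a
#' compound (e.g. a branched C4-C6 sugar) has no authentic calibration of its
#' own. The result carries `averaged = TRUE`.
#'
#' @param curves List of `calibration_curve` objects (length >= 2; pass the
#'   same curve twice to adopt it verbatim).
#' @param compound_id Identifier for the averaged curve (default
#'   `"averaged"`).
#' @return A `calibration_curve` with the mean coefficients, the smallest
#'   `A_max`, and the averaged flag set.
#' @export
averaged_curve <- function(curves, compound_id = "averaged") {
  if (!is.list(curves) || length(curves) < 2L)
    stop("need at least two curves to average", call. = FALSE)
  if (!all(vapply(curves, inherits, logical(1), "calibration_curve")))
    stop("all inputs must be calibration_curve objects", call. = FALSE)
  calibration_curve(
    compound_id,
    a = mean(vapply(curves, `[[`, numeric(1), "a")),
    b = mean(vapply(curves, `[[`, numeric(1), "b")),
    c = mean(vapply(curves, `[[`, numeric(1), "c")),
    A_max = min(vapply(curves, `[[`, numeric(1), "A_max")),
    averaged = TRUE
  )
}

#' Read a calibration table from CSV
#'
#' Expected columns: `compound_id`, `a`, `b`, `c`, and optionally `mw_class`
#' (a molecular-weight grouping label, e.g. carbon count) and `A_max`.
#' Compounds listed in `fallback_ids` (or absent rows requested later) can be
#' served by [averaged_curve()] over an `mw_class`.
#'
#' @param path CSV file path.
#' @return Named list of `calibration_curve` objects; attribute `mw_class`
#'   holds the grouping labels when present.
#' @export
read_calibration_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("compound_id", "a", "b", "c")
  if (!all(need %in% names(df)))
    stop("calibration CSV must have columns compound_id, a, b, c",
         call. = FALSE)
  if (!"A_max" %in% names(df)) df$A_max <- 100
  curves <- lapply(seq_len(nrow(df)), function(i) {
    calibration_curve(df$compound_id[i], df$a[i], df$b[i], df$c[i],
                      A_max = df$A_max[i])
  })
  names(curves) <- df$compound_id
  if ("mw_class" %in% names(df))
    attr(curves, "mw_class") <- stats::setNames(df$mw_class, df$compound_id)
  curves
}

#' Build a peak table from measured peak integrals
#'
#' @param sample_id Sample identifier.
#' @param compound_id Compound id per row.
#' @param peak_integral Non-negative peak integrals; a compound may appear on
#'   several rows (multiple chromatographic peaks).
#' @param peak_index Optional peak index per row.
#' @return A data frame of class `peak_table`.
#' @export
peak_table <- function(sample_id, compound_id, peak_integral,
                       peak_index = seq_along(peak_integral)) {
  if (any(peak_integral < 0))
    stop("peak integrals must be non-negative", call. = FALSE)
  structure(
    data.frame(sample_id = sample_id, compound_id = compound_id,
               peak_integral = peak_integral, peak_index = peak_index),
    class = c("peak_table", "data.frame")
  )
}

#' Quantify a peak table with calibration curves
#'
#' For each compound, the largest peak integral is converted to a
#' concentration with that compound's curve. Compounds without a curve fall
#' back to the averaged curve of their molecular-weight class when
#' `mw_class` metadata is available; otherwise quantification fails. Negative
#' quantified concentrations are floored at zero with a warning.
#'
#' @param peaks A `peak_table`.
#' @param curves Named list of `calibration_curve` objects (optionally with an
#'   `mw_class` attribute from [read_calibration_table()]).
#' @return Data frame with `sample_id`, `compound_id`, `peak_integral` (the
#'   selected largest peak), `concentration_mM`, and `curve_averaged`.
#' @export
quantify <- function(peaks, curves) {
  stopifnot(is.data.frame(peaks))
  mw <- attr(curves, "mw_class")
  key <- interaction(peaks$sample_id, peaks$compound_id, drop = TRUE)
  picked <- do.call(rbind, lapply(split(peaks, key), function(g) {
    g[which.max(g$peak_integral), , drop = FALSE]
  }))
  out <- picked[order(picked$sample_id, picked$compound_id),
                c("sample_id", "compound_id", "peak_integral")]
  rownames(out) <- NULL
  conc <- numeric(nrow(out))
  averaged <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    id <- out$compound_id[i]
    curve <- curves[[id]]
    if (is.null(curve)) {
      if (is.null(mw) || !(id %in% names(mw)))
        stop(sprintf("no calibration curve for %s and no fallback class", id),
             call. = FALSE)
      peers <- names(mw)[mw == mw[[id]] & names(mw) %in% names(curves) &
                           names(mw) != id]
      if (length(peers) < 2L)
        stop(sprintf(
          "no calibration curve for %s and fewer than two class peers", id),
          call. = FALSE)
      curve <- averaged_curve(curves[peers], compound_id = id)
    }
    conc[i] <- apply_curve(curve, out$peak_integral[i])
    averaged[i] <- curve$averaged
  }
  if (any(conc < 0)) {
    warning(sprintf("%d negative quantified concentration(s) floored at 0",
                    sum(conc < 0)))
    conc <- pmax(conc, 0)
  }
  out$concentration_mM <- conc
  out$curve_averaged <- averaged
  out
}

#' Forward model: synthesize peak tables from a trace set
#'
#' Numerically inverts each compound's calibration curve so that
#' `quantify(synthesize_peaks(traces))` recovers the traces exactly on
#' noiseless data. One peak table per sampling time.
#'
#' @param traces A `trace_set`.
#' @param curves Named list of `calibration_curve` objects covering all
#'   compounds in `traces`.
#' @return A single `peak_table` data frame covering all samples; sample ids
#'   are `S001, S002, ...` in time order, with a `time_s` column appended.
#' @export
synthesize_peaks <- function(traces, curves) {
  stopifnot(inherits(traces, "trace_set"))
  ids <- rownames(traces$concentrations)
  missing <- setdiff(ids, names(curves))
  if (length(missing))
    stop("no calibration curve for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  n_t <- length(traces$times)
  rows <- lapply(seq_len(n_t), function(j) {
    areas <- vapply(ids, function(id) {
      invert_curve(curves[[id]], traces$concentrations[id, j])
    }, numeric(1))
    data.frame(sample_id = sprintf("S%03d", j), compound_id = ids,
               peak_integral = areas, peak_index = 1L,
               time_s = traces$times[j])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}
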