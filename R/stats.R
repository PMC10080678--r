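# Distribution comparisons across experimental conditions with the
# significance-star annotation used on the concentration-distribution panels.

#' Two-sided p-value for a difference in mean concentration
#'
#' Default test is Welch's unequal-variance t test; a Mann-Whitney
#' (Wilcoxon rank-sum) option is provided. When both samples are constant
#' and equal the difference is identically zero and p = 1 by convention.
#'
#' @param a,b Numeric samples of concentrations, each of length >= 3.
#' @param method `"welch"` (default) or `"mann-whitney"`.
#' @return A p-value in `(0, 1]` (clamped below at machine precision).
#' @export
compare_means <- function(a, b, method = c("welch", "mann-whitney")) {
  method <- match.arg(method)
  if (length(a) < 3L || length(b) < 3L)
    stop("each sample needs at least 3 observations", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      message("both samples constant and equal; p = 1 by convention")
      return(1)
    }
    # constant but different: the difference is exact
    return(.Machine$double.eps)
  }
  p <- switch(method,
    welch = stats::t.test(a, b, var.equal = FALSE)$p.value,
    `mann-whitney` = stats::wilcox.test(a, b, exact = FALSE)$p.value
  )
  min(max(p, .Machine$double.eps), 1)
}

#' Significance stars for a p-value
#'
#' Bins: `ns` for p > 5e-2; `*` for 1e-2 < p <= 5e-2; `**` for
#' 1e-3 < p <= 1e-2; `***` for 1e-4 < p <= 1e-3; `****` for p <= 1e-4.
#' Boundaries are inclusive on the more significant side.
#'
#' @param p P-value(s) in `(0, 1]`.
#' @return Character vector of star annotations.
#' @export
star_annotation <- function(p) {
  if (any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  vapply(p, function(pi) {
    if (pi <= 1e-4) "****"
    else if (pi <= 1e-3) "***"
    else if (pi <= 1e-2) "**"
    else if (pi <= 5e-2) "*"
    else "ns"
  }, character(1))
}

#' Pairwise condition comparison report
#'
#' For every compound shared by all conditions and every unordered pair of
#' conditions, reports per-condition mean and SD of the sampled
#' concentrations, the p-value of [compare_means()], and its star
#' annotation. This reproduces the layout of per-compound distribution
#' comparison panels: every timepoint sample is treated as a replicate (the
#' autocorrelation of consecutive samples is not corrected for).
#'
#' @param tracesets Named list of `trace_set` objects, one per condition,
#'   sharing identical compound ids.
#' @param method Test passed to [compare_means()].
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; default `"none"` (per-panel annotation convention);
#'   `"BH"` enables Benjamini-Hochberg across the whole report.
#' @return A data frame with columns `compound_id`, `condition_a`,
#'   `condition_b`, `n_a`, `mean_a`, `sd_a`, `n_b`, `mean_b`, `sd_b`,
#'   `p_value`, `stars`, ordered by compound then condition pair.
#' @export
condition_report <- function(tracesets, method = "welch",
                             p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (!is.list(tracesets) || length(tracesets) < 2L)
    stop("need at least two conditions", call. = FALSE)
  if (is.null(names(tracesets)) || any(names(tracesets) == ""))
    stop("`tracesets` must be a named list of conditions", call. = FALSE)
  ids <- lapply(tracesets, function(ts) rownames(ts$concentrations))
  ref <- ids[[1]]
  for (k in seq_along(ids)[-1]) {
    extra <- setdiff(ids[[k]], ref)
    miss <- setdiff(ref, ids[[k]])
    if (length(extra) || length(miss))
      stop(sprintf(
        "condition %s compound set differs (missing: %s; extra: %s)",
        names(tracesets)[k],
        paste(miss, collapse = ","), paste(extra, collapse = ",")),
        call. = FALSE)
  }
  conds <- names(tracesets)
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  rows <- list()
  for (cmp in sort(ref)) {
    for (pr in pairs) {
      a <- tracesets[[pr[1]]]$concentrations[cmp, ]
      b <- tracesets[[pr[2]]]$concentrations[cmp, ]
      p <- compare_means(a, b, method = method)
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = cmp, condition_a = pr[1], condition_b = pr[2],
        n_a = length(a), mean_a = mean(a), sd_a = stats::sd(a),
        n_b = length(b), mean_b = mean(b), sd_b = stats::sd(b),
        p_value = p, stars = NA_character_
      )
    }
  }
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$stars <- star_annotation(out$p_value)
  out
}
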