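# Hierarchical clustering of concentration time traces with correlation
# distance and size-weighted average linkage. The merge height convention is
# d(A, B) / 2: each child sits at half the inter-cluster distance, so heights
# are half those reported by conventional UPGMA implementations.

#' Correlation distance between two time traces
#'
#' `d = 1 - cor(u, v)` computed from mean-centred vectors: 0 for traces of
#' identical shape, 2 for perfectly anticorrelated traces. Constant traces
#' have no defined correlation and raise an error rather than propagating NaN.
#'
#' @param u,v Numeric vectors of equal length (>= 3), neither constant.
#' @return Distance in `[0, 2]`.
#' @examples
#' correlation_distance(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 0.2
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v) || length(u) < 3L)
    stop("traces must have equal length >= 3", call. = FALSE)
  uc <- u - mean(u)
  vc <- v - mean(v)
  nu <- sqrt(sum(uc^2))
  nv <- sqrt(sum(vc^2))
  if (nu == 0 || nv == 0)
    stop("correlation distance is undefined for a constant trace",
         call. = FALSE)
  d <- 1 - sum(uc * vc) / (nu * nv)
  min(max(d, 0), 2) # guard rounding at the boundaries
}

#' Pairwise correlation-distance matrix of a trace set
#'
#' @param traces A `trace_set` (see [trace_set()]) or a numeric matrix with
#'   one row per compound and one column per time point (row names used as
#'   labels).
#' @return A symmetric matrix of class `dist_matrix` with zero diagonal and
#'   compound ids as dimnames.
#' @export
pairwise_distances <- function(traces) {
  m <- if (inherits(traces, "trace_set")) traces$concentrations else traces
  if (!is.matrix(m) || nrow(m) < 2L)
    stop("need a matrix of at least two traces", call. = FALSE)
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("trace", seq_len(nrow(m)))
  constant <- apply(m, 1, function(x) pop_sd(x) == 0)
  if (any(constant))
    stop("constant trace(s), correlation distance undefined: ",
         paste(labels[constant], collapse = ", "), call. = FALSE)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      d[i, j] <- d[j, i] <- correlation_distance(m[i, ], m[j, ])
    }
  }
  class(d) <- c("dist_matrix", "matrix")
  d
}

#' Average-linkage (UPGMA) dendrogram with proportional distance update
#'
#' Agglomerates the two closest clusters at each step. After merging `A` and
#' `B`, the distance to any other cluster `Y` is the size-weighted mean
#' `(|A| d(A,Y) + |B| d(B,Y)) / (|A| + |B|)`. The merge height is recorded as
#' `d(A, B) / 2` (each child is placed at half the merge distance). Exact
#' ties are broken toward the lowest pair of cluster indices, in creation
#' order; this is documented because merge order on ties can differ between
#' implementations.
#'
#' @param d A `dist_matrix` from [pairwise_distances()] or any symmetric
#'   non-negative matrix with zero diagonal.
#' @return An object of class `formose_dendrogram`: list with `merge` (an
#'   `hclust`-convention merge matrix: negative entries index leaves),
#'   `height` (merge heights, `d/2` convention), `labels`, and `sizes`
#'   (cluster size after each merge).
#' @export
average_linkage <- function(d) {
  d <- unclass(d)
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 2L)
    stop("`d` must be a square matrix with n >= 2", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0) || any(d < 0))
    stop("`d` must be symmetric, non-negative, with zero diagonal",
         call. = FALSE)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("trace", seq_len(n))

  # active clusters: id < 0 -> leaf -id; id > 0 -> merge row id
  ids <- -seq_len(n)
  sizes <- rep(1L, n)
  work <- d
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  merge_sizes <- integer(n - 1)

  for (step in seq_len(n - 1)) {
    m <- length(ids)
    # closest active pair; ties -> smallest (i, j) in creation order
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (i in seq_len(m - 1)) {
      for (j in seq((i + 1), m)) {
        if (work[i, j] < best_d) {
          best_d <- work[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    a <- ids[i]; b <- ids[j]
    merge[step, ] <- if (a < b) c(a, b) else c(b, a)
    height[step] <- best_d / 2
    new_size <- sizes[i] + sizes[j]
    merge_sizes[step] <- new_size

    # proportional-average update against all remaining clusters
    others <- setdiff(seq_len(m), c(i, j))
    new_row <- (sizes[i] * work[i, others] + sizes[j] * work[j, others]) /
      new_size
    work <- work[others, others, drop = FALSE]
    work <- rbind(cbind(work, new_row), c(new_row, 0))
    ids <- c(ids[others], step)
    sizes <- c(sizes[others], new_size)
  }

  structure(
    list(merge = merge, height = height, labels = labels,
         sizes = merge_sizes),
    class = "formose_dendrogram"
  )
}

#' @export
print.formose_dendrogram <- function(x, ...) {
  cat(sprintf("<formose_dendrogram> %d leaves, %d merges, heights %.4g-%.4g\n",
              length(x$labels), nrow(x$merge), min(x$height), max(x$height)))
  inv <- sum(diff(x$height) < -1e-12)
  if (inv > 0)
    cat(sprintf("  note: %d height inversion(s) present\n", inv))
  invisible(x)
}

#' Convert a dendrogram to a base-R `hclust` object
#'
#' Heights keep the `d/2` convention of [average_linkage()]; multiply by two
#' to compare with `stats::hclust(..., method = "average")`.
#'
#' @param dend A `formose_dendrogram`.
#' @return An `hclust` object (plottable with `plot()`).
#' @export
as_hclust <- function(dend) {
  stopifnot(inherits(dend, "formose_dendrogram"))
  n <- length(dend$labels)
  hc <- list(merge = dend$merge, height = dend$height,
             order = dendrogram_order(dend$merge, n),
             labels = dend$labels, method = "average",
             call = match.call(), dist.method = "correlation")
  class(hc) <- "hclust"
  hc
}

# leaf order for plotting: left-to-right traversal of the merge tree
dendrogram_order <- function(merge, n) {
  expand <- function(id) {
    if (id < 0) return(-id)
    c(expand(merge[id, 1]), expand(merge[id, 2]))
  }
  expand_row <- expand(nrow(merge))
  stopifnot(length(expand_row) == n)
  expand_row
}

#' Cut a dendrogram into flat clusters
#'
#' Either `k` clusters (by undoing the last `k - 1` merges, i.e. merge
#' truncation, which is well defined even when correlation-distance heights
#' invert) or all merges with height at or below `h`.
#'
#' @param dend A `formose_dendrogram`.
#' @param k Number of clusters (1 to number of leaves), or `NULL`.
#' @param h Height threshold (used when `k` is `NULL`).
#' @return An object of class `cluster_assignment`: a named integer vector of
#'   cluster labels (1-based, numbered by first appearance in leaf order)
#'   with attribute `cut` recording the parameter used.
#' @export
cut_clusters <- function(dend, k = NULL, h = NULL) {
  stopifnot(inherits(dend, "formose_dendrogram"))
  n <- length(dend$labels)
  if (is.null(k) && is.null(h))
    stop("supply `k` or `h`", call. = FALSE)
  if (!is.null(k)) {
    if (k < 1 || k > n) stop("`k` out of range [1, n]", call. = FALSE)
    apply_rows <- seq_len(n - k)
    cut_used <- list(type = "k", value = k)
  } else {
    apply_rows <- which(dend$height <= h)
    cut_used <- list(type = "height", value = h)
  }

  # union-find over leaves, applying the selected merges in order
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  cluster_root <- integer(nrow(dend$merge)) # root leaf of each merged cluster
  for (row in seq_len(nrow(dend$merge))) {
    members <- function(id) if (id < 0) -id else cluster_root[id]
    a <- find(members(dend$merge[row, 1]))
    b <- find(members(dend$merge[row, 2]))
    if (row %in% apply_rows) parent[b] <- a
    cluster_root[row] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  labels_int <- match(roots, unique(roots))
  names(labels_int) <- dend$labels
  structure(labels_int, class = "cluster_assignment", cut = cut_used)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cut <- attr(x, "cut")
  cat(sprintf("<cluster_assignment> %d clusters over %d compounds (cut: %s = %g)\n",
              length(unique(unclass(x))), length(x), cut$type, cut$value))
  print(split(names(x), unclass(x)))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two flat clusterings of the same items:
#' 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Cluster label vectors of equal length (any label type).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions must cover the same items", call. = FALSE)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  total <- comb2(length(a))
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
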