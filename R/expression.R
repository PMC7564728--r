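# Expression profiling: log2 transformation and average-linkage clustering
# of FPKM matrices into heatmap-ready form, plus RT-PCR band quantification
# relative to a reference gene with a two-sample t-test.

#' Log2-transform an expression matrix
#'
#' `x -> log2(x + pseudo_count)`.  FPKM matrices contain exact zeros, so a
#' pseudo-count (default 1, which maps 0 to 0 and keeps the transform
#' monotone) is applied inside the logarithm.
#'
#' @param mat non-negative numeric matrix.
#' @param pseudo_count positive offset added before the logarithm.
#' @return matrix of the same shape.
#' @export
log2_normalize <- function(mat, pseudo_count = 1) {
  if (any(mat < 0)) stop("negative expression values are not allowed")
  stopifnot(pseudo_count > 0)
  log2(mat + pseudo_count)
}

#' Per-row min-max scaling to [0, 1]
#'
#' Display scaling for heatmaps; constant rows map to 0.
#'
#' @param mat numeric matrix.
#' @return row-scaled matrix.
#' @export
scale_rows <- function(mat) {
  t(apply(mat, 1L, function(x) {
    r <- diff(range(x))
    if (r == 0) rep(0, length(x)) else (x - min(x)) / r
  }))
}

#' Average-linkage hierarchical clustering of matrix rows
#'
#' Agglomerative clustering with average linkage (UPGMA) on Euclidean row
#' distances (Pearson-correlation distance, `1 - r`, behind a flag),
#' producing the leaf ordering and merge heights used to arrange heatmap
#' rows.
#'
#' @param mat numeric matrix with at least 2 rows.
#' @param metric `"euclidean"` (default) or `"pearson"`.
#' @return list with `order` (leaf ordering as row indices), `labels`
#'   (row names in leaf order), `merge`, `height` (as in
#'   [stats::hclust()]) and `hclust` (the full object).
#' @export
cluster_rows <- function(mat, metric = c("euclidean", "pearson")) {
  metric <- match.arg(metric)
  if (nrow(mat) < 2L) stop("clustering requires at least 2 rows")
  d <- if (metric == "euclidean") {
    stats::dist(mat)
  } else {
    stats::as.dist(1 - stats::cor(t(mat)))
  }
  hc <- stats::hclust(d, method = "average")
  list(order = hc$order,
       labels = if (!is.null(rownames(mat))) rownames(mat)[hc$order] else hc$order,
       merge = hc$merge, height = hc$height, hclust = hc)
}

#' RT-PCR expression relative to a reference gene
#'
#' Band intensity divided by the reference-gene (e.g. actin) band intensity
#' from the same sample.
#'
#' @param intensity band intensity (>= 0).
#' @param reference_intensity reference-gene band intensity (> 0).
#' @return ratio vector.
#' @export
relative_expression <- function(intensity, reference_intensity) {
  if (any(intensity < 0)) stop("negative band intensity")
  if (any(reference_intensity <= 0)) {
    stop("reference intensity must be positive")
  }
  intensity / reference_intensity
}

#' Two-sample comparison of relative-expression ratios
#'
#' Classic equal-variance (pooled) two-sample Student's t-test with
#' `df = n_a + n_b - 2` and a two-sided p-value; the Welch unequal-variance
#' variant is available behind a flag.
#'
#' @param a,b numeric samples, each of size >= 2, with non-degenerate
#'   pooled variance.
#' @param welch use the Welch test instead of the pooled-variance test.
#' @param alpha significance level for the `significant` flag.
#' @return list with `t`, `df`, `p_value`, `significant`.
#' @export
compare_groups <- function(a, b, welch = FALSE, alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 observations")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate samples: both groups have zero variance")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, significant = ht$p.value < alpha)
}
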