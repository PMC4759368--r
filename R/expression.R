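#' Construct an expression matrix with sample metadata
#'
#' @param values Non-negative numeric matrix, genes in rows (rownames are
#'   gene ids), samples in columns.
#' @param samples Data.frame with `sample_id`, `condition`, `time`,
#'   `replicate`, one row per column of `values`; the
#'   (condition, time, replicate) triplets must be unique.
#' @return Object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples) {
  values <- as.matrix(values)
  samples <- as.data.frame(samples)
  req <- c("sample_id", "condition", "time", "replicate")
  if (!all(req %in% names(samples))) {
    stop("`samples` must have columns: ", paste(req, collapse = ", "))
  }
  if (ncol(values) != nrow(samples)) {
    stop("`values` columns and `samples` rows differ in number")
  }
  if (is.null(rownames(values))) stop("`values` must have gene-id rownames")
  if (anyDuplicated(samples[, c("condition", "time", "replicate")])) {
    stop("duplicate (condition, time, replicate) triplet")
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression intensities must be non-negative")
  colnames(values) <- samples$sample_id
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%d condition/time groups)\n",
              nrow(x$values), ncol(x$values),
              nrow(unique(x$samples[, c("condition", "time")]))))
  invisible(x)
}

#' Average expression over replicates
#'
#' Arithmetic mean per gene and (condition, time) group.
#'
#' @param matrix An [expr_matrix()].
#' @return List of class `expr_means` with `values` (genes x groups matrix,
#'   columns named `condition_t<time>`) and `groups` (data.frame
#'   `condition`, `time`).
#' @export
replicate_average <- function(matrix) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (anyNA(matrix$values)) {
    bad <- which(is.na(matrix$values), arr.ind = TRUE)[1, ]
    stop(sprintf("missing expression value for gene '%s' in sample '%s'",
                 rownames(matrix$values)[bad[1]],
                 colnames(matrix$values)[bad[2]]))
  }
  key <- paste0(matrix$samples$condition, "_t", matrix$samples$time)
  groups <- unique(data.frame(key = key,
                              condition = matrix$samples$condition,
                              time = matrix$samples$time,
                              stringsAsFactors = FALSE))
  means <- do.call(cbind, lapply(groups$key, function(k) {
    rowMeans(matrix$values[, key == k, drop = FALSE])
  }))
  dimnames(means) <- list(rownames(matrix$values), groups$key)
  structure(list(values = means,
                 groups = groups[, c("condition", "time")]),
            class = "expr_means")
}

#' Log2 ratios relative to the time-course average
#'
#' Per gene, each column's mean intensity is divided by the average
#' intensity across all columns (`ref = "timecourse"`) or by a designated
#' control column (`ref = "control"`), and the ratio is returned on the
#' log2 scale.  With the time-course reference the per-gene mean of the
#' pre-log ratios is exactly 1 by construction.
#'
#' @param means An `expr_means` object or a positive numeric matrix (genes
#'   x condition/time columns).
#' @param ref `"timecourse"` (default) or `"control"`.
#' @param control Column name or index of the control when
#'   `ref = "control"`.
#' @return Numeric matrix of log2 ratios with the input dimnames.
#' @examples
#' relative_log2_ratio(matrix(c(2, 4, 6), 1,
#'                            dimnames = list("g1", c("t0", "t1", "t2"))))
#' @export
relative_log2_ratio <- function(means, ref = c("timecourse", "control"),
                                control = NULL) {
  ref <- match.arg(ref)
  v <- if (inherits(means, "expr_means")) means$values else as.matrix(means)
  if (any(v <= 0)) {
    stop(paste0("zero or negative mean intensity: log ratio undefined ",
                "(consider a pseudocount before calling)"))
  }
  denom <- if (ref == "timecourse") {
    rowMeans(v)
  } else {
    if (is.null(control)) stop("`control` column required when ref='control'")
    v[, control]
  }
  log2(v / denom)
}

#' Select the most changed genes
#'
#' Keeps genes whose largest absolute log2 ratio reaches
#' `log2(fold_threshold)`, ranks them by that maximum (descending, ties by
#' gene id) and returns the top `n` ids.
#'
#' @param ratio_matrix Log2 ratio matrix with gene rownames.
#' @param fold_threshold Minimum fold change (>= 1) on the linear scale.
#' @param n Maximum number of genes to return.
#' @return Character vector of gene ids, ranked.
#' @export
select_top_genes <- function(ratio_matrix, fold_threshold = 5, n = 135) {
  ratio_matrix <- as.matrix(ratio_matrix)
  if (fold_threshold < 1) stop("`fold_threshold` must be >= 1")
  if (nrow(ratio_matrix) == 0) return(character())
  score <- apply(abs(ratio_matrix), 1, max)
  keep <- score >= log2(fold_threshold)
  ids <- rownames(ratio_matrix)[keep]
  sc <- score[keep]
  ids <- ids[order(-sc, ids)]
  utils::head(ids, n)
}

#' Hierarchical clustering of gene expression profiles
#'
#' Agglomerative clustering of log2 ratio profiles (Euclidean distance,
#' average linkage by default -- the conventional heatmap defaults), with
#' the tree cut into `k` groups.
#'
#' @param ratio_matrix Log2 ratio matrix with gene rownames.
#' @param k Number of groups (<= number of genes).
#' @param method Linkage passed to [stats::hclust()].
#' @return Named integer vector of group labels (1..k) per gene.
#' @export
cluster_genes <- function(ratio_matrix, k = 6, method = "average") {
  ratio_matrix <- as.matrix(ratio_matrix)
  if (k > nrow(ratio_matrix)) {
    stop(sprintf("k = %d exceeds the %d available genes", k,
                 nrow(ratio_matrix)))
  }
  hc <- stats::hclust(stats::dist(ratio_matrix), method = method)
  stats::cutree(hc, k = k)
}
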