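#' Filter low-expression genes
#'
#' Drops genes whose summary expression falls below a floor before network
#' construction; lowly expressed genes carry mostly technical noise and
#' inflate spurious correlations.
#'
#' @param expr Expression tibble: `gene_id` column plus one numeric column
#'   per sample (FPKM or similar, non-negative).
#' @param min_expr Threshold; genes with summary >= `min_expr` are kept
#'   (the boundary is kept).
#' @param stat Summary statistic across samples: `"mean"` (default) or
#'   `"max"`.
#' @return The filtered tibble, with attributes `n_kept` and `n_removed`.
#' @export
filter_genes <- function(expr, min_expr = 2, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  check_number(min_expr, "min_expr")
  m <- as_id_matrix(expr, "gene_id")
  if (any(m < 0) || any(!is.finite(m))) {
    stop_input("Expression values must be finite and non-negative.")
  }
  s <- if (stat == "mean") rowMeans(m) else apply(m, 1, max)
  keep <- s >= min_expr
  if (!any(keep)) {
    stop_input("No genes pass min_expr = %s; lower the threshold.", min_expr)
  }
  out <- expr[keep, , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Sample quality control
#'
#' Clusters samples (average linkage on Euclidean distance of
#' standardized expression), computes the pairwise Pearson correlation
#' matrix and the first two principal-component coordinates, and flags
#' samples that join the dendrogram unusually high as candidate outliers.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param height_quantile A sample is flagged when the height at which it
#'   merges into the tree exceeds this quantile of all merge heights.
#' @return A list of class `sample_qc`: `tree` (hclust), `cor` (sample
#'   correlation matrix), `pca` (tibble: sample_id, PC1, PC2, plus
#'   variance explained as attribute), `outliers` (tibble: sample_id,
#'   merge_height, flagged).
#' @export
sample_qc <- function(expr, height_quantile = 0.95) {
  m <- as_id_matrix(expr, "gene_id")
  if (ncol(m) < 3) stop_input("Need at least 3 samples for QC.")
  constant <- apply(m, 2, sd) == 0
  if (any(constant)) {
    warn(sprintf("Excluding constant sample(s): %s.",
                 paste(colnames(m)[constant], collapse = ", ")))
    m <- m[, !constant, drop = FALSE]
  }
  # standardize genes, then cluster samples
  z <- t(scale(t(m)))
  z <- z[apply(z, 1, function(r) all(is.finite(r))), , drop = FALSE]
  tree <- hclust(dist(t(z)), method = "average")

  cors <- cor(m)

  pc <- prcomp(t(z), rank. = 2)
  varexp <- pc$sdev[1:2]^2 / sum(pc$sdev^2)
  pca <- tibble::tibble(
    sample_id = colnames(m),
    PC1 = pc$x[, 1], PC2 = pc$x[, 2]
  )
  attr(pca, "var_explained") <- varexp

  # height at which each leaf first merges
  merge_height <- vapply(seq_len(ncol(m)), function(i) {
    hit <- which(tree$merge == -i, arr.ind = TRUE)[1, 1]
    tree$height[hit]
  }, numeric(1))
  cut <- quantile(tree$height, height_quantile)
  outliers <- tibble::tibble(
    sample_id = colnames(m),
    merge_height = merge_height,
    flagged = merge_height > cut
  )

  structure(
    list(tree = tree, cor = cors, pca = pca, outliers = outliers),
    class = "sample_qc"
  )
}

#' @export
print.sample_qc <- function(x, ...) {
  n_flag <- sum(x$outliers$flagged)
  cat(sprintf("Sample QC: %d samples, %d flagged as potential outliers\n",
              nrow(x$outliers), n_flag))
  if (n_flag > 0) {
    cat("  flagged:",
        paste(x$outliers$sample_id[x$outliers$flagged], collapse = ", "), "\n")
  }
  invisible(x)
}
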