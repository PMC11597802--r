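#' Intramodular hub genes by degree
#'
#' Ranks the genes of one module by degree on a thresholded within-module
#' similarity graph: edges are gene pairs whose similarity (TOM or
#' adjacency) reaches the `edge_quantile` quantile of the module's
#' off-diagonal similarities; degree is the edge count. Ties are broken
#' by summed edge weight, then lexicographically by gene id, so the
#' ranking is total and invariant to input order.
#'
#' @param sim Gene x gene similarity matrix (TOM or adjacency) with gene
#'   ids as dimnames.
#' @param labels Tibble with `gene_id` and `module`.
#' @param module Module to rank.
#' @param top_k How many hubs to report (default 5).
#' @param edge_quantile Quantile of within-module off-diagonal
#'   similarities used as the edge threshold (default 0.95).
#' @return An object of class `hub_selection`: `ranking` (tibble:
#'   gene_id, degree, weight, rank), `hubs` (top `top_k` gene ids),
#'   `module`, `threshold`.
#' @export
intramodular_hubs <- function(sim, labels, module, top_k = 5,
                              edge_quantile = 0.95) {
  check_square_symmetric(sim, "sim")
  top_k <- check_count(top_k, "top_k", min = 1L)
  check_number(edge_quantile, "edge_quantile", lower = 0, upper = 1)
  genes <- labels$gene_id[labels$module == module]
  genes <- intersect(rownames(sim), genes)
  if (length(genes) == 0) stop_input("Module '%s' not found.", module)
  if (length(genes) < top_k) {
    stop_input("Module '%s' has %d genes, fewer than top_k = %d.",
               module, length(genes), top_k)
  }
  sub <- sim[genes, genes, drop = FALSE]
  offdiag <- upper_tri_vec(sub)
  thr <- quantile(offdiag, edge_quantile, names = FALSE)
  edge <- sub >= thr
  diag(edge) <- FALSE

  degree <- rowSums(edge)
  weight <- rowSums(sub * edge)
  ord <- order(-degree, -weight, genes)
  ranking <- tibble::tibble(
    gene_id = genes[ord],
    degree = as.integer(degree[ord]),
    weight = weight[ord],
    rank = seq_along(genes)
  )
  structure(
    list(ranking = ranking, hubs = ranking$gene_id[seq_len(top_k)],
         module = module, threshold = thr, edge_quantile = edge_quantile),
    class = "hub_selection"
  )
}

#' @export
print.hub_selection <- function(x, ...) {
  cat(sprintf("Hub genes of module '%s' (edge threshold %.3g):\n",
              x$module, x$threshold))
  print(head(x$ranking, length(x$hubs)))
  invisible(x)
}

#' Hub co-expression network
#'
#' Builds the undirected co-expression graph over a set of hub genes:
#' edges join pairs whose absolute expression correlation reaches
#' `cor_threshold`.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param hub_ids Gene ids to connect (all must be present in `expr`).
#' @param cor_threshold Absolute-correlation edge threshold (default 0.8).
#' @return A list of class `hub_network`: `edges` (tibble: gene_a,
#'   gene_b, correlation), `degrees` (tibble: gene_id, degree).
#' @export
hub_network <- function(expr, hub_ids, cor_threshold = 0.8) {
  check_number(cor_threshold, "cor_threshold", lower = 0, upper = 1)
  m <- as_id_matrix(expr, "gene_id")
  hub_ids <- unique(as.character(hub_ids))
  if (length(hub_ids) < 2) stop_input("Need at least 2 hub ids.")
  missing <- setdiff(hub_ids, rownames(m))
  if (length(missing)) {
    stop_input("Hub id(s) absent from expression: %s.",
               paste(missing, collapse = ", "))
  }
  cc <- cor(t(m[hub_ids, , drop = FALSE]))
  pairs <- which(upper.tri(cc), arr.ind = TRUE)
  keep <- abs(cc[pairs]) >= cor_threshold
  edges <- tibble::tibble(
    gene_a = hub_ids[pairs[keep, 1]],
    gene_b = hub_ids[pairs[keep, 2]],
    correlation = cc[pairs][keep]
  )
  degree <- setNames(integer(length(hub_ids)), hub_ids)
  for (g in c(edges$gene_a, edges$gene_b)) degree[g] <- degree[g] + 1L
  structure(
    list(edges = edges,
         degrees = tibble::tibble(gene_id = hub_ids,
                                  degree = as.integer(degree))),
    class = "hub_network"
  )
}

#' Distance matrix between samples on standardized columns
#'
#' Helper producing the sample-by-sample distance matrices consumed by
#' [mantel_test()]: Euclidean distance on column-standardized values, or
#' 1 - |Pearson correlation| between samples.
#'
#' @param df Tibble with `sample_id` plus numeric columns (hub-gene FPKM
#'   or trait values).
#' @param metric `"euclidean"` (on standardized columns) or `"cor"`
#'   (1 - |correlation|).
#' @return Symmetric zero-diagonal distance matrix.
#' @export
sample_distance <- function(df, metric = c("euclidean", "cor")) {
  metric <- match.arg(metric)
  m <- as_id_matrix(df, "sample_id")
  if (metric == "euclidean") {
    z <- scale(m)
    z[, apply(m, 2, sd) == 0] <- 0
    as.matrix(dist(z))
  } else {
    d <- 1 - abs(cor(t(m)))
    diag(d) <- 0
    d
  }
}

#' Mantel permutation test
#'
#' Correlation between two distance matrices over the same entities:
#' `r_M` is the Pearson correlation of the strict-upper-triangle entries,
#' and significance comes from jointly permuting the rows and columns of
#' the second matrix, `p = (1 + #{r_perm >= r_obs}) / (1 + nperm)` for
#' the one-sided (greater) alternative, so the smallest attainable p is
#' `1/(nperm + 1)`.
#'
#' @param d1,d2 Symmetric, zero-diagonal distance (or similarity)
#'   matrices of equal size n >= 4.
#' @param nperm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @param alternative `"greater"` (conventional) or `"two.sided"`.
#' @return An object of class `mantel_result`: `r`, `p`, `nperm`, `seed`,
#'   `alternative`.
#' @examples
#' d <- as.matrix(dist(matrix(rnorm(20), 5)))
#' mantel_test(d, d, nperm = 99, seed = 1)
#' @export
mantel_test <- function(d1, d2, nperm = 999, seed = 1L,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  nperm <- check_count(nperm, "nperm", min = 1L)
  seed <- check_count(seed, "seed")
  check_square_symmetric(d1, "d1")
  check_square_symmetric(d2, "d2")
  n <- nrow(d1)
  if (nrow(d2) != n) stop_input("Matrices differ in size (%d vs %d).", n, nrow(d2))
  if (n < 4) stop_input("Need at least 4 entities.")
  if (max(abs(diag(d1))) > 1e-8 || max(abs(diag(d2))) > 1e-8) {
    stop_input("Distance matrices must have zero diagonal.")
  }

  v1 <- upper_tri_vec(d1)
  r_obs <- cor(v1, upper_tri_vec(d2))

  r_perm <- withr::with_seed(seed, {
    vapply(seq_len(nperm), function(i) {
      idx <- sample.int(n)
      # the observed arrangement already contributes the +1; redraw the
      # identity permutation so it is not counted twice
      while (all(idx == seq_len(n))) idx <- sample.int(n)
      cor(v1, upper_tri_vec(d2[idx, idx]))
    }, numeric(1))
  })
  p <- if (alternative == "greater") {
    (1 + sum(r_perm >= r_obs)) / (1 + nperm)
  } else {
    (1 + sum(abs(r_perm) >= abs(r_obs))) / (1 + nperm)
  }
  structure(
    list(r = r_obs, p = p, nperm = nperm, seed = seed,
         alternative = alternative),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r, x$p, x$alternative, x$nperm))
  invisible(x)
}
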