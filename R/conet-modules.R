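# Conventional module colour sequence, assigned by decreasing module size.
MODULE_COLORS <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue"
)

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering of genes on the TOM
#' dissimilarity 1 - omega, cut statically at an absolute dissimilarity
#' height. Clusters smaller than `min_size` are relabelled `"grey"`
#' (unassigned); surviving modules are named by the conventional colour
#' sequence in order of decreasing size.
#'
#' @param tom Topological overlap matrix from [tom_similarity()] (or any
#'   symmetric similarity in \[0, 1\] with unit diagonal).
#' @param min_size Minimum module size (default 30).
#' @param cut_height Absolute dissimilarity at which the tree is cut
#'   (default 0.95). Pairs of unrelated genes have topological overlap
#'   near 0 and so merge just below dissimilarity 1; branches that stay
#'   together below the cut share substantial overlap.
#' @return An object of class `module_assignment`: `labels` (tibble:
#'   gene_id, module), `tree` (hclust), `cut_height_used`, `sizes`
#'   (named count per module, grey included).
#' @export
detect_modules <- function(tom, min_size = 30, cut_height = 0.95) {
  check_square_symmetric(tom, "tom")
  min_size <- check_count(min_size, "min_size", min = 1L)
  check_number(cut_height, "cut_height", lower = 0, upper = 1)
  gene_ids <- rownames(tom) %||% sprintf("gene_%04d", seq_len(nrow(tom)))

  diss <- 1 - tom
  tree <- hclust(as.dist(diss), method = "average")
  h_cut <- cut_height
  raw <- cutree(tree, h = h_cut)

  sizes_raw <- table(raw)
  keep <- names(sizes_raw)[sizes_raw >= min_size]
  module <- rep("grey", length(raw))
  if (length(keep) > 0) {
    # order surviving clusters by decreasing size for colour naming
    keep <- keep[order(-sizes_raw[keep], as.integer(keep))]
    if (length(keep) > length(MODULE_COLORS)) {
      names_pool <- c(MODULE_COLORS,
                      sprintf("module%d", seq_len(length(keep) - length(MODULE_COLORS))))
    } else {
      names_pool <- MODULE_COLORS
    }
    for (i in seq_along(keep)) {
      module[raw == as.integer(keep[i])] <- names_pool[i]
    }
  } else {
    warn("All genes are unassigned (grey); no cluster reached min_size.")
  }

  labels <- tibble::tibble(gene_id = gene_ids, module = module)
  structure(
    list(
      labels = labels,
      tree = tree,
      cut_height_used = h_cut,
      sizes = sort(table(labels$module), decreasing = TRUE)
    ),
    class = "module_assignment"
  )
}

#' @export
print.module_assignment <- function(x, ...) {
  non_grey <- setdiff(names(x$sizes), "grey")
  cat(sprintf("Module assignment: %d genes, %d module(s) + grey\n",
              nrow(x$labels), length(non_grey)))
  print(x$sizes)
  invisible(x)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first right singular vector of the
#' module's standardized (per-gene, across samples) expression sub-matrix
#' — the one sample-profile that explains the most variance of the
#' module's genes. Its sign is fixed so the mean correlation with member
#' genes is non-negative.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param labels Tibble with `gene_id` and `module` (e.g.
#'   `detect_modules(...)$labels`); grey genes are skipped.
#' @return A list of class `module_eigengenes`: `eigengenes` (tibble:
#'   sample_id + one unit-norm column per module, named `ME<module>`),
#'   `var_explained` (named fraction per module).
#' @export
module_eigengene <- function(expr, labels) {
  m <- as_id_matrix(expr, "gene_id")
  if (ncol(m) < 2) stop_input("Need at least 2 samples.")
  if (!all(c("gene_id", "module") %in% names(labels))) {
    stop_input("`labels` needs columns gene_id and module.")
  }
  mods <- setdiff(unique(labels$module), "grey")
  if (length(mods) == 0) stop_input("No non-grey modules in `labels`.")

  me <- matrix(NA_real_, ncol(m), length(mods),
               dimnames = list(colnames(m), paste0("ME", mods)))
  varexp <- setNames(numeric(length(mods)), mods)
  for (i in seq_along(mods)) {
    genes <- labels$gene_id[labels$module == mods[i]]
    genes <- intersect(genes, rownames(m))
    if (length(genes) == 0) stop_input("Module '%s' has no genes in `expr`.", mods[i])
    sub <- m[genes, , drop = FALSE]
    sds <- apply(sub, 1, sd)
    if (all(sds == 0)) stop_input("Module '%s' contains only constant genes.", mods[i])
    if (any(sds == 0)) sub <- sub[sds > 0, , drop = FALSE]
    z <- t(scale(t(sub)))          # genes x samples, standardized per gene
    sv <- svd(z, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (mean(cor(v, t(z))) < 0) v <- -v
    me[, i] <- v
    varexp[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  structure(
    list(eigengenes = id_matrix_to_tibble(me, "sample_id"),
         var_explained = varexp),
    class = "module_eigengenes"
  )
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with each physiological
#' trait, with the two-sided p-value from the exact t transform
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on n - 2 degrees of freedom.
#'
#' @param eigengenes Tibble with `sample_id` + eigengene columns (e.g.
#'   `module_eigengene(...)$eigengenes`).
#' @param traits Tibble with `sample_id` + numeric trait columns, same
#'   samples (matched by id, order-free).
#' @return A tibble in long form: `module`, `trait`, `r`, `p`, `n`.
#'   Zero-variance traits yield NA entries with a warning.
#' @export
module_trait_correlation <- function(eigengenes, traits) {
  me <- as_id_matrix(eigengenes, "sample_id")
  tr <- as_id_matrix(traits, "sample_id")
  common <- intersect(rownames(me), rownames(tr))
  if (length(common) < 4) {
    stop_input("Need >= 4 shared samples; found %d.", length(common))
  }
  if (length(common) < nrow(me) || length(common) < nrow(tr)) {
    warn("Sample ids only partially overlap; using the intersection.")
  }
  me <- me[common, , drop = FALSE]
  tr <- tr[common, , drop = FALSE]
  n <- length(common)

  dead <- apply(tr, 2, sd) == 0
  if (any(dead)) {
    warn(sprintf("Zero-variance trait(s) give NA: %s.",
                 paste(colnames(tr)[dead], collapse = ", ")))
  }

  grid <- tidyr::expand_grid(module = colnames(me), trait = colnames(tr))
  purrr::pmap_dfr(grid, function(module, trait) {
    if (sd(tr[, trait]) == 0) {
      return(tibble::tibble(module = module, trait = trait,
                            r = NA_real_, p = NA_real_, n = n))
    }
    r <- cor(me[, module], tr[, trait])
    p <- cor_pvalue(r, n)
    tibble::tibble(module = module, trait = trait, r = r, p = p, n = n)
  })
}

# two-sided p for a Pearson correlation via the t transform
cor_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * pt(-abs(t_stat), df = n - 2)
}

#' Three-set Venn partition of DEG lists
#'
#' Exact counts and memberships of all seven regions of a three-set Venn
#' diagram over differentially-expressed-gene id lists, including the
#' pairwise-minus-third regions used to call variety-specific
#' stress-responsive genes.
#'
#' @param set_a,set_b,set_c Character vectors of gene ids (duplicates
#'   removed).
#' @param names Length-3 labels for the sets.
#' @return A list of class `venn_partition`: `counts` (tibble: region,
#'   n), `ids` (named list of id vectors per region).
#' @export
venn_partition <- function(set_a, set_b, set_c,
                           names = c("A", "B", "C")) {
  if (length(names) != 3) stop_input("`names` must have length 3.")
  a <- unique(as.character(set_a))
  b <- unique(as.character(set_b))
  cc <- unique(as.character(set_c))
  universe <- union(union(a, b), cc)
  in_a <- universe %in% a
  in_b <- universe %in% b
  in_c <- universe %in% cc

  regions <- list(
    universe[in_a & !in_b & !in_c],
    universe[!in_a & in_b & !in_c],
    universe[!in_a & !in_b & in_c],
    universe[in_a & in_b & !in_c],
    universe[in_a & !in_b & in_c],
    universe[!in_a & in_b & in_c],
    universe[in_a & in_b & in_c]
  )
  region_names <- c(
    sprintf("%s_only", names[1]),
    sprintf("%s_only", names[2]),
    sprintf("%s_only", names[3]),
    sprintf("%s_and_%s_not_%s", names[1], names[2], names[3]),
    sprintf("%s_and_%s_not_%s", names[1], names[3], names[2]),
    sprintf("%s_and_%s_not_%s", names[2], names[3], names[1]),
    "all_three"
  )
  names(regions) <- region_names
  structure(
    list(
      counts = tibble::tibble(
        region = region_names,
        n = unname(vapply(regions, length, integer(1)))
      ),
      ids = regions
    ),
    class = "venn_partition"
  )
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Three-set Venn partition\n")
  print(x$counts)
  invisible(x)
}
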