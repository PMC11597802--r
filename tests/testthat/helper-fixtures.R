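# Small fixtures and brute-force oracles shared across test files.

# long-form two-arm panel from a control and a treatment matrix
make_panel <- function(control, treatment) {
  stopifnot(identical(dim(control), dim(treatment)))
  entities <- rownames(control)
  indicators <- colnames(control)
  dplyr::bind_rows(
    tidyr::expand_grid(entity = entities, indicator = indicators) |>
      dplyr::mutate(arm = "control",
                    value = as.vector(t(control))),
    tidyr::expand_grid(entity = entities, indicator = indicators) |>
      dplyr::mutate(arm = "treatment",
                    value = as.vector(t(treatment)))
  )
}

# gene_id-first expression tibble -> numeric matrix
as_matrix_expr <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$gene_id
  m
}

# random valid adjacency: symmetric, unit diagonal, entries in [0, 1]
random_adjacency <- function(n, seed) {
  withr::with_seed(seed, {
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
    a
  })
}

# exhaustive 1-D k-means oracle: best within-SS over all contiguous
# partitions of the sorted values
contiguous_partition_oracle <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cuts <- utils::combn(n - 1, k - 1, simplify = FALSE)
  best <- Inf
  best_assign <- NULL
  for (ct in cuts) {
    bounds <- c(0, ct, n)
    assign <- rep(seq_len(k), times = diff(bounds))
    ss <- sum(vapply(split(x, assign),
                     function(v) sum((v - mean(v))^2), numeric(1)))
    if (ss < best - 1e-12) {
      best <- ss
      best_assign <- assign
    }
  }
  list(tot_withinss = best, assign = best_assign, sorted = x)
}

# mean ARI of detected vs planted module labels (grey-truth genes excluded)
planted_recovery_ari <- function(seed, cut_height = 0.95, beta = 6) {
  es <- simulate_expression(expr_sim_config(seed = seed))
  fe <- filter_genes(es$expression)
  tom <- tom_similarity(adjacency_matrix(fe, beta = beta))
  mods <- suppressWarnings(detect_modules(tom, min_size = 30,
                                          cut_height = cut_height))
  truth <- es$modules$module[match(mods$labels$gene_id, es$modules$gene_id)]
  keep <- truth != "grey"
  mclust::adjustedRandIndex(mods$labels$module[keep], truth[keep])
}

# samples x genes matrix with one dominant latent factor and power-law
# loadings, giving the heavy-tailed connectivity a soft-threshold scan
# expects from approximately scale-free data
hub_dominated_expression <- function(n_genes = 300, n_samples = 40, seed = 1) {
  withr::with_seed(seed, {
    f <- rnorm(n_samples)
    lam <- runif(n_genes)^1.5
    x <- vapply(seq_len(n_genes), function(i) {
      lam[i] * f + sqrt(1 - lam[i]^2) * rnorm(n_samples)
    }, numeric(n_samples))
    m <- t(x)
    rownames(m) <- sprintf("g%03d", seq_len(n_genes))
    colnames(m) <- sprintf("s%02d", seq_len(n_samples))
    out <- tibble::as_tibble(m)
    dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), out)
  })
}
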