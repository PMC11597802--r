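toy_expr <- function(values, samples = 6) {
  m <- do.call(rbind, values)
  rownames(m) <- names(values)
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                   tibble::as_tibble(m))
}

test_that("gene filtering keeps the boundary and counts removals", {
  expr <- toy_expr(list(
    g1 = rep(0.5, 4), g2 = rep(1.9, 4), g3 = rep(2.0, 4),
    g4 = rep(3.1, 4), g5 = rep(10, 4)))
  kept <- filter_genes(expr, min_expr = 2, stat = "mean")
  expect_identical(kept$gene_id, c("g3", "g4", "g5"))
  expect_equal(attr(kept, "n_kept"), 3)
  expect_equal(attr(kept, "n_removed"), 2)
  # max statistic rescues a spiky gene the mean drops
  spiky <- toy_expr(list(g1 = c(0, 0, 0, 7.9), g2 = rep(1, 4)))
  expect_identical(filter_genes(spiky, stat = "max")$gene_id, "g1")
  expect_error(filter_genes(expr, min_expr = 100), "lower the threshold")
})

test_that("sample QC flags a constructed outlier and separates groups on PC1", {
  withr::with_seed(21, {
    base <- matrix(rnorm(200 * 9), 200, 9)
    base[, 1:4] <- base[, 1:4] + 3        # two groups with distinct means
    out <- base
    out[, 9] <- out[, 9] + 10             # one sample shifted by ~10 sd
    colnames(out) <- paste0("s", 1:9)
    rownames(out) <- paste0("g", 1:200)
  })
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(out)),
                           tibble::as_tibble(abs(out)))
  qc <- sample_qc(expr, height_quantile = 0.85)
  expect_true(qc$outliers$flagged[qc$outliers$sample_id == "s9"])
  # duplicated sample has correlation exactly 1
  expr2 <- dplyr::mutate(expr, s1b = .data$s1)
  qc2 <- sample_qc(expr2)
  expect_equal(qc2$cor["s1", "s1b"], 1)
  # PC1 separates the constructed groups with no overlap
  pc1 <- qc$pca$PC1[qc$pca$sample_id %in% paste0("s", 1:8)]
  grp <- rep(c(1, 2), each = 4)
  expect_true(max(pc1[grp == 1]) < min(pc1[grp == 2]) ||
                min(pc1[grp == 1]) > max(pc1[grp == 2]))
})

test_that("adjacency modes match their closed forms", {
  expr <- toy_expr(list(
    g1 = c(1, 2, 3, 4, 5, 6),
    g2 = c(2, 4, 6, 8, 10, 12),     # perfectly correlated with g1
    g3 = c(6, 5, 4, 3, 2, 1)))      # perfectly anti-correlated
  a_u <- adjacency_matrix(expr, beta = 3, mode = "unsigned")
  expect_equal(a_u["g1", "g2"], 1)
  expect_equal(a_u["g1", "g3"], 1)
  a_s <- adjacency_matrix(expr, beta = 3, mode = "signed")
  expect_equal(a_s["g1", "g2"], 1)
  expect_equal(a_s["g1", "g3"], 0)
  expect_error(adjacency_matrix(
    toy_expr(list(g1 = rep(1, 4), g2 = 1:4)), beta = 2), "Zero-variance")
  # cor exactly 0.5 at beta 2 -> 0.25: mix a standardized profile with an
  # orthogonal contrast at weights (1/2, sqrt(3)/2)
  x <- c(1, 2, 3, 4)
  xs <- (x - mean(x)) / sd(x)
  zs <- c(1, -1, -1, 1) / sd(c(1, -1, -1, 1))
  y <- 0.5 * xs + sqrt(0.75) * zs
  expr2 <- toy_expr(list(g1 = x, g2 = y))
  expect_equal(cor(x, y), 0.5)
  expect_equal(adjacency_matrix(expr2, beta = 2)["g1", "g2"], 0.25)
})

test_that("soft-threshold scan: beta = 1 identity and monotone connectivity", {
  expr <- hub_dominated_expression(n_genes = 120, n_samples = 20, seed = 3)
  scan <- suppressWarnings(pick_soft_threshold(expr, powers = 1:8))
  # beta = 1 mean connectivity equals the mean off-diagonal |cor| sum
  m <- as_matrix_expr(expr)
  ac <- abs(cor(t(m))); diag(ac) <- 0
  expect_equal(
    scan$scan$mean_connectivity[scan$scan$power == 1],
    mean(rowSums(ac)))
  expect_true(all(diff(scan$scan$mean_connectivity) < 0))
})

test_that("hub-dominated expression reaches the scale-free plateau", {
  expr <- hub_dominated_expression(n_genes = 300, n_samples = 40, seed = 1)
  scan <- pick_soft_threshold(expr, powers = 1:12, target = 0.85)
  expect_true(scan$reached_target)
  expect_gte(max(scan$scan$fit_index), 0.85)
  # the chosen beta is the smallest power at or above target
  first_hit <- min(scan$scan$power[scan$scan$fit_index >= 0.85])
  expect_equal(scan$beta, first_hit)
})

test_that("white-noise expression falls back to the argmax with a flag", {
  withr::with_seed(14, {
    m <- matrix(rnorm(150 * 12), 150, 12,
                dimnames = list(paste0("g", 1:150), paste0("s", 1:12)))
  })
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                           tibble::as_tibble(m))
  expect_warning(scan <- pick_soft_threshold(expr, powers = 1:6), "argmax")
  expect_false(scan$reached_target)
  expect_equal(scan$beta,
               scan$scan$power[which.max(scan$scan$fit_index)])
})

test_that("topological overlap matches its closed forms", {
  # two nodes connected only to each other with weight a -> omega = a
  a <- diag(4)
  a[1, 2] <- a[2, 1] <- 0.6
  w <- tom_similarity(a)
  expect_equal(w[1, 2], 0.6)
  # complete unweighted triangle -> all overlaps 1
  tri <- matrix(1, 3, 3)
  expect_true(all(tom_similarity(tri) == 1))
  # edgeless pair sharing no neighbors: omega equals the adjacency exactly
  a2 <- diag(5)
  a2[1, 2] <- a2[2, 1] <- 0.3
  a2[3, 4] <- a2[4, 3] <- 0.9
  w2 <- tom_similarity(a2)
  expect_equal(w2[1, 2], 0.3)
  expect_equal(w2[3, 4], 0.9)
  expect_error(tom_similarity(matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
})

test_that("TOM of random valid adjacencies stays a valid similarity", {
  for (s in 1:20) {
    a <- random_adjacency(12, seed = 100 + s)
    w <- tom_similarity(a)
    expect_equal(w, t(w))
    expect_true(all(diag(w) == 1))
    expect_true(all(w >= 0 & w <= 1 + 1e-12))
  }
})

test_that("module detection recovers planted modules and applies the size rule", {
  aris <- vapply(1:20, planted_recovery_ari, numeric(1))
  expect_gte(mean(aris), 0.9)

  # a 10-gene planted cluster is relabelled grey under min_size = 30
  es <- simulate_expression(expr_sim_config(
    n_modules = 2, genes_per_module = 10, n_background = 0,
    noise_sd = 0.05, seed = 3))
  tom <- tom_similarity(adjacency_matrix(filter_genes(es$expression), beta = 6))
  mods <- expect_warning(detect_modules(tom, min_size = 30), "grey")
  expect_true(all(mods$labels$module == "grey"))

  # single-module data yields exactly one non-grey module
  es1 <- simulate_expression(expr_sim_config(
    n_modules = 1, genes_per_module = 40, n_background = 0,
    noise_sd = 0.2, seed = 9))
  tom1 <- tom_similarity(adjacency_matrix(es1$expression, beta = 6))
  mods1 <- detect_modules(tom1, min_size = 30)
  expect_identical(setdiff(unique(mods1$labels$module), "grey"), "turquoise")
})

test_that("module eigengenes: rank-1 and orthogonal closed forms, sign fix", {
  # identical genes -> variance explained 1, eigengene tracks the profile
  profile <- c(1, 3, 2, 5, 4, 6)
  expr <- toy_expr(list(g1 = profile, g2 = profile, g3 = profile))
  labels <- tibble::tibble(gene_id = paste0("g", 1:3), module = "blue")
  me <- module_eigengene(expr, labels)
  expect_equal(unname(me$var_explained["blue"]), 1)
  expect_equal(abs(cor(me$eigengenes$MEblue, profile)), 1)

  # two orthogonal standardized genes -> variance explained 0.5
  g1 <- c(1, 1, -1, -1); g2 <- c(1, -1, 1, -1)
  expr2 <- toy_expr(list(a = g1, b = g2))
  me2 <- module_eigengene(
    expr2, tibble::tibble(gene_id = c("a", "b"), module = "m"))
  expect_equal(unname(me2$var_explained["m"]), 0.5)

  # sign convention: mean correlation with members is >= 0 on random modules
  withr::with_seed(19, {
    for (i in 1:10) {
      m <- matrix(rnorm(8 * 10), 8, 10,
                  dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
      e <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                            tibble::as_tibble(m))
      lab <- tibble::tibble(gene_id = rownames(m), module = "x")
      res <- module_eigengene(e, lab)
      z <- t(scale(t(m)))
      expect_gte(mean(cor(res$eigengenes$MEx, t(z))), 0)
    }
  })
  expect_error(module_eigengene(
    toy_expr(list(g1 = rep(2, 4))),
    tibble::tibble(gene_id = "g1", module = "k")), "constant")
})

test_that("module-trait correlation matches the t-distribution oracle", {
  # identity: trait equal to the eigengene
  me <- tibble::tibble(sample_id = paste0("s", 1:8), MEred = rnorm(8))
  tr <- tibble::tibble(sample_id = me$sample_id, H2O2 = me$MEred)
  res <- module_trait_correlation(me, tr)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-12)

  # r = 0.5 at n = 16: p from the exact t transform at df = 14
  p_oracle <- 2 * stats::pt(-0.5 * sqrt(14) / sqrt(1 - 0.25), df = 14)
  expect_equal(stresscreen:::cor_pvalue(0.5, 16), p_oracle)
  expect_equal(p_oracle, 0.0486, tolerance = 1e-3)

  # agreement with cor.test on a random pair
  withr::with_seed(3, { x <- rnorm(16); y <- rnorm(16) })
  ct <- stats::cor.test(x, y)
  expect_equal(stresscreen:::cor_pvalue(cor(x, y), 16), ct$p.value)
})

test_that("module-trait p-values are calibrated under the null", {
  rejections <- withr::with_seed(77, {
    vapply(1:1000, function(i) {
      x <- rnorm(16); y <- rnorm(16)
      stresscreen:::cor_pvalue(cor(x, y), 16) < 0.05
    }, logical(1))
  })
  expect_gte(mean(rejections), 0.035)
  expect_lte(mean(rejections), 0.065)
})

test_that("Venn partition matches full enumeration", {
  res <- venn_partition(c(1, 2, 3, 4), c(3, 4, 5), c(4, 5, 6))
  ids <- res$ids
  expect_setequal(ids$all_three, "4")
  expect_setequal(ids$A_and_B_not_C, "3")
  expect_setequal(ids$B_and_C_not_A, "5")
  expect_length(ids$A_and_C_not_B, 0)
  expect_setequal(ids$A_only, c("1", "2"))
  expect_length(ids$B_only, 0)
  expect_setequal(ids$C_only, "6")
  # counts agree with a direct enumeration over the universe
  universe <- as.character(1:6)
  direct <- sum(table(
    paste(universe %in% as.character(1:4),
          universe %in% as.character(3:5),
          universe %in% as.character(4:6))))
  expect_equal(sum(res$counts$n), direct)

  # degenerate cases
  same <- venn_partition(letters[1:4], letters[1:4], letters[1:4])
  expect_equal(same$counts$n[same$counts$region == "all_three"], 4L)
  expect_equal(sum(same$counts$n), 4L)
  disj <- venn_partition("a", "b", "c")
  expect_equal(sort(disj$counts$n), c(0L, 0L, 0L, 0L, 1L, 1L, 1L))
})
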