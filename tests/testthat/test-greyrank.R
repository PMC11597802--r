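rel_fixture <- function() {
  withr::with_seed(11, {
    m <- matrix(runif(30, 0.4, 1.4), 10, 3,
                dimnames = list(sprintf("v%02d", 1:10), c("a", "b", "c")))
  })
  out <- tibble::as_tibble(m)
  dplyr::bind_cols(tibble::tibble(entity = rownames(m)), out)
}

test_that("oriented normalization hits its endpoints and reflects", {
  rel <- tibble::tibble(entity = c("x", "y", "z"), up = c(2, 4, 6),
                        down = c(2, 4, 6))
  nm <- orient_normalize(rel, c(up = "larger_better", down = "smaller_better"))
  expect_equal(nm$up, c(0, 0.5, 1))
  expect_equal(nm$down, c(1, 0.5, 0))
  # constant column -> all ones + warning
  relc <- tibble::tibble(entity = c("x", "y", "z"), k = c(3, 3, 3),
                         u = c(1, 2, 3))
  expect_warning(nmc <- orient_normalize(relc), "Constant")
  expect_equal(nmc$k, c(1, 1, 1))
  expect_error(orient_normalize(rel[1, ]), "2 entities")
})

test_that("grey coefficients match the closed form and the hand example", {
  # hand example: rows A = (1, 0), B = (0, 1), rho = 0.5
  norm <- tibble::tibble(entity = c("A", "B"), i1 = c(1, 0), i2 = c(0, 1))
  xi <- grey_coefficients(norm, rho = 0.5)
  expect_equal(unlist(xi[xi$entity == "A", -1], use.names = FALSE),
               c(1, 1 / 3))
  expect_equal(unlist(xi[xi$entity == "B", -1], use.names = FALSE),
               c(1 / 3, 1))
  # ... and the uniform-weight degree continues the example: gamma = 2/3
  deg <- relational_degree(xi)
  expect_equal(deg$gamma, c(2 / 3, 2 / 3))

  # entity equal to the reference scores 1 everywhere
  norm2 <- tibble::tibble(entity = c("ref", "other"), i1 = c(1, 0.2),
                          i2 = c(1, 0.7))
  xi2 <- grey_coefficients(norm2)
  expect_equal(unlist(xi2[xi2$entity == "ref", -1], use.names = FALSE),
               c(1, 1))
  # worst cell attains the closed form rho/(1+rho)
  expect_equal(min(as.matrix(xi2[-1])), 0.5 / 1.5)
})

test_that("grey coefficients are anti-monotone in the deviation", {
  withr::with_seed(5, m <- matrix(runif(40), 8, 5))
  rho <- 0.5
  delta <- abs(1 - m)
  dmin <- min(delta); dmax <- max(delta)
  xi <- (dmin + rho * dmax) / (delta + rho * dmax)
  # increasing any single delta (holding global min/max) never increases xi
  for (idx in sample(length(delta), 10)) {
    d2 <- delta
    d2[idx] <- min(d2[idx] + 0.05, dmax)
    xi2 <- (dmin + rho * dmax) / (d2 + rho * dmax)
    expect_lte(xi2[idx], xi[idx])
  }
})

test_that("rho limits behave as the closed forms predict", {
  norm <- tibble::tibble(entity = c("A", "B"), i1 = c(1, 0), i2 = c(0, 1))
  # rho = 1: minimum attainable coefficient is 1/2
  xi1 <- grey_coefficients(norm, rho = 1)
  expect_equal(min(as.matrix(xi1[-1])), 0.5)
  # rho -> 0: off-ideal cells collapse towards 0
  xis <- grey_coefficients(norm, rho = 1e-6)
  expect_lt(min(as.matrix(xis[-1])), 1e-5)
})

test_that("relational degree honors weights and keeps the reference at 1", {
  xi <- tibble::tibble(entity = c("A", "B"), i1 = c(1, 1 / 3),
                       i2 = c(1 / 3, 1))
  # one-hot weight selects a column
  expect_equal(relational_degree(xi, c(1, 0))$gamma, c(1, 1 / 3))
  # named weights are matched by indicator
  expect_equal(relational_degree(xi, c(i2 = 1, i1 = 0))$gamma, c(1 / 3, 1))
  expect_error(relational_degree(xi, c(0.5, 0.2, 0.3)), "3 weights")
  expect_error(relational_degree(xi, c(0.7, 0.7)), "sum to 1")

  # a reference-equal entity has degree exactly 1 under any valid weights
  withr::with_seed(9, {
    n <- 6
    m <- rbind(ref = rep(1, n), matrix(runif(4 * n), 4))
    w <- runif(n); w <- w / sum(w)
  })
  xi_ref <- grey_coefficients(
    dplyr::bind_cols(tibble::tibble(entity = c("ref", paste0("e", 1:4))),
                     tibble::as_tibble(m, .name_repair = ~ paste0("i", 1:n))))
  expect_equal(relational_degree(xi_ref, w)$gamma[1], 1)
})

test_that("CRITIC weights: symmetry, constant columns, normalization", {
  # two orthogonal columns with equal sd -> equal weights
  nm <- tibble::tibble(entity = paste0("e", 1:4),
                       a = c(0, 1, 0, 1), b = c(0, 0, 1, 1))
  expect_equal(unname(critic_weights(nm)), c(0.5, 0.5))
  # a constant column gets weight 0
  nm2 <- dplyr::mutate(nm, k = 1)
  w2 <- expect_silent(critic_weights(nm2))
  expect_equal(unname(w2["k"]), 0)
  expect_equal(sum(w2), 1)
  # weights always sum to 1
  withr::with_seed(3, {
    for (i in 1:20) {
      m <- matrix(runif(5 * 4), 5, 4,
                  dimnames = list(paste0("e", 1:5), paste0("i", 1:4)))
      w <- critic_weights(
        dplyr::bind_cols(tibble::tibble(entity = rownames(m)),
                         tibble::as_tibble(m)))
      expect_equal(sum(w), 1, tolerance = 1e-12)
    }
  })
})

test_that("CRITIC weights are permutation-equivariant in indicator order", {
  withr::with_seed(17, {
    m <- matrix(runif(6 * 5), 6, 5,
                dimnames = list(paste0("e", 1:6), paste0("i", 1:5)))
  })
  df <- dplyr::bind_cols(tibble::tibble(entity = rownames(m)),
                         tibble::as_tibble(m))
  w <- critic_weights(df)
  perm <- c("i3", "i1", "i5", "i2", "i4")
  w_perm <- critic_weights(df[c("entity", perm)])
  expect_equal(w_perm, w[perm])
})

test_that("agreement R^2 matches a direct Pearson oracle", {
  expect_equal(agreement_r2(1:4, 1:4)$r2, 1)
  # brute-force Pearson^2 on (1,2,3,4) vs (1,2,3,5)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  ag <- agreement_r2(x, y)
  expect_equal(ag$r2, r_oracle^2)
  expect_true(ag$agree)
  # constructed orthogonal residuals give r2 = 0
  expect_equal(agreement_r2(c(-1, 0, 1, 0), c(0, -1, 0, 1))$r2, 0)
  expect_error(agreement_r2(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("grey_rank recovers a planted ordering and gates agreement", {
  res <- grey_rank(rel_fixture())
  expect_s3_class(res, "grey_result")
  expect_equal(sum(res$weights), 1, tolerance = 1e-12)
  expect_true(all(res$xi[-1] > 0 & res$xi[-1] <= 1))
  td <- tidy(res)
  expect_named(td, c("entity", "gamma_unweighted", "gamma_weighted",
                     "rank_unweighted", "rank_weighted"))
  g <- glance(res)
  expect_true(g$r2_agreement >= 0 && g$r2_agreement <= 1)
})

test_that("key time point is the divergence argmax with earliest-tie rule", {
  # the reported day-7 divergence pair dominates all other days
  summaries <- tibble::tibble(
    timepoint = c(0, 1, 3, 5, 7),
    gamma_unweighted = c(0.5, 0.52, 0.48, 0.55, 0.163514),
    gamma_weighted = c(0.5, 0.55, 0.54, 0.62, 0.303217)
  )
  res <- select_key_timepoint(summaries)
  expect_equal(res$timepoint, 7)
  expect_equal(max(res$divergence$divergence), 0.303217 - 0.163514)

  # argmax matches an exhaustive scan on random tables
  withr::with_seed(23, {
    for (i in 1:10) {
      s <- tibble::tibble(timepoint = 1:6,
                          gamma_unweighted = runif(6),
                          gamma_weighted = runif(6))
      expected <- s$timepoint[which.max(abs(s$gamma_weighted -
                                              s$gamma_unweighted))]
      expect_equal(select_key_timepoint(s)$timepoint, expected)
    }
  })

  # all-equal divergences: earliest time point + warning
  tied <- tibble::tibble(timepoint = c(3, 1, 2),
                         gamma_unweighted = c(0.4, 0.4, 0.4),
                         gamma_weighted = c(0.6, 0.6, 0.6))
  expect_warning(res_tied <- select_key_timepoint(tied), "Tied")
  expect_equal(res_tied$timepoint, 1)
})
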