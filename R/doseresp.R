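#' Two-parameter log-logistic mortality fit (binomial MLE)
#'
#' Fits the two-parameter log-logistic dose-response
#' \deqn{p(c) = \frac{1}{1 + (e/c)^b}}
#' to dead/cohort counts by binomial maximum likelihood, pooling replicates
#' within the variety. `e` is the LC50 (the concentration at which the
#' fitted mortality probability is exactly 0.5) in the units of
#' `concentration`; `b > 0` is the slope on the log-concentration scale.
#' The lower asymptote is fixed at 0 and the upper at 1, appropriate when
#' unstressed controls show no mortality, and rows at concentration 0 are
#' excluded (the model forces p(0) = 0).
#'
#' Internally this is logistic regression on log(c):
#' logit p = b (log c - log e), optimised over (log b, log e) with
#' [stats::optim()] (BFGS, analytic-free); the Wald standard error of
#' log e comes from the numerically differentiated Hessian.
#'
#' @param table Data frame with columns `concentration`, `dead`, `cohort`
#'   and optionally `day` and `replicate`. All rows after day filtering
#'   are pooled.
#' @param day Day to fit; default the last recorded day (mortality is
#'   cumulative, so the final day carries the full dose-response).
#' @return An object of class `ll2_fit`: `b`, `e`, `loglik`, `se_log_e`,
#'   `converged`, `n_obs`, `day`. Supports [predict()] (mortality
#'   probability at new concentrations), [tidy()] and [glance()].
#' @examples
#' tbl <- simulate_mortality(mortality_sim_config(
#'   varieties = data.frame(variety = "v1", b = 6, e = 250), seed = 1))
#' fit_log_logistic(dplyr::filter(tbl, variety == "v1"))
#' @export
fit_log_logistic <- function(table, day = NULL) {
  req <- c("concentration", "dead", "cohort")
  if (!all(req %in% names(table))) {
    stop_input("`table` needs columns %s.", paste(req, collapse = ", "))
  }
  if ("day" %in% names(table)) {
    day <- day %||% max(table$day)
    table <- dplyr::filter(table, .data$day == !!day)
    if (nrow(table) == 0) stop_input("No rows at day %s.", day)
  }
  if (any(table$dead < 0 | table$dead > table$cohort)) {
    stop_input("`dead` must lie in [0, cohort].")
  }

  pooled <- table |>
    dplyr::filter(.data$concentration > 0) |>
    dplyr::group_by(.data$concentration) |>
    dplyr::summarise(dead = sum(.data$dead), cohort = sum(.data$cohort),
                     .groups = "drop")
  if (nrow(pooled) < 2) {
    stop_input("Need observations at >= 2 positive concentrations.")
  }
  frac <- pooled$dead / pooled$cohort
  if (all(frac == 0) || all(frac == 1)) {
    stop_input(paste(
      "Mortality is %s at every positive concentration;",
      "the LC50 is not identifiable from these data."),
      if (all(frac == 0)) "0" else "100%")
  }

  logc <- log(pooled$concentration)
  nll <- function(par) {
    b <- exp(par[1]); loge <- par[2]
    eta <- b * (logc - loge)
    # stable binomial nll: -[dead*eta - cohort*log(1+exp(eta))]
    -sum(pooled$dead * eta - pooled$cohort * log1p(exp(eta)))
  }

  # moment-style start: interpolate where the pooled fraction crosses 0.5
  p0 <- pmin(pmax(frac, 1 / (2 * max(pooled$cohort))),
             1 - 1 / (2 * max(pooled$cohort)))
  start_fit <- stats::lm(stats::qlogis(p0) ~ logc)
  b0 <- max(abs(stats::coef(start_fit)[2]), 1e-2)
  e0 <- -stats::coef(start_fit)[1] / stats::coef(start_fit)[2]
  if (!is.finite(e0)) e0 <- mean(logc)
  opt <- optim(unname(c(log(b0), e0)), nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-12))

  se_log_e <- tryCatch({
    vc <- solve(opt$hessian)
    sqrt(vc[2, 2])
  }, error = function(e) NA_real_)

  structure(
    list(
      b = exp(opt$par[1]),
      e = exp(opt$par[2]),
      loglik = -opt$value +
        sum(lchoose(pooled$cohort, pooled$dead)),
      se_log_e = se_log_e,
      converged = opt$convergence == 0,
      n_obs = nrow(pooled),
      day = if (!is.null(day)) day else NA
    ),
    class = "ll2_fit"
  )
}

#' @export
print.ll2_fit <- function(x, ...) {
  cat(sprintf("Log-logistic dose-response fit (binomial MLE)\n"))
  cat(sprintf("  LC50 (e) = %.4g   slope (b) = %.4g   logLik = %.3f%s\n",
              x$e, x$b, x$loglik,
              if (x$converged) "" else "   [NOT CONVERGED]"))
  if (is.finite(x$se_log_e)) {
    ci <- exp(log(x$e) + c(-1.96, 1.96) * x$se_log_e)
    cat(sprintf("  Wald 95%% CI for LC50: [%.4g, %.4g]\n", ci[1], ci[2]))
  }
  invisible(x)
}

#' @param object An `ll2_fit`.
#' @param newdata Numeric vector of concentrations (>= 0).
#' @param ... Unused.
#' @return For `predict`, the fitted mortality probabilities; p(0) = 0.
#' @rdname fit_log_logistic
#' @export
predict.ll2_fit <- function(object, newdata, ...) {
  if (any(newdata < 0)) stop_input("Concentrations must be >= 0.")
  ifelse(newdata == 0, 0, 1 / (1 + (object$e / newdata)^object$b))
}

#' Fit LC50 per variety
#'
#' Maps [fit_log_logistic()] over each variety in a mortality table.
#'
#' @inheritParams fit_log_logistic
#' @return A tibble with one row per variety: `variety`, `b`, `e`
#'   (the LC50), `se_log_e`, `loglik`, `converged`.
#' @export
fit_lc50_by_variety <- function(table, day = NULL) {
  if (!"variety" %in% names(table)) stop_input("`table` needs a `variety` column.")
  table |>
    dplyr::group_by(.data$variety) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_log_logistic(df, day = day)
      tibble::tibble(b = f$b, e = f$e, se_log_e = f$se_log_e,
                     loglik = f$loglik, converged = f$converged)
    }) |>
    dplyr::ungroup()
}

#' Tolerance classes from LC50 values (exact 1-D k-means)
#'
#' Clusters per-variety LC50 values into `k` tolerance classes by exact
#' one-dimensional k-means: the optimal clusters of a 1-D k-means problem
#' are contiguous in sorted order, so the global within-cluster
#' sum-of-squares optimum is found by dynamic programming over contiguous
#' partitions — no random initialisation and no seed sensitivity. Classes
#' are named by descending centre: `tolerant`, `moderate`, `sensitive`
#' for k = 3 (`class_1` ... otherwise).
#'
#' @param lc50 Named numeric vector (names = varieties) or a tibble with
#'   columns `variety` and `e` such as from [fit_lc50_by_variety()].
#' @param k Number of classes (default 3).
#' @return An object of class `tolerance_classes`: `classes` (tibble:
#'   variety, lc50, class), `centers` (descending), `withinss`, `tot_withinss`.
#' @examples
#' classify_kmeans_1d(c(a = 202, b = 205, c = 250, d = 255, e = 320, f = 322))
#' @export
classify_kmeans_1d <- function(lc50, k = 3) {
  if (is.data.frame(lc50)) {
    if (!all(c("variety", "e") %in% names(lc50))) {
      stop_input("Data-frame input needs columns `variety` and `e`.")
    }
    lc50 <- setNames(lc50$e, lc50$variety)
  }
  k <- check_count(k, "k", min = 1L)
  if (is.null(names(lc50))) names(lc50) <- paste0("v", seq_along(lc50))
  if (length(unique(lc50)) < k) {
    stop_input("Only %d distinct values for k = %d; use a smaller k.",
               length(unique(lc50)), k)
  }

  ord <- order(lc50, names(lc50))
  x <- lc50[ord]
  part <- kmeans1d_dp(as.numeric(x), k)

  cluster_sorted <- rep(seq_len(k), times = diff(c(0, part$breaks)))
  centers <- vapply(split(as.numeric(x), cluster_sorted), mean, numeric(1))
  wss <- vapply(split(as.numeric(x), cluster_sorted),
                function(v) sum((v - mean(v))^2), numeric(1))

  # name classes by descending centre LC50
  lab <- if (k == 3) c("tolerant", "moderate", "sensitive")
         else paste0("class_", seq_len(k))
  by_desc <- order(-centers)
  class_name <- setNames(lab, by_desc)[as.character(cluster_sorted)]

  class_orig <- unname(class_name[match(names(lc50), names(x))])
  classes <- tibble::tibble(
    variety = names(lc50), lc50 = as.numeric(lc50), class = class_orig
  )
  structure(
    list(
      classes = classes,
      centers = sort(centers, decreasing = TRUE),
      withinss = wss[by_desc],
      tot_withinss = sum(wss)
    ),
    class = "tolerance_classes"
  )
}

#' @export
print.tolerance_classes <- function(x, ...) {
  cat(sprintf("Tolerance classes (exact 1-D k-means, k = %d)\n",
              length(x$centers)))
  cat("Centers (descending LC50):",
      paste(signif(x$centers, 5), collapse = ", "), "\n")
  print(dplyr::arrange(x$classes, dplyr::desc(.data$lc50)))
  invisible(x)
}

# Exact 1-D k-means via O(n^2 k) dynamic programming on sorted input.
# Returns the cumulative break indices (end index of each cluster).
kmeans1d_dp <- function(x, k) {
  n <- length(x)
  stopifnot(!is.unsorted(x))
  csum <- cumsum(x)
  csq <- cumsum(x^2)
  # ss(i, j): within-SS of x[i..j]
  ss <- function(i, j) {
    s <- csum[j] - if (i > 1) csum[i - 1] else 0
    q <- csq[j] - if (i > 1) csq[i - 1] else 0
    q - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  for (j in seq_len(n)) cost[1, j] <- ss(1, j)
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:n) {
        for (i in m:j) {
          cand <- cost[m - 1, i - 1] + ss(i, j)
          if (cand < cost[m, j]) {
            cost[m, j] <- cand
            back[m, j] <- i
          }
        }
      }
    }
  }
  breaks <- integer(k)
  j <- n
  for (m in k:1) {
    breaks[m] <- j
    j <- if (m > 1) back[m, j] - 1L else 0L
  }
  list(breaks = breaks, tot_withinss = cost[k, n])
}
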