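#' Orientation-aware min-max normalization
#'
#' Rescales each indicator column of a relative panel to \[0, 1\] so that 1
#' is always the most desirable value: larger-is-better columns use
#' (x - min)/(max - min), smaller-is-better columns the reflected
#' (max - x)/(max - min). After this step the ideal reference series for
#' grey relational analysis is the all-ones vector.
#'
#' @param rel A wide tibble (first column `entity`, remaining columns
#'   numeric indicators), e.g. from [relative_values()].
#' @param orientation Named character vector (`"larger_better"` /
#'   `"smaller_better"`) per indicator. Defaults to the `orientation`
#'   attribute of `rel`; indicators without an entry are treated as
#'   larger-is-better.
#'
#' @return A tibble of the same shape with values in \[0, 1\]. Constant
#'   columns carry no ranking information and are set to 1 with a warning.
#' @export
orient_normalize <- function(rel, orientation = NULL) {
  orientation <- orientation %||% attr(rel, "orientation")
  m <- as_id_matrix(rel, "entity")
  if (nrow(m) < 2) stop_input("Need at least 2 entities to normalize.")
  ori <- rep("larger_better", ncol(m))
  names(ori) <- colnames(m)
  if (!is.null(orientation)) {
    bad <- setdiff(names(orientation), colnames(m))
    if (length(bad)) {
      stop_input("Orientation given for unknown indicator(s): %s.",
                 paste(bad, collapse = ", "))
    }
    ori[names(orientation)] <- orientation
  }
  if (!all(ori %in% c("larger_better", "smaller_better"))) {
    stop_input("Orientations must be 'larger_better' or 'smaller_better'.")
  }

  out <- m
  constant <- character(0)
  for (j in seq_len(ncol(m))) {
    rng <- range(m[, j])
    if (diff(rng) == 0) {
      out[, j] <- 1
      constant <- c(constant, colnames(m)[j])
      next
    }
    out[, j] <- if (ori[j] == "larger_better") {
      (m[, j] - rng[1]) / diff(rng)
    } else {
      (rng[2] - m[, j]) / diff(rng)
    }
  }
  if (length(constant)) {
    warn(sprintf("Constant indicator column(s) set to 1: %s.",
                 paste(constant, collapse = ", ")))
  }
  res <- id_matrix_to_tibble(out, "entity")
  attr(res, "orientation") <- ori
  res
}

#' Grey relational coefficients against the ideal series
#'
#' Deng-type grey relational coefficients of every entity against the ideal
#' reference series (all ones after oriented normalization):
#' \deqn{\xi_i(k) = \frac{\Delta_{min} + \rho\,\Delta_{max}}
#'                      {\Delta_i(k) + \rho\,\Delta_{max}}}
#' with \eqn{\Delta_i(k) = |1 - x_i(k)|} and the min/max taken globally
#' over all entities and indicators (two-level min/max).
#'
#' @param normalized Tibble from [orient_normalize()] (entity + indicator
#'   columns, values in \[0, 1\]).
#' @param rho Distinguishing coefficient in (0, 1\]; 0.5 by convention.
#'   Smaller values sharpen the contrast between good and bad cells.
#'
#' @return Tibble of coefficients, same shape as the input; every value
#'   lies in \[rho/(1+rho), 1\] when the best cell is ideal.
#' @export
grey_coefficients <- function(normalized, rho = 0.5) {
  check_number(rho, "rho")
  if (rho <= 0 || rho > 1) stop_input("`rho` must be in (0, 1].")
  m <- as_id_matrix(normalized, "entity")
  if (any(m < -1e-9) || any(m > 1 + 1e-9)) {
    stop_input("Normalized values must lie in [0, 1]; run orient_normalize() first.")
  }
  delta <- abs(1 - m)
  dmin <- min(delta)
  dmax <- max(delta)
  if (dmax == 0) {
    warn("All entities equal the ideal reference; all coefficients are 1.")
    xi <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
  } else {
    xi <- (dmin + rho * dmax) / (delta + rho * dmax)
  }
  id_matrix_to_tibble(xi, "entity")
}

#' Grey relational degree
#'
#' Collapses the coefficient matrix to one score per entity,
#' \eqn{\gamma_i = \sum_k w_k \xi_i(k)}; uniform weights (the row mean)
#' when no weights are given.
#'
#' @param xi Coefficient tibble from [grey_coefficients()].
#' @param weights Optional non-negative weights summing to 1, one per
#'   indicator (in column order, or named by indicator).
#'
#' @return Tibble with columns `entity`, `gamma`, and `rank` (1 = closest
#'   to the ideal; ties share the minimum rank).
#' @export
relational_degree <- function(xi, weights = NULL) {
  m <- as_id_matrix(xi, "entity")
  if (is.null(weights)) {
    weights <- rep(1 / ncol(m), ncol(m))
  } else {
    if (length(weights) != ncol(m)) {
      stop_input("Got %d weights for %d indicators.", length(weights), ncol(m))
    }
    if (!is.null(names(weights))) {
      if (!setequal(names(weights), colnames(m))) {
        stop_input("Weight names do not match indicator names.")
      }
      weights <- weights[colnames(m)]
    }
    if (any(weights < 0)) stop_input("Weights must be non-negative.")
    if (abs(sum(weights) - 1) > 1e-8) stop_input("Weights must sum to 1.")
  }
  gamma <- unname(drop(m %*% weights))
  tibble::tibble(
    entity = rownames(m),
    gamma = gamma,
    rank = rank(-gamma, ties.method = "min")
  )
}

#' CRITIC objective indicator weights
#'
#' CRITIC (CRiteria Importance Through Intercriteria Correlation) weights:
#' each indicator's information content is its dispersion times its total
#' decorrelation from the other indicators,
#' \eqn{C_j = \sigma_j \sum_k (1 - r_{jk})}, normalised to sum to one.
#' \eqn{\sigma_j} is the sample (n-1) standard deviation of the normalised
#' column, \eqn{r_{jk}} the Pearson correlation (not absolute-valued, per
#' the original formulation; the j = k term contributes 0).
#'
#' @param normalized Tibble from [orient_normalize()].
#' @return Named numeric vector of weights summing to 1. A constant column
#'   gets weight 0; if every \eqn{C_j} is 0 the weights fall back to
#'   uniform with a warning.
#' @export
critic_weights <- function(normalized) {
  m <- as_id_matrix(normalized, "entity")
  if (ncol(m) < 2) stop_input("CRITIC needs at least 2 indicators.")
  if (nrow(m) < 3) stop_input("CRITIC needs at least 3 entities.")
  sds <- apply(m, 2, sd)
  r <- suppressWarnings(cor(m))      # NA rows for constant columns
  r[!is.finite(r)] <- 0              # constant columns decorrelate fully ...
  diag(r) <- 1                       # own term contributes 1 - r_jj = 0
  cj <- sds * rowSums(1 - r)
  cj[sds == 0] <- 0                  # ... but carry no information themselves
  if (sum(cj) == 0) {
    warn("All CRITIC information measures are zero; falling back to uniform weights.")
    w <- rep(1 / ncol(m), ncol(m))
  } else {
    w <- cj / sum(cj)
  }
  setNames(w, colnames(m))
}

#' Agreement between two relational-degree vectors
#'
#' Squared Pearson correlation between the unweighted and weighted grey
#' relational degrees, used as a gate: high agreement means the weighting
#' scheme does not change the story and either ranking can be used; low
#' agreement means the weights matter and both rankings should inform the
#' decision.
#'
#' @param gamma_unweighted,gamma_weighted Equal-length numeric vectors
#'   (length >= 3) of relational degrees over the same entities.
#' @param threshold Agreement threshold on R^2 for the `agree` flag.
#' @return A list with `r2` and logical `agree`.
#' @export
agreement_r2 <- function(gamma_unweighted, gamma_weighted, threshold = 0.9) {
  if (length(gamma_unweighted) != length(gamma_weighted)) {
    stop_input("Degree vectors must have equal length.")
  }
  if (length(gamma_unweighted) < 3) stop_input("Need at least 3 entities.")
  if (sd(gamma_unweighted) == 0 || sd(gamma_weighted) == 0) {
    stop_input("Zero variance in a degree vector; R^2 undefined.")
  }
  r2 <- cor(gamma_unweighted, gamma_weighted)^2
  list(r2 = r2, agree = r2 >= threshold)
}

#' Full grey relational ranking of a relative panel
#'
#' Convenience wrapper chaining [orient_normalize()],
#' [grey_coefficients()], [critic_weights()] and [relational_degree()]
#' into one fitted object holding both the unweighted and the weighted
#' ranking plus their agreement.
#'
#' @inheritParams orient_normalize
#' @inheritParams grey_coefficients
#' @param weight_mode `"critic"` (default) or `"uniform"`; with
#'   `"uniform"` the weighted ranking equals the unweighted one.
#' @param agree_threshold Passed to [agreement_r2()].
#' @return An object of class `grey_result` with elements `xi`, `weights`,
#'   `degrees` (tibble: entity, gamma_unweighted, gamma_weighted,
#'   rank_unweighted, rank_weighted), `r2_agreement`, `agree`, `rho`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' rel <- tibble::tibble(entity = c("v1", "v2", "v3", "v4"),
#'                       a = c(1, .8, .6, .9), b = c(.2, .5, .9, .3))
#' grey_rank(rel, orientation = c(a = "larger_better", b = "smaller_better"))
#' @export
grey_rank <- function(rel, orientation = NULL, rho = 0.5,
                      weight_mode = c("critic", "uniform"),
                      agree_threshold = 0.9) {
  weight_mode <- match.arg(weight_mode)
  normalized <- orient_normalize(rel, orientation)
  xi <- grey_coefficients(normalized, rho = rho)
  n_ind <- ncol(xi) - 1L
  w_uniform <- setNames(rep(1 / n_ind, n_ind), names(xi)[-1])
  w <- if (weight_mode == "critic") critic_weights(normalized) else w_uniform
  du <- relational_degree(xi)
  dw <- relational_degree(xi, weights = w)
  ag <- tryCatch(
    agreement_r2(du$gamma, dw$gamma, threshold = agree_threshold),
    stresscreen_input_error = function(e) list(r2 = NA_real_, agree = NA)
  )
  structure(
    list(
      xi = xi,
      weights = w,
      degrees = tibble::tibble(
        entity = du$entity,
        gamma_unweighted = du$gamma,
        gamma_weighted = dw$gamma,
        rank_unweighted = du$rank,
        rank_weighted = dw$rank
      ),
      r2_agreement = ag$r2,
      agree = ag$agree,
      rho = rho,
      weight_mode = weight_mode
    ),
    class = "grey_result"
  )
}

#' @export
print.grey_result <- function(x, ...) {
  cat(sprintf(
    "Grey relational ranking: %d entities, %d indicators (rho = %g, %s weights)\n",
    nrow(x$degrees), length(x$weights), x$rho, x$weight_mode
  ))
  cat(sprintf("Weighted/unweighted agreement R^2 = %.3f (%s)\n",
              x$r2_agreement,
              if (isTRUE(x$agree)) "agree" else "weights matter"))
  print(dplyr::arrange(x$degrees, .data$rank_weighted), n = 10)
  invisible(x)
}

#' Key time point by weighted/unweighted divergence
#'
#' Given one (unweighted, weighted) relational-degree summary per time
#' point, selects the time point where the two disagree most — the point
#' where the objective weighting carries the most information and hence
#' the most discriminating sampling time.
#'
#' @param summaries Data frame with columns `timepoint`,
#'   `gamma_unweighted`, `gamma_weighted` (one row per time point).
#' @return A list with `timepoint` (the argmax of the absolute divergence;
#'   ties broken by the earliest time point, with a warning) and
#'   `divergence` (tibble sorted by time point with the per-point
#'   divergence).
#' @export
select_key_timepoint <- function(summaries) {
  req <- c("timepoint", "gamma_unweighted", "gamma_weighted")
  if (!all(req %in% names(summaries))) {
    stop_input("`summaries` needs columns %s.", paste(req, collapse = ", "))
  }
  if (nrow(summaries) < 2) stop_input("Need at least 2 time points.")
  if (anyNA(summaries[req])) stop_input("Missing degree summaries.")
  div <- summaries |>
    dplyr::mutate(
      divergence = abs(.data$gamma_weighted - .data$gamma_unweighted)
    ) |>
    dplyr::arrange(.data$timepoint)
  best <- max(div$divergence)
  hits <- which(div$divergence == best)
  if (length(hits) > 1) {
    warn("Tied divergence across time points; returning the earliest.")
  }
  list(timepoint = div$timepoint[hits[1]], divergence = div)
}
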