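# broom-style tidiers for the fitted objects.

#' @exportS3Method generics::tidy
tidy.grey_result <- function(x, ...) {
  x$degrees
}

#' @exportS3Method generics::glance
glance.grey_result <- function(x, ...) {
  tibble::tibble(
    n_entities = nrow(x$degrees),
    n_indicators = length(x$weights),
    rho = x$rho,
    weight_mode = x$weight_mode,
    r2_agreement = x$r2_agreement,
    agree = x$agree
  )
}

#' @exportS3Method generics::tidy
tidy.ll2_fit <- function(x, ...) {
  tibble::tibble(
    term = c("b", "e"),
    estimate = c(x$b, x$e),
    std.error = c(NA_real_, x$e * x$se_log_e)  # delta method from log scale
  )
}

#' @exportS3Method generics::glance
glance.ll2_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    converged = x$converged,
    n_obs = x$n_obs,
    day = x$day
  )
}

#' @exportS3Method generics::tidy
tidy.tolerance_classes <- function(x, ...) {
  x$classes
}

#' @exportS3Method generics::glance
glance.tolerance_classes <- function(x, ...) {
  tibble::tibble(
    k = length(x$centers),
    tot_withinss = x$tot_withinss
  )
}

#' @exportS3Method generics::tidy
tidy.soft_threshold_scan <- function(x, ...) {
  x$scan
}

#' @exportS3Method generics::glance
glance.soft_threshold_scan <- function(x, ...) {
  tibble::tibble(
    beta = x$beta,
    target = x$target,
    reached_target = x$reached_target,
    best_fit_index = max(x$scan$fit_index)
  )
}

#' @exportS3Method generics::tidy
tidy.module_assignment <- function(x, ...) {
  x$labels
}

#' @exportS3Method generics::glance
glance.module_assignment <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$labels),
    n_modules = length(setdiff(unique(x$labels$module), "grey")),
    n_grey = sum(x$labels$module == "grey"),
    cut_height_used = x$cut_height_used
  )
}

#' @exportS3Method generics::tidy
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$r,
    p.value = x$p,
    nperm = x$nperm,
    alternative = x$alternative
  )
}

#' @exportS3Method generics::tidy
tidy.hub_selection <- function(x, ...) {
  dplyr::mutate(x$ranking, module = x$module, .before = 1)
}

#' @exportS3Method generics::tidy
tidy.venn_partition <- function(x, ...) {
  x$counts
}
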