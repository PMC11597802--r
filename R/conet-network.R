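#' Correlation-power adjacency matrix
#'
#' Weighted network adjacency from pairwise Pearson correlation of gene
#' expression profiles: `|cor|^beta` (unsigned, the default) or
#' `((1 + cor)/2)^beta` (signed, which sends strong negative correlation
#' to 0 instead of 1). Raising to the soft-threshold power `beta`
#' suppresses weak correlations continuously instead of hard-thresholding.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param beta Soft-threshold power (>= 1).
#' @param mode `"unsigned"` or `"signed"`.
#' @return Symmetric gene x gene matrix with unit diagonal.
#' @export
adjacency_matrix <- function(expr, beta = 6, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  check_number(beta, "beta", lower = 1)
  m <- as_id_matrix(expr, "gene_id")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    stop_input("Zero-variance gene(s): %s.",
               paste(head(rownames(m)[sds == 0], 5), collapse = ", "))
  }
  cc <- cor(t(m))
  a <- if (mode == "unsigned") abs(cc)^beta else ((1 + cc) / 2)^beta
  diag(a) <- 1
  a
}

#' Soft-threshold scan for approximate scale-free topology
#'
#' For each candidate power the unsigned adjacency is formed, each gene's
#' connectivity k is summed, k is binned into equal-count bins, and
#' log10(frequency) is regressed on log10(mean k). The scale-free fit
#' index is that regression's R^2, signed negative when the slope is
#' positive (a scale-free degree distribution must decay). The chosen
#' power is the smallest one whose fit index reaches `target`; when none
#' does, the argmax is returned with `reached_target = FALSE`.
#'
#' @param expr Expression tibble (`gene_id` + sample columns).
#' @param powers Candidate integer powers.
#' @param target Fit-index plateau target (default 0.85).
#' @param n_bins Connectivity bins for the fit-index regression; reduced
#'   automatically (with a warning) when there are fewer distinct
#'   connectivity values.
#' @return An object of class `soft_threshold_scan`: `scan` (tibble:
#'   power, fit_index, mean_connectivity), `beta` (chosen power),
#'   `target`, `reached_target`.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, target = 0.85,
                                n_bins = 10) {
  check_number(target, "target", lower = -1, upper = 1)
  m <- as_id_matrix(expr, "gene_id")
  if (ncol(m) < 4) stop_input("Need at least 4 samples.")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    stop_input("Zero-variance gene(s): %s.",
               paste(head(rownames(m)[sds == 0], 5), collapse = ", "))
  }
  abscor <- abs(cor(t(m)))
  diag(abscor) <- 0

  rows <- purrr::map_dfr(powers, function(beta) {
    k <- rowSums(abscor^beta)
    tibble::tibble(
      power = beta,
      fit_index = scale_free_fit_index(k, n_bins = n_bins),
      mean_connectivity = mean(k)
    )
  })
  hit <- which(rows$fit_index >= target)
  if (length(hit) > 0) {
    beta <- rows$power[hit[1]]
    reached <- TRUE
  } else {
    beta <- rows$power[which.max(rows$fit_index)]
    reached <- FALSE
    warn(sprintf(
      "No power reaches fit index %.2f; using argmax power %d (fit %.3f).",
      target, beta, max(rows$fit_index)))
  }
  structure(
    list(scan = rows, beta = beta, target = target, reached_target = reached),
    class = "soft_threshold_scan"
  )
}

# Scale-free topology fit index: R^2 of log10(frequency) on log10(mean k)
# over equal-width connectivity bins (empty bins dropped), negated when
# the slope is positive — a scale-free degree distribution must decay.
scale_free_fit_index <- function(k, n_bins = 10) {
  k <- k[k > 0]
  n_distinct <- length(unique(k))
  if (n_distinct < 2) return(0)
  if (n_distinct < n_bins) {
    warn(sprintf("Only %d distinct connectivity values; using %d bins.",
                 n_distinct, n_distinct))
    n_bins <- n_distinct
  }
  bins <- cut(k, breaks = n_bins, labels = FALSE, include.lowest = TRUE)
  df <- tibble::tibble(k = k, bin = bins) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_k = mean(.data$k), freq = dplyr::n(),
                     .groups = "drop") |>
    dplyr::filter(.data$mean_k > 0)
  if (nrow(df) < 3 || length(unique(df$mean_k)) < 2) return(0)
  lx <- log10(df$mean_k)
  ly <- log10(df$freq)
  if (sd(ly) == 0) return(0)
  r <- cor(lx, ly)
  if (is.finite(r) && r > 0) -r^2 else r^2
}

#' @export
print.soft_threshold_scan <- function(x, ...) {
  cat(sprintf(
    "Soft-threshold scan: chosen beta = %d (target %.2f %s)\n",
    x$beta, x$target,
    if (x$reached_target) "reached" else "NOT reached; argmax fallback"))
  print(x$scan, n = nrow(x$scan))
  invisible(x)
}

#' Topological overlap matrix
#'
#' Converts an adjacency matrix into topological overlap similarity:
#' \deqn{\omega_{ij} = \frac{L_{ij} + a_{ij}}
#'                          {\min(k_i, k_j) + 1 - a_{ij}}}
#' where \eqn{L_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} counts shared
#' neighbourhood and \eqn{k_i = \sum_{u \ne i} a_{iu}} is connectivity.
#' Two genes overlap strongly when they are directly connected *and* talk
#' to the same other genes, which is more robust to single spurious
#' correlations than raw adjacency.
#'
#' @param a Symmetric adjacency matrix with unit diagonal and entries in
#'   \[0, 1\].
#' @return Symmetric matrix of the same size with unit diagonal and
#'   entries in \[0, 1\].
#' @export
tom_similarity <- function(a) {
  check_square_symmetric(a, "a")
  if (any(a < 0) || any(a > 1)) stop_input("Adjacency entries must be in [0, 1].")
  if (any(abs(diag(a) - 1) > 1e-8)) stop_input("Adjacency must have unit diagonal.")
  k <- rowSums(a) - 1
  # (a %*% a)_ij = 2 a_ij + L_ij for i != j (unit diagonal)
  l <- a %*% a - 2 * a
  kmin <- outer(k, k, pmin)
  w <- (l + a) / (kmin + 1 - a)
  diag(w) <- 1
  dimnames(w) <- dimnames(a)
  # clamp tiny negatives from floating point
  w[w < 0 & w > -1e-12] <- 0
  w
}
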