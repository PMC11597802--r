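# Internal validation and matrix helpers shared across stages.

# stop with a consistent class so tests can match on it
stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "stresscreen_input_error")
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("`%s` must be a single finite number.", name)
  }
  if (x < lower || x > upper) {
    stop_input("`%s` must be in [%s, %s], got %s.", name, lower, upper, x)
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name, lower = min)
  if (x != as.integer(x)) stop_input("`%s` must be a whole number.", name)
  invisible(as.integer(x))
}

# First-column-id wide tibble -> numeric matrix with rownames.
# Used for expression (gene_id x samples), traits (sample_id x traits) and
# indicator panels (entity x indicators).
as_id_matrix <- function(df, id_col) {
  if (!is.data.frame(df)) stop_input("Expected a data frame with an `%s` column.", id_col)
  if (!id_col %in% names(df)) {
    stop_input("Column `%s` is missing from the input.", id_col)
  }
  ids <- as.character(df[[id_col]])
  if (anyDuplicated(ids)) {
    stop_input("Duplicate `%s` values: %s.", id_col,
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[setdiff(names(df), id_col)])
  if (!is.numeric(m)) stop_input("All non-id columns must be numeric.")
  rownames(m) <- ids
  m
}

id_matrix_to_tibble <- function(m, id_col) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)), out)
  out
}

check_square_symmetric <- function(m, name, tol = 1e-8) {
  if (!is.matrix(m) || !is.numeric(m) || nrow(m) != ncol(m)) {
    stop_input("`%s` must be a square numeric matrix.", name)
  }
  if (max(abs(m - t(m))) > tol) {
    stop_input("`%s` must be symmetric.", name)
  }
  invisible(m)
}

# Strict upper triangle as a vector (column-major, matches upper.tri order)
upper_tri_vec <- function(m) m[upper.tri(m)]

# Deterministic per-unit sub-seed derived from one master seed; keeps every
# generated stream reproducible and below .Machine$integer.max (Lehmer mix
# in double precision, exact for these magnitudes).
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 +
                as.numeric(offset) * 16807) %% 2147483647) + 1L
}
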