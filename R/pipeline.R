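#' Pipeline configuration
#'
#' Builds and validates the flat configuration driving [run_pipeline()].
#' Unknown keys are rejected so typos fail before any stage runs.
#'
#' @param ... Named overrides of the defaults below.
#' @return A validated `pipeline_config` list.
#'
#' @section Keys:
#' \describe{
#'   \item{seed}{Global seed; every stage's randomness derives from it.}
#'   \item{simulate}{Generate inputs with the built-in simulators (the
#'     only supported input source in this release).}
#'   \item{stages}{Character vector of stages to run, in dependency
#'     order, among `screen`, `lc50`, `timepoint`, `network`, `hubs`,
#'     `mantel`.}
#'   \item{rho}{GRA distinguishing coefficient (0, 1].}
#'   \item{weight_mode}{`"critic"` or `"uniform"`.}
#'   \item{agree_threshold}{R^2 gate on weighted/unweighted agreement.}
#'   \item{k_classes}{Tolerance classes for 1-D k-means.}
#'   \item{min_expr}{Expression filter floor.}
#'   \item{filter_stat}{`"mean"` or `"max"` filter summary.}
#'   \item{powers}{Candidate soft-threshold powers.}
#'   \item{sft_target}{Scale-free fit plateau target.}
#'   \item{beta}{Soft-threshold power used to build the network: an
#'     integer (default 6, the conventional unsigned-network power) or
#'     `"scan"` to use the scan-chosen power. The scan is always run and
#'     reported either way.}
#'   \item{network_mode}{`"unsigned"` or `"signed"` adjacency.}
#'   \item{min_module_size}{Minimum module size.}
#'   \item{cut_height}{Absolute TOM-dissimilarity tree-cut height.}
#'   \item{top_k}{Hub genes per module.}
#'   \item{edge_quantile}{Within-module edge threshold quantile.}
#'   \item{hub_cor_threshold}{Hub-network |cor| edge threshold.}
#'   \item{nperm}{Mantel permutations.}
#'   \item{mantel_metric}{`"euclidean"` or `"cor"`.}
#'   \item{out_dir}{Optional directory; when set, every stage artifact is
#'     written there as CSV/TSV/JSON.}
#'   \item{sim_panel, sim_mortality, sim_expression}{Optional lists of
#'     overrides passed to the respective `*_sim_config()` constructors.}
#' }
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    simulate = TRUE,
    stages = c("screen", "lc50", "timepoint", "network", "hubs", "mantel"),
    rho = 0.5,
    weight_mode = "critic",
    agree_threshold = 0.9,
    k_classes = 3L,
    min_expr = 2,
    filter_stat = "mean",
    powers = 1:20,
    sft_target = 0.85,
    beta = 6L,
    network_mode = "unsigned",
    min_module_size = 30L,
    cut_height = 0.95,
    top_k = 5L,
    edge_quantile = 0.95,
    hub_cor_threshold = 0.8,
    nperm = 999L,
    mantel_metric = "euclidean",
    out_dir = NULL,
    sim_panel = list(),
    sim_mortality = list(),
    sim_expression = list()
  )
  overrides <- list(...)
  if (length(overrides) == 1 && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop_input("Unknown configuration key(s): %s.",
               paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides)

  # pre-flight validation: fail before any stage runs
  cfg$seed <- check_count(cfg$seed, "seed")
  bad_stage <- setdiff(cfg$stages, defaults$stages)
  if (length(bad_stage)) {
    stop_input("Unknown stage(s): %s.", paste(bad_stage, collapse = ", "))
  }
  check_number(cfg$rho, "rho"); if (cfg$rho <= 0 || cfg$rho > 1)
    stop_input("`rho` must be in (0, 1].")
  if (!cfg$weight_mode %in% c("critic", "uniform"))
    stop_input("`weight_mode` must be 'critic' or 'uniform'.")
  check_number(cfg$agree_threshold, "agree_threshold", lower = 0, upper = 1)
  cfg$k_classes <- check_count(cfg$k_classes, "k_classes", min = 2L)
  check_number(cfg$min_expr, "min_expr", lower = 0)
  if (!cfg$filter_stat %in% c("mean", "max"))
    stop_input("`filter_stat` must be 'mean' or 'max'.")
  if (any(cfg$powers < 1)) stop_input("`powers` must be >= 1.")
  check_number(cfg$sft_target, "sft_target", lower = 0, upper = 1)
  if (!(identical(cfg$beta, "scan") ||
        (is.numeric(cfg$beta) && length(cfg$beta) == 1 && cfg$beta >= 1)))
    stop_input("`beta` must be a power >= 1 or \"scan\".")
  if (!cfg$network_mode %in% c("unsigned", "signed"))
    stop_input("`network_mode` must be 'unsigned' or 'signed'.")
  cfg$min_module_size <- check_count(cfg$min_module_size, "min_module_size",
                                     min = 1L)
  check_number(cfg$cut_height, "cut_height", lower = 0, upper = 1)
  cfg$top_k <- check_count(cfg$top_k, "top_k", min = 1L)
  check_number(cfg$edge_quantile, "edge_quantile", lower = 0, upper = 1)
  check_number(cfg$hub_cor_threshold, "hub_cor_threshold", lower = 0, upper = 1)
  cfg$nperm <- check_count(cfg$nperm, "nperm", min = 1L)
  if (!cfg$mantel_metric %in% c("euclidean", "cor"))
    stop_input("`mantel_metric` must be 'euclidean' or 'cor'.")
  if (!isTRUE(cfg$simulate)) {
    stop_input("This release only runs on simulated inputs; set simulate = TRUE.")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path Path to a flat YAML document of [pipeline_config()] keys.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_input("Config file not found: %s.", path)
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full screening-to-network pipeline
#'
#' Executes the enabled stages in dependency order on simulated inputs:
#' variety screening by grey relational ranking (`screen`), LC50 fitting
#' and tolerance classification (`lc50`), key-time-point selection
#' (`timepoint`), co-expression network and module-trait analysis
#' (`network`), hub selection (`hubs`) and the Mantel linkage of hub
#' expression to traits (`mantel`). All randomness derives from the
#' single `seed`; identical configurations give identical reports.
#'
#' @param config A [pipeline_config()] (or a list of overrides).
#' @return A list of class `pipeline_report` with one element per
#'   executed stage plus `config_digest` (the parameters and derived
#'   sub-seeds actually used).
#' @examples
#' \donttest{
#' rep <- run_pipeline(pipeline_config(
#'   nperm = 99,
#'   sim_expression = list(genes_per_module = 20, n_background = 30)))
#' rep$lc50$classes
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  report <- list()
  sub <- function(stage) derive_seed(config$seed, match(
    stage, c("screen", "lc50", "timepoint", "network", "hubs", "mantel")))
  out <- list()

  stages <- config$stages

  # --- screening: grey relational ranking of relative indicators -------
  if ("screen" %in% stages) {
    sim <- simulate_indicator_panel(do.call(panel_sim_config, utils::modifyList(
      list(seed = sub("screen")), config$sim_panel)))
    rel <- relative_values(sim$panel, orientation = sim$orientation)
    gr <- grey_rank(rel, rho = config$rho,
                    weight_mode = config$weight_mode,
                    agree_threshold = config$agree_threshold)
    out$screen <- list(
      grey = gr,
      true_ranking = sim$true_ranking,
      recovered_ranking = gr$degrees$entity[order(gr$degrees$rank_weighted)],
      spearman_vs_truth = cor(
        match(gr$degrees$entity, sim$true_ranking),
        gr$degrees$rank_weighted, method = "spearman")
    )
  }

  # --- LC50 fitting and tolerance classes ------------------------------
  if ("lc50" %in% stages) {
    mcfg <- do.call(mortality_sim_config, utils::modifyList(
      list(seed = sub("lc50")), config$sim_mortality))
    tbl <- simulate_mortality(mcfg)
    fits <- fit_lc50_by_variety(tbl)
    classes <- classify_kmeans_1d(fits, k = config$k_classes)
    out$lc50 <- list(
      fits = fits,
      classes = classes,
      truth = mcfg$varieties,
      median_rel_error = stats::median(
        abs(fits$e - mcfg$varieties$e[match(fits$variety,
                                            mcfg$varieties$variety)]) /
          mcfg$varieties$e[match(fits$variety, mcfg$varieties$variety)])
    )
  }

  # --- key time point ---------------------------------------------------
  if ("timepoint" %in% stages) {
    out$timepoint <- timepoint_stage(config, sub("timepoint"))
  }

  # --- co-expression network -------------------------------------------
  need_net <- any(c("network", "hubs", "mantel") %in% stages)
  if (need_net) {
    ecfg <- do.call(expr_sim_config, utils::modifyList(
      list(seed = sub("network")), config$sim_expression))
    sim <- simulate_expression(ecfg)
    expr <- filter_genes(sim$expression, min_expr = config$min_expr,
                         stat = config$filter_stat)
    qc <- sample_qc(expr)
    scan <- suppressWarnings(pick_soft_threshold(
      expr, powers = config$powers, target = config$sft_target))
    beta_used <- if (identical(config$beta, "scan")) scan$beta else config$beta
    adj <- adjacency_matrix(expr, beta = beta_used, mode = config$network_mode)
    tom <- tom_similarity(adj)
    modules <- detect_modules(tom, min_size = config$min_module_size,
                              cut_height = config$cut_height)
    me <- module_eigengene(expr, modules$labels)
    mt <- module_trait_correlation(me$eigengenes, sim$traits)
    if ("network" %in% stages) {
      out$network <- list(
        n_kept = attr(expr, "n_kept"), n_removed = attr(expr, "n_removed"),
        qc = qc, scan = scan, beta_used = beta_used, modules = modules,
        eigengenes = me, module_trait = mt,
        planted = sim$modules
      )
    }
  }

  # --- hubs -------------------------------------------------------------
  if ("hubs" %in% stages) {
    non_grey <- setdiff(unique(modules$labels$module), "grey")
    hubs <- purrr::map(setNames(non_grey, non_grey), function(mod) {
      k <- min(config$top_k,
               sum(modules$labels$module == mod))
      intramodular_hubs(tom, modules$labels, mod, top_k = k,
                        edge_quantile = config$edge_quantile)
    })
    all_hub_ids <- unique(unlist(purrr::map(hubs, "hubs")))
    net <- if (length(all_hub_ids) >= 2) {
      hub_network(expr, all_hub_ids,
                  cor_threshold = config$hub_cor_threshold)
    } else NULL
    out$hubs <- list(per_module = hubs, network = net,
                     hub_ids = all_hub_ids)
  }

  # --- Mantel linkage ---------------------------------------------------
  if ("mantel" %in% stages) {
    hub_ids <- if ("hubs" %in% stages) out$hubs$hub_ids else {
      head(modules$labels$gene_id[modules$labels$module != "grey"], 10)
    }
    hub_expr <- expr[match(hub_ids, expr$gene_id), , drop = FALSE]
    d_genes <- sample_distance(
      id_matrix_to_tibble(t(as_id_matrix(hub_expr, "gene_id")), "sample_id"),
      metric = config$mantel_metric)
    d_traits <- sample_distance(sim$traits, metric = config$mantel_metric)
    out$mantel <- mantel_test(d_genes, d_traits, nperm = config$nperm,
                              seed = sub("mantel"))
  }

  params <- unclass(config)
  params$out_dir <- NULL        # path is environment-specific, not a result
  out$config_digest <- list(
    parameters = params,
    sub_seeds = setNames(
      vapply(c("screen", "lc50", "timepoint", "network", "hubs", "mantel"),
             sub, integer(1)),
      c("screen", "lc50", "timepoint", "network", "hubs", "mantel"))
  )
  report <- structure(out, class = "pipeline_report")
  if (!is.null(config$out_dir)) write_pipeline_report(report, config$out_dir)
  report
}

# time-point stage: simulate a per-day physiological panel for two
# contrasted varieties, summarise each day once unweighted and once
# CRITIC-weighted, and pick the day where the two degree summaries
# diverge most. Entities are the time points; criteria are the relative
# indicators averaged over the two varieties.
timepoint_stage <- function(config, seed) {
  days <- c(0, 1, 3, 5, 7)
  phys <- c(H2O2 = "smaller_better", MDA = "smaller_better",
            SS = "larger_better", Pro = "larger_better",
            SOD = "larger_better", POD = "larger_better",
            CAT = "larger_better", Chl = "larger_better")
  # stress effects deepen with day; two varieties with different tolerance
  per_day <- purrr::map_dfr(seq_along(days), function(i) {
    strength <- (days[i] / max(days))
    sim <- simulate_indicator_panel(panel_sim_config(
      n_varieties = 2,
      indicators = phys,
      tolerance_scores = c(0.9, 0.3),
      effect_scale = 0.6 * strength,
      noise_sd = 0.05,
      seed = derive_seed(seed, i)))
    rel <- relative_values(sim$panel, orientation = sim$orientation)
    m <- as_id_matrix(rel, "entity")
    tibble::tibble(timepoint = days[i],
                   indicator = colnames(m),
                   value = colMeans(m))
  })
  rel_days <- per_day |>
    tidyr::pivot_wider(names_from = "indicator", values_from = "value") |>
    dplyr::rename(entity = "timepoint") |>
    dplyr::mutate(entity = as.character(.data$entity))
  attr(rel_days, "orientation") <- phys
  gr <- grey_rank(rel_days, rho = config$rho, weight_mode = "critic",
                  agree_threshold = config$agree_threshold)
  key <- select_key_timepoint(tibble::tibble(
    timepoint = as.numeric(gr$degrees$entity),
    gamma_unweighted = gr$degrees$gamma_unweighted,
    gamma_weighted = gr$degrees$gamma_weighted))
  list(grey = gr, key_timepoint = key$timepoint, divergence = key$divergence)
}

#' Write every pipeline artifact as plain files
#'
#' @param report A `pipeline_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w_csv <- function(df, name) utils::write.csv(
    df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  if (!is.null(report$screen)) {
    w_csv(report$screen$grey$degrees, "screen_degrees.csv")
    jsonlite::write_json(
      list(weights = as.list(report$screen$grey$weights),
           r2_agreement = report$screen$grey$r2_agreement,
           spearman_vs_truth = report$screen$spearman_vs_truth),
      file.path(dir, "screen_summary.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$lc50)) {
    w_csv(report$lc50$fits, "lc50_fits.csv")
    w_csv(report$lc50$classes$classes, "lc50_classes.csv")
  }
  if (!is.null(report$timepoint)) {
    w_csv(report$timepoint$divergence, "timepoint_divergence.csv")
  }
  if (!is.null(report$network)) {
    w_csv(report$network$scan$scan, "soft_threshold_scan.csv")
    w_csv(report$network$modules$labels, "module_labels.csv")
    w_csv(report$network$eigengenes$eigengenes, "module_eigengenes.csv")
    w_csv(report$network$module_trait, "module_trait_correlation.csv")
  }
  if (!is.null(report$hubs)) {
    w_csv(purrr::map_dfr(report$hubs$per_module, function(h) {
      dplyr::mutate(head(h$ranking, length(h$hubs)), module = h$module)
    }), "hub_genes.csv")
    if (!is.null(report$hubs$network)) w_csv(report$hubs$network$edges,
                                             "hub_network_edges.csv")
  }
  if (!is.null(report$mantel)) {
    jsonlite::write_json(
      unclass(report$mantel), file.path(dir, "mantel.json"),
      auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    report$config_digest, file.path(dir, "run_report.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  if (!is.null(x$screen)) {
    cat(sprintf("  screen:   %d varieties ranked, agreement R^2 = %.3f\n",
                nrow(x$screen$grey$degrees), x$screen$grey$r2_agreement))
  }
  if (!is.null(x$lc50)) {
    tab <- table(x$lc50$classes$classes$class)
    cat(sprintf("  lc50:     %s\n",
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  }
  if (!is.null(x$timepoint)) {
    cat(sprintf("  timepoint: day %s\n", x$timepoint$key_timepoint))
  }
  if (!is.null(x$network)) {
    cat(sprintf("  network:  beta = %d, %d module(s)\n",
                x$network$beta_used,
                length(setdiff(unique(x$network$modules$labels$module),
                               "grey"))))
  }
  if (!is.null(x$hubs)) {
    cat(sprintf("  hubs:     %d hub genes\n", length(x$hubs$hub_ids)))
  }
  if (!is.null(x$mantel)) {
    cat(sprintf("  mantel:   r = %.3f, p = %.4g\n", x$mantel$r, x$mantel$p))
  }
  invisible(x)
}
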