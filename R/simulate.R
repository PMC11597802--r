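# Seeded simulators. Each generator is a pure function of its config:
# the same config (including seed) gives byte-identical output, and every
# per-variety / per-gene stream is drawn from a sub-seed derived
# deterministically from the master seed.

#' Configuration for the indicator-panel simulator
#'
#' @param n_varieties Number of varieties (>= 2).
#' @param indicators Named character vector: indicator name ->
#'   `"larger_better"` / `"smaller_better"`.
#' @param tolerance_scores Latent per-variety tolerance in \[0, 1\];
#'   defaults to an evenly spaced grid (variety 1 most tolerant).
#' @param effect_scale Multiplicative treatment effect per unit of
#'   (1 - tolerance): a fully sensitive variety loses (gains) this
#'   fraction of its control value for larger- (smaller-) is-better
#'   indicators.
#' @param noise_sd Relative (multiplicative) measurement noise sd.
#' @param baselines Optional named vector of control-arm baselines per
#'   indicator; defaults to values spread over \[5, 50\].
#' @param seed Integer seed.
#' @return A `panel_sim_config` list.
#' @export
panel_sim_config <- function(n_varieties = 15,
                             indicators = c(
                               plant_height = "larger_better",
                               growth_rate = "larger_better",
                               fresh_weight = "larger_better",
                               dry_weight = "larger_better",
                               biomass_accumulation = "larger_better"
                             ),
                             tolerance_scores = NULL,
                             effect_scale = 0.4,
                             noise_sd = 0.02,
                             baselines = NULL,
                             seed = 1L) {
  n_varieties <- check_count(n_varieties, "n_varieties", min = 2L)
  check_number(effect_scale, "effect_scale", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  seed <- check_count(seed, "seed")
  if (is.null(tolerance_scores)) {
    tolerance_scores <- seq(1, 0, length.out = n_varieties)
  }
  if (length(tolerance_scores) != n_varieties ||
      !all(is.finite(tolerance_scores))) {
    stop_input("`tolerance_scores` must be %d finite values.", n_varieties)
  }
  if (!all(indicators %in% c("larger_better", "smaller_better")) ||
      is.null(names(indicators))) {
    stop_input("`indicators` must be a named orientation vector.")
  }
  if (is.null(baselines)) {
    baselines <- setNames(
      seq(5, 50, length.out = length(indicators)), names(indicators))
  }
  structure(
    list(n_varieties = n_varieties, indicators = indicators,
         tolerance_scores = tolerance_scores, effect_scale = effect_scale,
         noise_sd = noise_sd, baselines = baselines, seed = seed),
    class = "panel_sim_config"
  )
}

#' Simulate a variety-by-indicator panel with a known tolerance ordering
#'
#' Control values are drawn around per-indicator baselines; the treatment
#' value is the control times `1 - effect_scale * (1 - score)` for
#' larger-is-better indicators (stress depresses growth more in sensitive
#' varieties) and `1 + effect_scale * (1 - score)` for smaller-is-better
#' ones (stress markers rise more), times multiplicative noise. The latent
#' ordering is returned so recovery can be tested.
#'
#' @param cfg A [panel_sim_config()].
#' @return A list: `panel` (long tibble: entity, indicator, arm, value),
#'   `orientation`, `tolerance_scores` (named, descending = more
#'   tolerant first in `true_ranking`), `true_ranking` (variety ids, most
#'   tolerant first).
#' @export
simulate_indicator_panel <- function(cfg) {
  stopifnot(inherits(cfg, "panel_sim_config"))
  varieties <- sprintf("variety_%02d", seq_len(cfg$n_varieties))
  scores <- setNames(cfg$tolerance_scores, varieties)
  ind <- names(cfg$indicators)

  rows <- withr::with_seed(cfg$seed, {
    purrr::map_dfr(seq_along(varieties), function(i) {
      control <- cfg$baselines * exp(rnorm(length(ind), 0, cfg$noise_sd))
      shift <- cfg$effect_scale * (1 - scores[i])
      mult <- ifelse(cfg$indicators == "larger_better", 1 - shift, 1 + shift)
      treatment <- control * mult * exp(rnorm(length(ind), 0, cfg$noise_sd))
      tibble::tibble(
        entity = varieties[i],
        indicator = rep(ind, 2),
        arm = rep(c("control", "treatment"), each = length(ind)),
        value = c(control, treatment)
      )
    })
  })
  list(
    panel = rows,
    orientation = cfg$indicators,
    tolerance_scores = scores,
    true_ranking = varieties[order(-scores, varieties)]
  )
}

#' Configuration for the mortality simulator
#'
#' @param concentrations Stressor concentrations in mM (must include the
#'   positive doses of interest; 0 is allowed and yields no deaths).
#' @param days Observation days (deaths are cumulative within replicate).
#' @param n_plants Cohort size per replicate.
#' @param n_reps Replicates per variety.
#' @param varieties Data frame with columns `variety`, `b` (slope > 0) and
#'   `e` (true LC50 in mM, > 0).
#' @param seed Integer seed.
#' @return A `mortality_sim_config` list.
#' @export
mortality_sim_config <- function(concentrations = c(0, 100, 200, 300),
                                 days = c(5, 10, 15, 20),
                                 n_plants = 50,
                                 n_reps = 3,
                                 varieties = data.frame(
                                   variety = sprintf("variety_%02d", 1:15),
                                   b = rep(6, 15),
                                   e = seq(325, 200, length.out = 15)
                                 ),
                                 seed = 1L) {
  if (any(concentrations < 0)) stop_input("Concentrations must be >= 0.")
  n_plants <- check_count(n_plants, "n_plants", min = 1L)
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  seed <- check_count(seed, "seed")
  if (!all(c("variety", "b", "e") %in% names(varieties)) ||
      any(varieties$b <= 0) || any(varieties$e <= 0) ||
      !all(is.finite(varieties$b)) || !all(is.finite(varieties$e))) {
    stop_input("`varieties` needs finite columns variety, b > 0, e > 0.")
  }
  if (length(days) < 1 || any(days <= 0)) stop_input("`days` must be positive.")
  structure(
    list(concentrations = sort(unique(concentrations)),
         days = sort(unique(days)), n_plants = n_plants, n_reps = n_reps,
         varieties = varieties, seed = seed),
    class = "mortality_sim_config"
  )
}

#' Simulate cumulative mortality counts under a log-logistic dose-response
#'
#' Final-day deaths per replicate are Binomial(n_plants, p(c)) with
#' p(c) = 1/(1 + (e/c)^b) and p(0) = 0, so day-final proportions follow
#' the dose-response exactly. Within a replicate the hazard accumulates
#' linearly over the observation window: each dead plant's death day is
#' uniform over the days, making cumulative deaths non-decreasing in day
#' and reaching the binomial total on the final day.
#'
#' @param cfg A [mortality_sim_config()].
#' @return A tibble: `variety`, `concentration`, `day`, `replicate`,
#'   `dead` (cumulative), `cohort`.
#' @export
simulate_mortality <- function(cfg) {
  stopifnot(inherits(cfg, "mortality_sim_config"))
  grid <- tidyr::expand_grid(
    variety = cfg$varieties$variety,
    concentration = cfg$concentrations,
    replicate = seq_len(cfg$n_reps)
  )
  days <- cfg$days
  out <- purrr::pmap_dfr(grid, function(variety, concentration, replicate) {
    row <- cfg$varieties[cfg$varieties$variety == variety, ]
    p <- if (concentration == 0) 0 else
      1 / (1 + (row$e / concentration)^row$b)
    sub <- derive_seed(
      cfg$seed,
      match(variety, cfg$varieties$variety) * 10000L +
        match(concentration, cfg$concentrations) * 100L + replicate
    )
    withr::with_seed(sub, {
      total <- rbinom(1, cfg$n_plants, p)
      death_day <- if (total > 0) sample(days, total, replace = TRUE) else integer(0)
      tibble::tibble(
        variety = variety,
        concentration = concentration,
        day = days,
        replicate = replicate,
        dead = vapply(days, function(d) sum(death_day <= d), integer(1)),
        cohort = cfg$n_plants
      )
    })
  })
  out
}

#' Configuration for the planted-module expression simulator
#'
#' @param n_modules Number of planted co-expression modules.
#' @param genes_per_module Genes per planted module.
#' @param n_background Background (noise-only) genes.
#' @param n_groups,n_reps Sample design (default 4 groups x 4 replicates
#'   = 16 samples, two varieties x control/stress).
#' @param driver_effect Sd of the latent module driver signal on the log
#'   scale.
#' @param noise_sd Residual gene-level sd on the log scale.
#' @param trait_noise_sd Sd of each trait around its driving eigengene.
#' @param seed Integer seed.
#' @return An `expr_sim_config` list.
#' @export
expr_sim_config <- function(n_modules = 3,
                            genes_per_module = 50,
                            n_background = 100,
                            n_groups = 4,
                            n_reps = 4,
                            driver_effect = 1,
                            noise_sd = 0.3,
                            trait_noise_sd = 0.2,
                            seed = 1L) {
  n_modules <- check_count(n_modules, "n_modules", min = 1L)
  genes_per_module <- check_count(genes_per_module, "genes_per_module", min = 2L)
  n_background <- check_count(n_background, "n_background", min = 0L)
  n_groups <- check_count(n_groups, "n_groups", min = 2L)
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  if (n_groups * n_reps < 4) stop_input("Need at least 4 samples.")
  check_number(driver_effect, "driver_effect", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(trait_noise_sd, "trait_noise_sd", lower = 0)
  seed <- check_count(seed, "seed")
  structure(
    list(n_modules = n_modules, genes_per_module = genes_per_module,
         n_background = n_background, n_groups = n_groups, n_reps = n_reps,
         driver_effect = driver_effect, noise_sd = noise_sd,
         trait_noise_sd = trait_noise_sd, seed = seed),
    class = "expr_sim_config"
  )
}

#' Simulate an FPKM-like expression matrix with planted modules and traits
#'
#' Each planted module m has a latent driver over samples built from a
#' per-group effect plus replicate noise (so drivers track the 4-group
#' design); member genes are `loading * driver + noise` on the log scale,
#' background genes are pure noise. FPKM-like non-negativity comes from
#' exponentiating the log-scale signal around a gene-specific baseline,
#' which preserves (rank and, approximately, Pearson) correlation
#' structure while matching FPKM support. Each physiological trait is its
#' module's driver plus noise, so module eigengenes correlate with traits
#' by construction.
#'
#' @param cfg An [expr_sim_config()].
#' @return A list: `expression` (tibble, gene_id + one column per sample),
#'   `modules` (tibble: gene_id, module — planted labels, background =
#'   "grey"), `traits` (tibble, sample_id + one trait column per module,
#'   cycling through H2O2, MDA, SS, Pro, SOD, POD, CAT, Chl), `groups`
#'   (named character: sample -> group), `drivers` (matrix, samples x
#'   modules).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  n_samples <- cfg$n_groups * cfg$n_reps
  groups <- rep(sprintf("group%d", seq_len(cfg$n_groups)), each = cfg$n_reps)
  samples <- sprintf("%s_rep%d", groups, rep(seq_len(cfg$n_reps), cfg$n_groups))
  trait_pool <- c("H2O2", "MDA", "SS", "Pro", "SOD", "POD", "CAT", "Chl")

  withr::with_seed(cfg$seed, {
    # latent drivers: orthogonal group contrasts + within-group variation,
    # standardized. Orthogonality keeps planted modules distinct; random
    # group effects in a small group space would frequently collide and
    # merge two modules into one.
    n_contrasts <- cfg$n_groups - 1L
    qmat <- qr.Q(qr(cbind(1, matrix(rnorm(cfg$n_groups * n_contrasts),
                                    cfg$n_groups))))[, -1, drop = FALSE]
    drivers <- vapply(seq_len(cfg$n_modules), function(m) {
      g <- if (m <= n_contrasts) {
        qmat[, m] * sqrt(cfg$n_groups)
      } else {
        rnorm(cfg$n_groups, 0, 1)   # beyond the contrast space: unconstrained
      }
      z <- g[match(groups, unique(groups))] + rnorm(n_samples, 0, 0.4)
      (z - mean(z)) / sd(z)
    }, numeric(n_samples))
    colnames(drivers) <- sprintf("module%d", seq_len(cfg$n_modules))
    rownames(drivers) <- samples

    n_genes <- cfg$n_modules * cfg$genes_per_module + cfg$n_background
    gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
    labels <- c(rep(colnames(drivers), each = cfg$genes_per_module),
                rep("grey", cfg$n_background))

    logx <- matrix(0, n_genes, n_samples,
                   dimnames = list(gene_ids, samples))
    for (g in seq_len(n_genes)) {
      base <- runif(1, log(5), log(200))
      if (labels[g] == "grey") {
        sig <- rnorm(n_samples, 0, cfg$driver_effect)
      } else {
        loading <- runif(1, 0.7, 1) * sample(c(-1, 1), 1)
        sig <- loading * cfg$driver_effect * drivers[, labels[g]]
      }
      logx[g, ] <- base + sig + rnorm(n_samples, 0, cfg$noise_sd)
    }

    traits <- vapply(seq_len(cfg$n_modules), function(m) {
      drivers[, m] + rnorm(n_samples, 0, cfg$trait_noise_sd)
    }, numeric(n_samples))
    colnames(traits) <- trait_pool[(seq_len(cfg$n_modules) - 1) %%
                                     length(trait_pool) + 1]
    # de-duplicate trait names if n_modules > pool size
    colnames(traits) <- make.unique(colnames(traits), sep = "_")
    rownames(traits) <- samples

    list(
      expression = id_matrix_to_tibble(exp(logx), "gene_id"),
      modules = tibble::tibble(gene_id = gene_ids, module = labels),
      traits = id_matrix_to_tibble(traits, "sample_id"),
      groups = setNames(groups, samples),
      drivers = drivers
    )
  })
}
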