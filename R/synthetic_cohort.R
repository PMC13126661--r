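#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the structure of the study data the package is
#' designed for: two groups (ALL survivors and healthy controls) of 70
#' subjects each, ages drawn uniformly over 6.2-20.3 years with a 40:30
#' male:female ratio per group, and per-subject 379-region whole-brain
#' weighted connectomes with community structure aligned to the 24-region
#' WM hierarchy.
#'
#' Edge weights are gamma distributed (right-skewed, like streamline
#' weights). Edges inside a module — a coarse WM region, the six-node
#' subcortical system, or one of the background modules tiling the non-WM
#' nodes — are always present and carry a `within_module_boost` mean-weight
#' multiplier (anatomically adjacent parcels are essentially always
#' connected by tractography); cross-module edges are present with
#' probability `density`. Edges between subcortical and cortical nodes are
#' attenuated by `subcortical_crosstalk`, concentrating subcortical
#' connectivity inside the striato-thalamic system.
#'
#' Group effects are multiplicative on the ALL group's mean weights:
#' `effect_subcortical_seg` scales edges among the six subcortical nodes
#' (raising their local segregation: clustering up, participation down),
#' and `effect_cortical_int` scales the cross-module edges of the
#' designated cortical hub groups (DLPC and PMC; raising their
#' integration). Both default to 1 (no group difference).
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param seed Integer base seed; per-subject streams are derived from it so
#'   enlarging the cohort does not perturb earlier subjects.
#' @param base_weight_shape,base_weight_scale Gamma shape and scale of
#'   background edge weights (defaults give mean 1, coefficient of
#'   variation 0.5).
#' @param within_module_boost Mean-weight multiplier for within-module edges
#'   (>= 1).
#' @param density Fraction of cross-module node pairs carrying an edge, in
#'   (0, 1]; within-module edges are always present.
#' @param subcortical_crosstalk Mean-weight attenuation factor for
#'   subcortical-to-cortical edges, in (0, 1].
#' @param effect_subcortical_seg,effect_cortical_int Multiplicative ALL-group
#'   effects (> 0).
#' @param age_range Length-2 numeric, years.
#' @param sex_ratio Length-2 integer, males:females per `n_per_group`
#'   (scaled to the group size).
#' @param unit_volumes If TRUE all region volumes are 1 (normalization-free
#'   tests); otherwise volumes are log-normal around plausible parcel sizes.
#' @return A list of class `wm_sim_config`.
#' @export
sim_config <- function(n_per_group = 70L, seed = 1L,
                       base_weight_shape = 4, base_weight_scale = 0.25,
                       within_module_boost = 3, density = 0.2,
                       subcortical_crosstalk = 0.2,
                       effect_subcortical_seg = 1, effect_cortical_int = 1,
                       age_range = c(6.2, 20.3), sex_ratio = c(40L, 30L),
                       unit_volumes = FALSE) {
  cfg <- list(n_per_group = as.integer(n_per_group), seed = as.integer(seed),
              base_weight_shape = base_weight_shape,
              base_weight_scale = base_weight_scale,
              within_module_boost = within_module_boost, density = density,
              subcortical_crosstalk = subcortical_crosstalk,
              effect_subcortical_seg = effect_subcortical_seg,
              effect_cortical_int = effect_cortical_int,
              age_range = age_range, sex_ratio = sex_ratio,
              unit_volumes = isTRUE(unit_volumes))
  if (cfg$n_per_group < 2L) rlang::abort("n_per_group must be >= 2")
  if (cfg$density <= 0 || cfg$density > 1) rlang::abort("density must be in (0, 1]")
  if (cfg$subcortical_crosstalk <= 0 || cfg$subcortical_crosstalk > 1) {
    rlang::abort("subcortical_crosstalk must be in (0, 1]")
  }
  mult <- c(cfg$within_module_boost, cfg$effect_subcortical_seg,
            cfg$effect_cortical_int, cfg$base_weight_shape, cfg$base_weight_scale)
  if (any(mult <= 0)) rlang::abort("weights, boosts and effects must be > 0")
  if (cfg$within_module_boost < 1) rlang::abort("within_module_boost must be >= 1")
  class(cfg) <- "wm_sim_config"
  cfg
}

#' Generate a synthetic cohort of whole-brain connectomes
#'
#' Draws `2 * n_per_group` subjects (groups `ALL` and `HC`) with covariates,
#' a shared region-volume table, and one 379-region whole-brain weighted
#' connectome per subject (see [sim_config()] for the generative model).
#' Fully reproducible from the config seed; subject `k`'s matrix has its own
#' derived random stream.
#'
#' @param config A [sim_config()].
#' @param hierarchy A [wm_hierarchy()]; whole-brain indices are attached
#'   from the packaged default lookup if absent.
#' @return A list with elements `connectomes` (list of `connectome`s),
#'   `covariates` (tibble) and `volumes` (tibble).
#' @export
generate_cohort <- function(config = sim_config(), hierarchy = wm_hierarchy()) {
  stopifnot(inherits(config, "wm_sim_config"))
  if (anyNA(hierarchy$wholebrain_index)) {
    hierarchy <- attach_wholebrain_indices(hierarchy)
  }
  n <- config$n_per_group
  n_total <- 2L * n

  covariates <- withr::with_seed(config$seed, {
    n_m <- round(n * config$sex_ratio[1] / sum(config$sex_ratio))
    sexes <- c(rep("M", n_m), rep("F", n - n_m))
    tibble::tibble(
      subject_id = sprintf("sub%03d", seq_len(n_total)),
      group = rep(c("ALL", "HC"), each = n),
      age = stats::runif(n_total, config$age_range[1], config$age_range[2]),
      sex = rep(sexes, 2L))
  })

  volumes <- withr::with_seed(config$seed + 1L, {
    v <- if (config$unit_volumes) rep(1, 379) else
      stats::rlnorm(379, meanlog = log(3000), sdlog = 0.5)
    tibble::tibble(wholebrain_index = 0:378, volume = v)
  })

  st <- cohort_edge_structure(config, hierarchy)
  connectomes <- purrr::map(seq_len(n_total), function(k) {
    m <- if (covariates$group[k] == "ALL") st$mean_all else st$mean_hc
    seed_k <- (config$seed + 7919L * k) %% 2147483647L
    w <- withr::with_seed(seed_k, {
      present <- stats::rbinom(length(st$p_edge), 1L, st$p_edge)
      present * stats::rgamma(length(st$p_edge),
                              shape = config$base_weight_shape,
                              scale = config$base_weight_scale * m)
    })
    M <- matrix(0, 379, 379)
    M[st$ut_idx] <- w
    M <- M + t(M)
    connectome(M, scale = "wholebrain379",
               subject_id = covariates$subject_id[k])
  })

  list(connectomes = connectomes, covariates = covariates, volumes = volumes)
}

# Per-pair edge probabilities and mean-weight multipliers for HC and ALL
# subjects, on the upper triangle of the 379 x 379 matrix. Modules: the 24
# WM coarse regions (with the six subcortical nodes merged into one
# striato-thalamic system block) plus background modules of 16 nodes tiling
# the non-WM regions.
cohort_edge_structure <- function(config, hierarchy) {
  module <- integer(379)
  wb <- hierarchy$wholebrain_index + 1L
  module[wb] <- hierarchy$coarse_index
  is_sub <- logical(379)
  is_sub[wb[hierarchy$kind == "subcortical"]] <- TRUE
  module[is_sub] <- 100L
  rest <- setdiff(seq_len(379L), wb)
  module[rest] <- 200L + (seq_along(rest) - 1L) %/% 16L

  hub_nodes <- wb[hierarchy$group %in% c("DLPC", "PMC")]

  ut_idx <- which(upper.tri(matrix(0, 379, 379)))
  row_i <- ((ut_idx - 1L) %% 379L) + 1L
  col_j <- ((ut_idx - 1L) %/% 379L) + 1L

  same_module <- module[row_i] == module[col_j]
  sub_pair <- is_sub[row_i] & is_sub[col_j]
  sub_cross <- xor(is_sub[row_i], is_sub[col_j])

  p_edge <- ifelse(same_module, 1, config$density)
  mean_hc <- ifelse(same_module, config$within_module_boost, 1) *
    ifelse(sub_cross, config$subcortical_crosstalk, 1)

  mean_all <- mean_hc
  mean_all[sub_pair] <- mean_all[sub_pair] * config$effect_subcortical_seg
  hub_cross <- !same_module & !sub_pair &
    ((row_i %in% hub_nodes) | (col_j %in% hub_nodes))
  mean_all[hub_cross] <- mean_all[hub_cross] * config$effect_cortical_int

  list(p_edge = p_edge, mean_hc = mean_hc, mean_all = mean_all,
       ut_idx = ut_idx)
}

#' End-to-end parameter-recovery benchmark
#'
#' Runs the full pipeline (generate cohort, build multiscale connectomes,
#' compute metrics at both scales, nodewise group statistics, cross-scale
#' classification) over `n_replicates` independently seeded cohorts, and
#' summarises per region x metric how often an FDR-significant group effect
#' was detected, in which direction, and which cross-scale scenario it was
#' assigned.
#'
#' @param config A [sim_config()] (its `seed` is combined with the
#'   replicate index).
#' @param n_replicates Number of independent cohorts.
#' @param seed Integer seed offsetting the replicate streams.
#' @param hierarchy A [wm_hierarchy()].
#' @return A list with `per_replicate` (tibble: replicate x region x metric
#'   detection records at the coarse scale, plus scenario) and `summary`
#'   (tibble: detection frequency and direction split per region x metric).
#' @export
recovery_benchmark <- function(config = sim_config(), n_replicates = 20L,
                               seed = 1L, hierarchy = wm_hierarchy()) {
  if (anyNA(hierarchy$wholebrain_index)) {
    hierarchy <- attach_wholebrain_indices(hierarchy)
  }
  per_rep <- purrr::map(seq_len(n_replicates), function(r) {
    cfg <- config
    cfg$seed <- (seed + 104729L * r) %% 2147483647L
    res <- run_cohort_analysis(cfg, hierarchy)
    res$report |>
      dplyr::transmute(replicate = r, .data$coarse_region, .data$metric,
                       detected = .data$coarse_significant,
                       direction = .data$coarse_direction,
                       .data$scenario)
  }) |> dplyr::bind_rows()

  summary <- per_rep |>
    dplyr::group_by(.data$coarse_region, .data$metric) |>
    dplyr::summarise(
      detection_rate = mean(.data$detected),
      rate_up = mean(.data$detected & .data$direction == "ALL>HC", na.rm = TRUE),
      rate_down = mean(.data$detected & .data$direction == "ALL<HC", na.rm = TRUE),
      consistent_rate = mean(.data$scenario == "consistent"),
      .groups = "drop")
  list(per_replicate = per_rep, summary = summary)
}

# one full pipeline pass on one simulated cohort; shared by
# recovery_benchmark() and the tests
run_cohort_analysis <- function(config, hierarchy, alpha = 0.05) {
  cohort <- generate_cohort(config, hierarchy)
  ms <- purrr::map(cohort$connectomes, build_multiscale,
                   volumes = cohort$volumes, hierarchy = hierarchy)
  fine_mets <- compute_metrics(purrr::map(ms, "fine"), hierarchy, "fine76")
  coarse_mets <- compute_metrics(purrr::map(ms, "coarse"), hierarchy, "coarse24")
  fine_res <- run_group_analysis(fine_mets, cohort$covariates, alpha = alpha)
  coarse_res <- run_group_analysis(coarse_mets, cohort$covariates, alpha = alpha)
  report <- classify_crossscale(fine_res, coarse_res, hierarchy)
  list(cohort = cohort, fine_metrics = fine_mets, coarse_metrics = coarse_mets,
       fine_results = fine_res, coarse_results = coarse_res, report = report)
}
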