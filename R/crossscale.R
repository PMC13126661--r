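#' Classify cross-scale effect scenarios
#'
#' Compares FDR-significant nodewise group effects between the fine 76-node
#' and coarse 24-region scales and assigns each region x metric cell to one
#' of five scenarios:
#'
#' * `consistent`: the coarse region is significant and at least one of its
#'   fine nodes is significant in the same direction, none in the opposite
#'   direction — the effect survives aggregation unchanged.
#' * `fine_only`: the coarse region is not significant but one or more fine
#'   nodes are, all in one direction — a focal, subregional effect diluted
#'   by aggregation.
#' * `convergent`: the coarse region is significant while its fine nodes are
#'   mixed in direction (or none reaches significance individually) —
#'   sub-threshold or heterogeneous fine shifts summing to a regional
#'   change.
#' * `cancelling`: the coarse region is not significant but fine nodes are
#'   significant in both directions — opposing fine shifts neutralising
#'   each other.
#' * `null`: no significant call at either scale.
#'
#' By default the two hemispheres of a region are pooled (12 region labels);
#' with `by_hemisphere = TRUE` the 24 coarse regions are classified
#' separately. When hemispheres are pooled, the coarse call for a region is
#' significant if either hemisphere's coarse node is, and its direction is
#' the sign of the summed significant coarse effects.
#'
#' @param fine_results `wm_node_results` at scale `fine76`.
#' @param coarse_results `wm_node_results` at scale `coarse24`.
#' @param hierarchy A [wm_hierarchy()].
#' @param by_hemisphere Keep left/right coarse regions separate?
#' @return A tibble of class `wm_crossscale` with columns `coarse_region`,
#'   `metric`, `coarse_direction` (NA when the coarse call is not
#'   significant), `coarse_significant`, `fine_up_count`, `fine_down_count`,
#'   `fine_null_count` and `scenario`.
#' @export
classify_crossscale <- function(fine_results, coarse_results, hierarchy,
                                by_hemisphere = FALSE) {
  stopifnot(inherits(hierarchy, "wm_hierarchy"))
  fine_lab <- node_labels(hierarchy, "fine76")
  coarse_lab <- node_labels(hierarchy, "coarse24")
  metrics <- sort(unique(fine_results$metric))
  if (!setequal(unique(fine_results$node), fine_lab)) {
    rlang::abort("fine results do not cover the hierarchy's fine nodes")
  }
  if (!setequal(unique(coarse_results$node), coarse_lab)) {
    rlang::abort("coarse results do not cover the hierarchy's coarse regions")
  }

  region_of_fine <- if (by_hemisphere) {
    stats::setNames(hierarchy$coarse_label, fine_lab)
  } else {
    stats::setNames(hierarchy$group, fine_lab)
  }
  region_of_coarse <- if (by_hemisphere) {
    stats::setNames(coarse_lab, coarse_lab)
  } else {
    stats::setNames(sub("_(L|R)$", "", coarse_lab), coarse_lab)
  }
  regions <- unique(unname(region_of_coarse))

  rows <- purrr::map(metrics, function(m) {
    fr <- fine_results[fine_results$metric == m, ]
    cr <- coarse_results[coarse_results$metric == m, ]
    purrr::map(regions, function(rg) {
      fn <- fr[region_of_fine[fr$node] == rg, ]
      cn <- cr[region_of_coarse[cr$node] == rg, ]
      up <- sum(fn$significant & fn$direction == "ALL>HC")
      down <- sum(fn$significant & fn$direction == "ALL<HC")
      nl <- nrow(fn) - up - down
      c_sig <- any(cn$significant)
      c_dir <- NA_character_
      if (c_sig) {
        net <- sum(cn$beta_group[cn$significant])
        c_dir <- if (net >= 0) "ALL>HC" else "ALL<HC"
      }
      tibble::tibble(
        coarse_region = rg, metric = m,
        coarse_direction = c_dir, coarse_significant = c_sig,
        fine_up_count = up, fine_down_count = down, fine_null_count = nl,
        scenario = classify_cell(c_sig, c_dir, up, down))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  class(rows) <- c("wm_crossscale", class(rows))
  rows
}

# the scenario rules as one pure function so alternative taxonomies are a
# drop-in replacement
classify_cell <- function(coarse_sig, coarse_dir, up, down) {
  same <- if (isTRUE(coarse_dir == "ALL>HC")) up else down
  opp <- if (isTRUE(coarse_dir == "ALL>HC")) down else up
  if (coarse_sig) {
    if (same >= 1 && opp == 0) return("consistent")
    return("convergent")
  }
  if (up >= 1 && down >= 1) return("cancelling")
  if (up + down >= 1) return("fine_only")
  "null"
}

#' Summary grid of cross-scale group differences
#'
#' Collapses a cross-scale report into a machine-readable grid, one row per
#' region x metric x scale, with a three-valued call: `increase`,
#' `decrease`, or `none` (covering both heterogeneous and null cells),
#' mirroring the red/blue/grey summary-matrix presentation of multiscale
#' group-difference analyses.
#'
#' @param report A `wm_crossscale` tibble from [classify_crossscale()].
#' @return A tibble with columns `coarse_region`, `metric`, `scale`
#'   (`fine76`/`coarse24`) and `call`.
#' @export
render_summary <- function(report) {
  stopifnot(inherits(report, "wm_crossscale"))
  fine_call <- function(up, down) {
    dplyr::case_when(up > 0 & down == 0 ~ "increase",
                     down > 0 & up == 0 ~ "decrease",
                     .default = "none")
  }
  coarse_call <- function(sig, dir) {
    dplyr::case_when(sig & dir == "ALL>HC" ~ "increase",
                     sig & dir == "ALL<HC" ~ "decrease",
                     .default = "none")
  }
  dplyr::bind_rows(
    report |>
      dplyr::transmute(.data$coarse_region, .data$metric, scale = "fine76",
                       call = fine_call(.data$fine_up_count, .data$fine_down_count)),
    report |>
      dplyr::transmute(.data$coarse_region, .data$metric, scale = "coarse24",
                       call = coarse_call(.data$coarse_significant,
                                          .data$coarse_direction)))
}

#' @export
glance.wm_crossscale <- function(x, ...) {
  counts <- table(factor(x$scenario, levels = c("consistent", "fine_only",
                                                "convergent", "cancelling",
                                                "null")))
  tibble::as_tibble(as.list(counts)) |>
    dplyr::mutate(n_cells = nrow(x), .before = 1)
}

#' Plot a cross-scale summary grid
#'
#' Region x metric tile grid per scale: blue for increased values in the
#' ALL group, red for decreased, grey for heterogeneous or null cells.
#'
#' @param object A `wm_crossscale` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wm_crossscale <- function(object, ...) {
  grid <- render_summary(object)
  grid$scale <- factor(grid$scale, levels = c("fine76", "coarse24"))
  grid$coarse_region <- factor(grid$coarse_region,
                               levels = rev(unique(object$coarse_region)))
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$metric, y = .data$coarse_region,
                                     fill = .data$call)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.4) +
    ggplot2::facet_wrap(~scale) +
    ggplot2::scale_fill_manual(values = c(increase = "#2166ac",
                                          decrease = "#b2182b",
                                          none = "grey80")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "ALL vs HC") +
    ggplot2::theme_minimal()
}
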