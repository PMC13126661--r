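#' Covariate-adjusted group comparison for one node's metric
#'
#' Fits the ordinary-least-squares model
#' `y ~ group + age + sex` with the group indicator coded `HC = 0`,
#' `ALL = 1` (so a positive group effect means ALL > HC), and tests the
#' group coefficient with heteroskedasticity-consistent robust standard
#' errors (HC3 by default) against a t reference distribution with
#' `n - 4` degrees of freedom.
#'
#' @param y Numeric vector of metric values, one per subject, aligned with
#'   `covariates` rows.
#' @param covariates A covariate tibble (see [read_covariates()]).
#' @param robust Sandwich estimator flavour: `"HC3"` (default), `"HC1"` or
#'   `"HC0"`.
#' @return A one-row tibble with `beta_group`, `robust_se`, `t_stat`,
#'   `p_raw` and `degenerate` (TRUE when `y` is constant, in which case
#'   `p_raw = 1` by convention).
#' @export
fit_node_model <- function(y, covariates, robust = c("HC3", "HC1", "HC0")) {
  robust <- match.arg(robust)
  covariates <- validate_covariates(covariates)
  n <- length(y)
  if (n != nrow(covariates)) rlang::abort("y and covariates disagree in length")
  if (anyNA(y) || any(!is.finite(y))) rlang::abort("y must be finite")
  counts <- table(factor(covariates$group, levels = c("ALL", "HC")))
  if (any(counts < 10)) {
    rlang::abort("need at least 10 subjects per group")
  }
  if (stats::sd(y) == 0) {
    return(tibble::tibble(beta_group = 0, robust_se = NA_real_,
                          t_stat = NA_real_, p_raw = 1, degenerate = TRUE))
  }
  dat <- data.frame(
    y = y,
    group = as.integer(covariates$group == "ALL"),
    age = covariates$age,
    sex = as.integer(covariates$sex == "M"))
  fit <- stats::lm(y ~ group + age + sex, data = dat)
  if (fit$rank < 4L) rlang::abort("design matrix is rank deficient")
  vc <- sandwich::vcovHC(fit, type = robust)
  beta <- stats::coef(fit)[["group"]]
  se <- sqrt(vc["group", "group"])
  t_stat <- beta / se
  p <- 2 * stats::pt(-abs(t_stat), df = n - 4L)
  tibble::tibble(beta_group = beta, robust_se = se, t_stat = t_stat,
                 p_raw = p, degenerate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1. The adjustment
#' family is the set of values passed in; [run_group_analysis()] applies it
#' within each (metric, scale) stratum.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of adjusted p-values of the same length.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Nodewise group analysis of a metric table
#'
#' For every node x metric in a [compute_metrics()] table, fits the
#' covariate-adjusted group model ([fit_node_model()]) and applies
#' Benjamini-Hochberg FDR correction across nodes, by default within each
#' (metric, scale) family.
#'
#' @param metrics A long metric tibble from [compute_metrics()].
#' @param covariates Covariate tibble covering exactly the subjects present
#'   in `metrics`.
#' @param robust Sandwich estimator flavour (see [fit_node_model()]).
#' @param family `"per-metric-scale"` (default): FDR within each metric;
#'   `"pooled"`: one family across all node x metric tests of the table.
#' @param alpha FDR significance threshold.
#' @return A tibble of class `wm_node_results` with columns `scale`, `node`,
#'   `metric`, `beta_group`, `robust_se`, `t_stat`, `p_raw`, `p_fdr`,
#'   `direction` (`"ALL>HC"`/`"ALL<HC"`) and `significant`.
#' @export
run_group_analysis <- function(metrics, covariates,
                               robust = c("HC3", "HC1", "HC0"),
                               family = c("per-metric-scale", "pooled"),
                               alpha = 0.05) {
  robust <- match.arg(robust)
  family <- match.arg(family)
  covariates <- validate_covariates(covariates)
  scale <- attr(metrics, "scale")
  if (is.null(scale)) scale <- NA_character_
  subj <- unique(metrics$subject_id)
  if (!setequal(subj, covariates$subject_id)) {
    rlang::abort("subjects in metrics and covariates disagree")
  }
  covariates <- covariates[match(subj, covariates$subject_id), ]

  node_order <- unique(metrics$node)
  fits <- metrics |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$metric, .data$node) |>
    dplyr::group_modify(function(d, key) {
      y <- d$value[match(subj, d$subject_id)]
      keep <- !is.na(y)
      fit_node_model(y[keep], covariates[keep, , drop = FALSE], robust = robust)
    }) |>
    dplyr::ungroup()

  fits$scale <- scale
  if (family == "per-metric-scale") {
    fits <- fits |>
      dplyr::group_by(.data$metric) |>
      dplyr::mutate(p_fdr = bh_fdr(.data$p_raw)) |>
      dplyr::ungroup()
  } else {
    fits$p_fdr <- bh_fdr(fits$p_raw)
  }
  fits <- fits |>
    dplyr::mutate(
      direction = ifelse(.data$beta_group >= 0, "ALL>HC", "ALL<HC"),
      significant = !.data$degenerate & .data$p_fdr < alpha) |>
    dplyr::arrange(match(.data$metric, c("CC", "EC", "LA", "PC")),
                   match(.data$node, node_order)) |>
    dplyr::select("scale", "node", "metric", "beta_group", "robust_se",
                  "t_stat", "p_raw", "p_fdr", "direction", "significant")
  attr(fits, "alpha") <- alpha
  class(fits) <- c("wm_node_results", class(fits))
  fits
}

#' @export
tidy.wm_node_results <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "wm_node_results")
  out
}

#' @export
glance.wm_node_results <- function(x, ...) {
  tibble::tibble(
    scale = x$scale[1],
    n_tests = nrow(x),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha") %||% 0.05,
    min_p_fdr = min(x$p_fdr))
}

#' Frequency-match controls to cases on age and sex
#'
#' Greedy group-level frequency matching: within each sex, every case is
#' matched to the still-unused pool member of the same sex whose age lies
#' within `age_tol` years (nearest age first). If the pool cannot supply a
#' control for every case, the selection is trimmed (dropping the
#' worst-fitting matches) to the largest size that preserves the cases'
#' exact sex ratio. Ties are broken deterministically by a seeded shuffle of
#' the pool order.
#'
#' @param cases Covariate tibble of cases.
#' @param pool Covariate tibble of candidate controls.
#' @param age_tol Age tolerance in years (default 1).
#' @param seed Integer seed for tie-breaking.
#' @return Tibble of selected pool rows (possibly empty), with a
#'   `matched_case` column naming the case each control was matched to.
#' @export
frequency_match <- function(cases, pool, age_tol = 1, seed = 1L) {
  cases <- validate_covariates(cases)
  pool <- validate_covariates(pool)
  if (nrow(pool) == 0) rlang::abort("control pool is empty")

  sel <- list()
  for (sx in unique(cases$sex)) {
    cs <- cases[cases$sex == sx, ]
    pl <- pool[pool$sex == sx, ]
    if (nrow(pl) == 0) next
    ord <- withr::with_seed(seed, sample.int(nrow(pl)))
    pl <- pl[ord, ]
    used <- rep(FALSE, nrow(pl))
    # hardest-to-match cases first: fewest in-tolerance candidates
    n_cand <- vapply(cs$age, function(a) sum(abs(pl$age - a) <= age_tol), integer(1))
    for (ci in order(n_cand, cs$age)) {
      d <- abs(pl$age - cs$age[ci])
      ok <- which(!used & d <= age_tol)
      if (length(ok) == 0) next
      pick <- ok[which.min(d[ok])]
      used[pick] <- TRUE
      row <- pl[pick, ]
      row$matched_case <- cs$subject_id[ci]
      row$age_gap <- d[pick]
      sel[[length(sel) + 1L]] <- row
    }
  }
  sel <- dplyr::bind_rows(sel)
  if (nrow(sel) == 0) {
    return(tibble::tibble(subject_id = character(0), group = character(0),
                          age = numeric(0), sex = character(0),
                          matched_case = character(0)))
  }
  # trim to the largest size preserving the cases' exact sex ratio
  case_counts <- table(factor(cases$sex, levels = c("M", "F")))
  g <- Reduce(gcd2, case_counts[case_counts > 0])
  unit <- case_counts / g
  got <- table(factor(sel$sex, levels = c("M", "F")))
  t_max <- min(ifelse(unit > 0, floor(got / pmax(unit, 1)), Inf)[unit > 0])
  keep_n <- unit * t_max
  sel <- sel |>
    dplyr::group_by(.data$sex) |>
    dplyr::arrange(.data$age_gap, .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() <= keep_n[as.character(dplyr::first(.data$sex))]) |>
    dplyr::ungroup() |>
    dplyr::select(-"age_gap")
  sel
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

`%||%` <- function(x, y) if (is.null(x)) y else x
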