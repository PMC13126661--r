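#' Weighted clustering coefficient (Onnela form)
#'
#' Nodal segregation measure: the geometric-mean intensity of the triangles
#' around each node, relative to the number of possible neighbour pairs.
#' With weights rescaled by the matrix maximum, `what = w / max(W)`,
#'
#'   CC_i = (2 / (k_i (k_i - 1))) * sum_{j<h} (what_ij what_ih what_jh)^(1/3)
#'
#' where `k_i` is the binary degree. Nodes with fewer than two neighbours
#' get CC 0. Values lie in `[0, 1]` and are invariant to a global rescaling
#' of the weights.
#'
#' @param W Square symmetric nonnegative zero-diagonal numeric matrix
#'   (a `connectome` works as-is).
#' @return Named numeric vector of nodal clustering coefficients.
#' @export
clustering_coefficient <- function(W) {
  W <- as_weight_matrix(W)
  mx <- max(W)
  if (mx == 0) {
    rlang::warn("all-zero matrix: clustering coefficient is 0 everywhere")
    return(stats::setNames(numeric(nrow(W)), rownames(W)))
  }
  Wh <- (W / mx)^(1 / 3)
  k <- rowSums(W > 0)
  # diag(Wh^3) counts each (ordered) triangle pair, i.e. 2 * sum_{j<h}
  tri <- diag(Wh %*% Wh %*% Wh)
  denom <- k * (k - 1)
  cc <- ifelse(denom > 0, tri / denom, 0)
  stats::setNames(cc, rownames(W))
}

#' Weighted eigenvector centrality
#'
#' Nodal influence measure: the entry of the dominant (Perron) eigenvector
#' of the weight matrix, computed by power iteration (relative tolerance
#' `tol`, at most `max_iter` iterations), with nonnegative entries and unit
#' L2 norm. The iteration runs on the diagonally shifted matrix `W + cI`
#' (small positive `c`), which leaves the eigenvectors unchanged but breaks
#' the eigenvalue tie of bipartite graphs that would otherwise make plain
#' power iteration oscillate. If the graph is disconnected the centrality
#' is still computed on the full matrix, with a warning naming the
#' components.
#'
#' @param W Square symmetric nonnegative zero-diagonal numeric matrix.
#' @param tol Relative convergence tolerance of the power iteration.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return Named numeric vector with unit L2 norm.
#' @export
eigenvector_centrality <- function(W, tol = 1e-10, max_iter = 10000L) {
  W <- as_weight_matrix(W)
  n <- nrow(W)
  if (max(W) == 0) rlang::abort("all-zero matrix: eigenvector centrality undefined")
  comp <- graph_components(W)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    rlang::warn(sprintf(
      "graph is disconnected (%d components of sizes %s); centrality computed on the full matrix",
      max(comp), paste(sizes, collapse = ", ")))
  }
  # shift c: any c > 0 makes the Perron eigenvalue strictly dominant
  shift <- 0.05 * max(rowSums(W))
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(max_iter)) {
    v_new <- W %*% v + shift * v
    nrm <- sqrt(sum(v_new^2))
    if (nrm == 0) rlang::abort("power iteration collapsed to zero vector")
    v_new <- as.vector(v_new) / nrm
    if (max(abs(v_new - v)) <= tol * max(abs(v_new))) {
      v <- v_new
      return(stats::setNames(pmax(v, 0), rownames(W)))
    }
    v <- v_new
  }
  rlang::abort(sprintf("eigenvector centrality did not converge in %d iterations", max_iter))
}

#' Local assortativity of strength (edge decomposition)
#'
#' Decomposes the global weighted strength-assortativity coefficient `r`
#' into nodal contributions. Over ordered node pairs `(i, j)` with
#' `w_ij > 0`, with nodal strengths `s`, total stub weight `S = sum w_ij`,
#' stub-weighted mean `mu = sum w_ij s_j / S` and variance
#' `sigma2 = sum w_ij (s_j - mu)^2 / S`:
#'
#'   LA_i = sum_j w_ij (s_i - mu)(s_j - mu) / (sigma2 * S)
#'
#' so that `sum_i LA_i = r`, the weighted Pearson correlation of endpoint
#' strengths over edge stubs. Positive LA marks nodes that preferentially
#' attach to partners of similar strength. Undefined (an error) when all
#' strengths are equal.
#'
#' @param W Square symmetric nonnegative zero-diagonal numeric matrix.
#' @return Named numeric vector of nodal assortativity contributions.
#' @export
local_assortativity <- function(W) {
  W <- as_weight_matrix(W)
  s <- rowSums(W)
  S <- sum(W)
  if (S == 0) rlang::abort("all-zero matrix: local assortativity undefined")
  # stub-weighted moments of endpoint strength; by symmetry the "source"
  # and "target" marginals coincide
  mu <- sum(W %*% s) / S
  sigma2 <- sum(sweep(W, 2, (s - mu)^2, `*`)) / S
  if (sigma2 <= .Machine$double.eps * mu^2) {
    rlang::abort("degenerate strengths: all nodal strengths equal, local assortativity undefined")
  }
  la <- (s - mu) * as.vector(W %*% (s - mu)) / (sigma2 * S)
  stats::setNames(la, rownames(W))
}

#' Participation coefficient
#'
#' Integration measure: how evenly a node's connection strength is spread
#' over network modules. With `s_i(m)` the strength of node `i` into module
#' `m` and `s_i` its total strength,
#'
#'   PC_i = 1 - sum_m (s_i(m) / s_i)^2
#'
#' PC is 0 for a node whose weight stays inside one module (and, by
#' convention, for an isolated node) and approaches `1 - 1/M` for weight
#' split equally over `M` modules.
#'
#' @param W Square symmetric nonnegative zero-diagonal numeric matrix.
#' @param partition Integer (or factor) module assignment covering every
#'   node, e.g. from [coarse_partition()].
#' @return Named numeric vector of participation coefficients.
#' @export
participation_coefficient <- function(W, partition) {
  W <- as_weight_matrix(W)
  n <- nrow(W)
  partition <- as.integer(as.factor(partition))
  if (length(partition) != n || anyNA(partition)) {
    rlang::abort("partition must assign a module to every node")
  }
  k <- max(partition)
  M <- matrix(0, n, k)
  M[cbind(seq_len(n), partition)] <- 1
  sm <- W %*% M            # strength of each node into each module
  s <- rowSums(W)
  frac <- sm / ifelse(s > 0, s, 1)
  pc <- ifelse(s > 0, 1 - rowSums(frac^2), 0)
  stats::setNames(pc, rownames(W))
}

#' Compute all four nodal metrics for a cohort of connectomes
#'
#' Runs clustering coefficient (CC), eigenvector centrality (EC), local
#' assortativity (LA) and participation coefficient (PC) per subject on
#' connectomes of one scale and returns a long tibble. The PC module
#' partition defaults to the 24 anatomical regions at the fine scale and
#' the 4 bilateral systems at the coarse scale.
#'
#' Subjects whose strengths are degenerate (LA undefined) get `NA` for LA
#' and are reported in the `degenerate` attribute.
#'
#' @param connectomes List of `connectome` objects, all at `scale`.
#' @param hierarchy A [wm_hierarchy()].
#' @param scale `"fine76"` or `"coarse24"`.
#' @param partition Optional explicit PC partition (integer vector over the
#'   nodes of `scale`); overrides the default.
#' @return A tibble with columns `subject_id`, `node`, `metric`
#'   (`CC`/`EC`/`LA`/`PC`) and `value`, carrying `scale` as an attribute.
#' @export
compute_metrics <- function(connectomes, hierarchy,
                            scale = c("fine76", "coarse24"),
                            partition = NULL) {
  scale <- match.arg(scale)
  stopifnot(inherits(hierarchy, "wm_hierarchy"))
  bad <- vapply(connectomes, function(x) conn_scale(x) != scale, logical(1))
  if (any(bad)) {
    rlang::abort(sprintf("%d connectome(s) are not at scale %s", sum(bad), scale))
  }
  if (is.null(partition)) {
    partition <- default_pc_partition(hierarchy, scale)
  }
  degenerate <- character(0)
  rows <- purrr::map(connectomes, function(x) {
    sid <- conn_subject(x)
    cc <- clustering_coefficient(x)
    ec <- eigenvector_centrality(x)
    la <- tryCatch(local_assortativity(x), error = function(e) {
      degenerate <<- c(degenerate, sid)
      stats::setNames(rep(NA_real_, nrow(x)), rownames(x))
    })
    pc <- participation_coefficient(x, partition)
    tibble::tibble(
      subject_id = sid,
      node = rep(conn_labels(x), 4L),
      metric = rep(c("CC", "EC", "LA", "PC"), each = nrow(x)),
      value = c(cc, ec, la, pc))
  })
  out <- dplyr::bind_rows(rows)
  if (length(degenerate) > 0) {
    rlang::warn(paste0("LA undefined (degenerate strengths) for subject(s): ",
                       paste(degenerate, collapse = ", ")))
  }
  attr(out, "scale") <- scale
  attr(out, "degenerate") <- degenerate
  out
}

# default participation-coefficient module partition per scale:
# anatomical 24 regions over the fine nodes; 4 bilateral systems over the
# 24 coarse regions
default_pc_partition <- function(hierarchy, scale) {
  if (scale == "fine76") {
    coarse_partition(hierarchy, "groups24")
  } else {
    fine_sys <- coarse_partition(hierarchy, "systems")
    sys <- fine_sys[match(unique(hierarchy$coarse_index), hierarchy$coarse_index)]
    stats::setNames(as.integer(sys), node_labels(hierarchy, "coarse24"))
  }
}

as_weight_matrix <- function(W) {
  if (inherits(W, "connectome")) {
    m <- unclass(W)
    attr(m, "labels") <- NULL
    attr(m, "scale") <- NULL
    attr(m, "subject_id") <- NULL
    attr(m, "within_mass") <- NULL
    return(m)
  }
  if (!is.matrix(W) || !is.numeric(W)) rlang::abort("W must be a numeric matrix")
  if (nrow(W) != ncol(W)) rlang::abort("W must be square")
  if (any(W < 0)) rlang::abort("W must be nonnegative")
  if (max(abs(W - t(W))) > 1e-8 * max(abs(W), 1e-300)) {
    rlang::abort("W must be symmetric")
  }
  if (any(diag(W) != 0)) rlang::abort("W must have zero diagonal")
  W
}

# connected components via breadth-first search on the binarized graph
graph_components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
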