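#' Normalize edge weights by region volume
#'
#' Corrects the streamline-weight bias towards large regions by scaling each
#' edge by the inverse of the volumes of its endpoints:
#' `w'_ij = w_ij * 2 / (v_i + v_j)` (default, symmetric, identity when all
#' volumes are 1), or `w'_ij = w_ij / (v_i * v_j)` with `method =
#' "product"`. The diagonal stays zero and symmetry is preserved.
#'
#' @param x A whole-brain `connectome`.
#' @param volumes A volume table (see [read_volumes()]) covering every node:
#'   `wholebrain_index` is the 0-based row/column index into `x`.
#' @param method `"sum"` (default) or `"product"`.
#' @return A volume-normalized `connectome` at the same scale.
#' @export
normalize_by_volume <- function(x, volumes, method = c("sum", "product")) {
  stopifnot(inherits(x, "connectome"))
  method <- match.arg(method)
  volumes <- validate_volumes(volumes)
  n <- nrow(x)
  v <- volumes$volume[match(seq_len(n) - 1L, volumes$wholebrain_index)]
  if (anyNA(v)) {
    rlang::abort(sprintf("missing volume for %d node(s), e.g. index %d",
                         sum(is.na(v)), which(is.na(v))[1] - 1L))
  }
  m <- unclass(x)
  if (method == "sum") {
    denom <- outer(v, v, `+`) / 2
  } else {
    denom <- outer(v, v, `*`)
  }
  m <- m / denom
  diag(m) <- 0
  connectome(m, labels = conn_labels(x), scale = conn_scale(x),
             subject_id = conn_subject(x))
}

#' Extract the 76-node working-memory sub-connectome
#'
#' Selects the rows/columns of the whole-brain matrix corresponding to the
#' 76 WM parcels, in the hierarchy's canonical fine order.
#'
#' @param x A whole-brain `connectome` (379 nodes).
#' @param hierarchy A [wm_hierarchy()] with whole-brain indices attached.
#' @return A `connectome` at scale `fine76`.
#' @export
extract_subnetwork <- function(x, hierarchy) {
  stopifnot(inherits(x, "connectome"), inherits(hierarchy, "wm_hierarchy"))
  if (conn_scale(x) != "wholebrain379") {
    rlang::abort("extract_subnetwork expects a wholebrain379 connectome")
  }
  if (anyNA(hierarchy$wholebrain_index)) {
    rlang::abort("hierarchy has unmapped nodes; run attach_wholebrain_indices() first")
  }
  idx <- hierarchy$wholebrain_index + 1L  # 0-based -> R
  m <- unclass(x)[idx, idx, drop = FALSE]
  connectome(m, labels = node_labels(hierarchy, "fine76"),
             scale = "fine76", subject_id = conn_subject(x))
}

#' Coarse-grain a fine WM connectome to 24 regions by summation
#'
#' For each pair of distinct coarse regions A and B, the coarse edge weight
#' is the sum of all fine edge weights between nodes of A and nodes of B.
#' Fine edges *within* a region are not placed on the coarse diagonal (the
#' coarse graph stays loop-free for the nodal metrics); their summed mass is
#' returned separately as the `within_mass` attribute, so total connectivity
#' is preserved across the two outputs:
#' `sum(fine off-diagonal) = sum(coarse off-diagonal) + 2 * sum(within_mass)`.
#'
#' @param x A `connectome` at scale `fine76`.
#' @param hierarchy A [wm_hierarchy()].
#' @return A `connectome` at scale `coarse24`, with a named numeric
#'   `within_mass` attribute over the 24 regions.
#' @export
coarsen <- function(x, hierarchy) {
  stopifnot(inherits(x, "connectome"), inherits(hierarchy, "wm_hierarchy"))
  if (conn_scale(x) != "fine76") {
    rlang::abort("coarsen expects a fine76 connectome")
  }
  part <- hierarchy$coarse_index
  k <- max(part)
  # membership matrix: M[i, a] = 1 iff fine node i is in coarse region a
  M <- matrix(0, nrow(x), k)
  M[cbind(seq_len(nrow(x)), part)] <- 1
  agg <- t(M) %*% unclass(x) %*% M
  within <- diag(agg) / 2  # each within-region fine edge counted twice
  diag(agg) <- 0
  labels <- node_labels(hierarchy, "coarse24")
  names(within) <- labels
  out <- connectome(agg, labels = labels, scale = "coarse24",
                    subject_id = conn_subject(x))
  attr(out, "within_mass") <- within
  out
}

#' Within-region mass of a coarsened connectome
#' @param x A `connectome` produced by [coarsen()].
#' @return Named numeric vector of within-region summed fine edge weights.
#' @export
within_mass <- function(x) attr(x, "within_mass")

#' Build fine- and coarse-scale WM connectomes from a whole-brain matrix
#'
#' Composes the multiscale construction: volume normalization at the
#' whole-brain scale, extraction of the 76-node WM sub-network, and
#' summation coarse-graining to 24 regions.
#'
#' @param x A whole-brain `connectome`.
#' @param volumes Volume table, or `NULL` to skip normalization.
#' @param hierarchy A [wm_hierarchy()] with whole-brain indices attached.
#' @param norm `"sum"`, `"product"` or `"none"`.
#' @return A list with elements `fine` (76-node `connectome`) and `coarse`
#'   (24-region `connectome` carrying its `within_mass`).
#' @export
build_multiscale <- function(x, volumes, hierarchy,
                             norm = c("sum", "product", "none")) {
  norm <- match.arg(norm)
  if (norm != "none") {
    if (is.null(volumes)) rlang::abort("volume table required unless norm = 'none'")
    x <- normalize_by_volume(x, volumes, method = norm)
  }
  fine <- extract_subnetwork(x, hierarchy)
  coarse <- coarsen(fine, hierarchy)
  list(fine = fine, coarse = coarse)
}
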