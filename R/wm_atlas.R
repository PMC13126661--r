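#' The working-memory node hierarchy
#'
#' The working-memory (WM) structural network studied by this package is a
#' fixed set of 76 parcels of the HCP-MMP1 whole-brain parcellation: 35
#' bilateral cortical areas showing robust 2-back-minus-0-back task
#' activation, plus the bilateral caudate, putamen and thalamus. The 70
#' cortical parcels are grouped into 9 bilateral anatomical categories
#' (ACMPC, DLPC, IFC, IPC, IFOC, OPFC, PCC, PMC, SPC) and the 6 subcortical
#' parcels are their own groups, giving 24 coarse regions (12 bilateral
#' region labels x 2 hemispheres).
#'
#' `wm_hierarchy()` reads the node table packaged with `wmnet` and returns a
#' `wm_hierarchy` tibble with one row per fine node, ordered coarse-group
#' major (groups in atlas table order, left hemisphere before right, parcels
#' in table row order within a group). This ordering is the canonical node
#' order of every 76-node and 24-node matrix the package produces.
#'
#' @param path Path to a node table TSV with columns `parcel`, `hemisphere`
#'   (`left`/`right`), `kind` (`cortical`/`subcortical`) and `group`.
#'   Defaults to the table packaged with the package.
#'
#' @return A tibble of class `wm_hierarchy` with columns `parcel`,
#'   `hemisphere`, `kind`, `group`, `fine_index` (1..76), `coarse_label`
#'   (e.g. `"DLPC_L"`), `coarse_index` (1..24) and `wholebrain_index`
#'   (0-based index into the 379-region whole-brain matrix; `NA` until
#'   attached with [attach_wholebrain_indices()]).
#'
#' @examples
#' h <- wm_hierarchy()
#' nrow(h)                      # 76 fine nodes
#' dplyr::n_distinct(h$coarse_label)  # 24 coarse regions
#' @export
wm_hierarchy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "wm_nodes.tsv", package = "wmnet",
                        mustWork = TRUE)
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("parcel", "hemisphere", "kind", "group")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    rlang::abort(paste0("node table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  new_wm_hierarchy(tab)
}

# Validates the node table and derives fine/coarse indexing. Row order of
# `tab` defines the canonical fine order; coarse order follows from it.
new_wm_hierarchy <- function(tab) {
  stopifnot(all(c("parcel", "hemisphere", "kind", "group") %in% names(tab)))
  if (any(!nzchar(tab$parcel))) rlang::abort("empty parcel name")
  if (!all(tab$hemisphere %in% c("left", "right"))) {
    rlang::abort("hemisphere must be 'left' or 'right'")
  }
  if (!all(tab$kind %in% c("cortical", "subcortical"))) {
    rlang::abort("kind must be 'cortical' or 'subcortical'")
  }
  sub <- tab$kind == "subcortical"
  if (!all(tab$group[sub] == tab$parcel[sub])) {
    rlang::abort("subcortical parcels must have group equal to their own name")
  }

  h <- tibble::as_tibble(tab[c("parcel", "hemisphere", "kind", "group")])
  h$fine_index <- seq_len(nrow(h))
  h$coarse_label <- paste0(h$group, "_",
                           ifelse(h$hemisphere == "left", "L", "R"))
  h$coarse_index <- match(h$coarse_label, unique(h$coarse_label))
  if (!"wholebrain_index" %in% names(tab)) {
    h$wholebrain_index <- NA_integer_
  } else {
    h$wholebrain_index <- as.integer(tab$wholebrain_index)
  }

  if (nrow(h) != 76) {
    rlang::abort(sprintf("expected 76 fine nodes, got %d", nrow(h)))
  }
  if (dplyr::n_distinct(h$coarse_label) != 24) {
    rlang::abort("expected 24 coarse regions")
  }
  # bilateral symmetry: each group carries the same parcel set per hemisphere
  by_grp <- split(h, h$group)
  ok <- vapply(by_grp, function(g) {
    setequal(g$parcel[g$hemisphere == "left"],
             g$parcel[g$hemisphere == "right"])
  }, logical(1))
  if (!all(ok)) {
    rlang::abort(paste0("left/right parcel sets differ for group(s): ",
                        paste(names(by_grp)[!ok], collapse = ", ")))
  }
  class(h) <- c("wm_hierarchy", class(h))
  h
}

#' @export
print.wm_hierarchy <- function(x, ...) {
  cat(sprintf(
    "<wm_hierarchy> %d fine nodes, %d coarse regions, %d with whole-brain index\n",
    nrow(x), dplyr::n_distinct(x$coarse_label), sum(!is.na(x$wholebrain_index))))
  NextMethod()
}

#' Attach whole-brain matrix indices to the hierarchy
#'
#' Maps each of the 76 WM parcels to its row/column index in the 379-region
#' whole-brain connectivity matrix. The mapping is supplied as a lookup table
#' because whole-brain orderings differ between tractography pipelines; the
#' package ships a deterministic synthetic default
#' (`wholebrain_lookup_synthetic.tsv`) that is a stand-in convention, not the
#' published atlas ordering.
#'
#' @param hierarchy A [wm_hierarchy()] object.
#' @param lookup A data frame with columns `parcel`, `hemisphere` and
#'   `wholebrain_index` (0-based, in `0..378`), or a path to such a TSV/CSV.
#'   Defaults to the packaged synthetic lookup.
#'
#' @return The hierarchy with `wholebrain_index` populated for every node.
#' @export
attach_wholebrain_indices <- function(hierarchy, lookup = NULL) {
  stopifnot(inherits(hierarchy, "wm_hierarchy"))
  if (is.null(lookup)) {
    lookup <- system.file("extdata", "wholebrain_lookup_synthetic.tsv",
                          package = "wmnet", mustWork = TRUE)
  }
  if (is.character(lookup)) {
    lookup <- readr::read_tsv(lookup, show_col_types = FALSE)
  }
  required <- c("parcel", "hemisphere", "wholebrain_index")
  if (!all(required %in% names(lookup))) {
    rlang::abort("lookup must have columns parcel, hemisphere, wholebrain_index")
  }
  key <- paste(hierarchy$parcel, hierarchy$hemisphere)
  lk_key <- paste(lookup$parcel, lookup$hemisphere)
  if (anyDuplicated(lk_key)) rlang::abort("duplicate (parcel, hemisphere) in lookup")
  idx <- lookup$wholebrain_index[match(key, lk_key)]
  if (anyNA(idx)) {
    miss <- key[is.na(idx)]
    rlang::abort(paste0("unmapped parcel(s): ", paste(miss, collapse = ", ")))
  }
  idx <- as.integer(idx)
  if (any(idx < 0L | idx > 378L)) {
    rlang::abort("wholebrain_index out of range [0, 378]")
  }
  if (anyDuplicated(idx)) {
    dup <- idx[duplicated(idx)]
    rlang::abort(paste0("collision: whole-brain index assigned to two parcels: ",
                        paste(unique(dup), collapse = ", ")))
  }
  hierarchy$wholebrain_index <- idx
  hierarchy
}

# bilateral system groupings used as the participation-coefficient module
# partition at the coarse scale
wm_systems <- list(
  frontal       = c("ACMPC", "DLPC", "IFC", "IFOC", "OPFC", "PMC"),
  parietal      = c("IPC", "SPC"),
  posteromedial = c("PCC"),
  subcortical   = c("caudate", "putamen", "thalamus")
)

#' Partition the fine nodes into modules
#'
#' Returns a module assignment for the 76 fine nodes, used as the
#' participation-coefficient partition and by the synthetic generator.
#' `"groups24"` is the 24-region anatomical partition; `"systems"` pools the
#' regions into 4 bilateral systems (frontal, parietal, posteromedial,
#' subcortical).
#'
#' @param hierarchy A [wm_hierarchy()] object.
#' @param level `"groups24"` or `"systems"`.
#' @param systems Optional named list of character vectors overriding the
#'   default system definition (names are system labels, elements are region
#'   group labels).
#'
#' @return An integer vector of module ids over the fine nodes, with module
#'   labels as a `"labels"` attribute and names set to node labels.
#' @export
coarse_partition <- function(hierarchy, level = c("groups24", "systems"),
                             systems = NULL) {
  stopifnot(inherits(hierarchy, "wm_hierarchy"))
  if (length(level) > 1) level <- level[[1]]
  if (!is.character(level) || !level %in% c("groups24", "systems")) {
    rlang::abort(paste0("unknown partition level: ", as.character(level)[1]))
  }
  if (level == "groups24") {
    part <- hierarchy$coarse_index
    labels <- unique(hierarchy$coarse_label)
  } else {
    if (is.null(systems)) systems <- wm_systems
    sys_of_group <- rep(names(systems), lengths(systems))
    names(sys_of_group) <- unlist(systems)
    if (!all(hierarchy$group %in% names(sys_of_group))) {
      rlang::abort("system definition does not cover every region group")
    }
    sys <- unname(sys_of_group[hierarchy$group])
    labels <- names(systems)[names(systems) %in% sys]
    part <- match(sys, labels)
  }
  names(part) <- node_labels(hierarchy)
  attr(part, "labels") <- labels
  part
}

#' Canonical node labels of the hierarchy
#'
#' Fine labels are `parcel_L` / `parcel_R`; coarse labels are
#' `group_L` / `group_R`.
#'
#' @param hierarchy A [wm_hierarchy()] object.
#' @param scale `"fine76"` or `"coarse24"`.
#' @return Character vector of 76 or 24 labels.
#' @export
node_labels <- function(hierarchy, scale = c("fine76", "coarse24")) {
  scale <- match.arg(scale)
  if (scale == "fine76") {
    paste0(hierarchy$parcel, "_",
           ifelse(hierarchy$hemisphere == "left", "L", "R"))
  } else {
    unique(hierarchy$coarse_label)
  }
}

#' Write a hierarchy back to its on-disk TSV form
#'
#' @param hierarchy A [wm_hierarchy()] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "wm_hierarchy"))
  cols <- c("parcel", "hemisphere", "kind", "group")
  tab <- as.data.frame(hierarchy)[cols]
  if (!all(is.na(hierarchy$wholebrain_index))) {
    tab$wholebrain_index <- hierarchy$wholebrain_index
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
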