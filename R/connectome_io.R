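#' Construct a connectome object
#'
#' A connectome is a weighted, undirected brain network: a square symmetric
#' nonnegative matrix with zero diagonal and ordered node labels, at one of
#' three scales (whole-brain 379, fine 76-node WM network, coarse 24-region
#' WM network).
#'
#' Small numerical asymmetries (relative to the largest absolute entry, up
#' to `tol`) are symmetrized as `(W + t(W))/2`, matching the tiny
#' asymmetries some tractography exporters emit; larger asymmetries indicate
#' a directed matrix and are an error. A nonzero diagonal is forced to zero
#' with a warning.
#'
#' @param weights Square numeric matrix.
#' @param labels Character vector of node labels (defaults to existing
#'   dimnames or `n1..nN`).
#' @param scale One of `"wholebrain379"`, `"fine76"`, `"coarse24"`.
#' @param subject_id Subject identifier.
#' @param tol Relative symmetry tolerance.
#'
#' @return An object of class `connectome`: the validated matrix with
#'   attributes `labels`, `scale`, `subject_id`.
#' @export
connectome <- function(weights, labels = NULL,
                       scale = c("wholebrain379", "fine76", "coarse24"),
                       subject_id = "subject", tol = 1e-8) {
  scale <- match.arg(scale)
  if (!is.matrix(weights) || !is.numeric(weights)) {
    rlang::abort("weights must be a numeric matrix")
  }
  n <- nrow(weights)
  if (ncol(weights) != n) rlang::abort("weights must be square")
  expected <- c(wholebrain379 = 379L, fine76 = 76L, coarse24 = 24L)[[scale]]
  if (n != expected) {
    rlang::abort(sprintf("scale '%s' requires a %d x %d matrix, got %d x %d",
                         scale, expected, expected, n, ncol(weights)))
  }
  if (anyNA(weights)) rlang::abort("weights contain missing values")
  if (any(weights < 0)) rlang::abort("negative entry in connectivity matrix")
  scale_ref <- max(abs(weights), 1e-300)
  asym <- max(abs(weights - t(weights)))
  if (asym > tol * scale_ref) {
    rlang::abort(sprintf(
      "matrix asymmetry %.3g exceeds relative tolerance %.1g", asym / scale_ref, tol))
  }
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) {
    rlang::warn("nonzero diagonal forced to 0")
    diag(weights) <- 0
  }
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- paste0("n", seq_len(n))
  }
  if (length(labels) != n) rlang::abort("label count must equal matrix dimension")
  dimnames(weights) <- list(labels, labels)
  structure(weights,
            labels = labels, scale = scale, subject_id = subject_id,
            class = c("connectome", "matrix", "array"))
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> subject '%s', scale %s, %d nodes, %d positive edges\n",
              attr(x, "subject_id"), attr(x, "scale"), nrow(x),
              sum(x[upper.tri(x)] > 0)))
  invisible(x)
}

conn_scale <- function(x) attr(x, "scale")
conn_labels <- function(x) attr(x, "labels")
conn_subject <- function(x) attr(x, "subject_id")

#' Read a connectivity matrix from delimited text
#'
#' Reads a dense square numeric matrix (no header) in comma- or
#' whitespace-delimited form, as emitted by tractography connectome tools,
#' and validates it as a [connectome()].
#'
#' @param path File path.
#' @param expected_dim Required matrix dimension (379, 76 or 24).
#' @param subject_id Subject identifier to attach.
#' @param tol Relative symmetry tolerance (see [connectome()]).
#' @return A `connectome` at the scale implied by `expected_dim`.
#' @export
read_connectome <- function(path, expected_dim = 379L,
                            subject_id = sub("\\.[^.]*$", "", basename(path)),
                            tol = 1e-8) {
  if (!expected_dim %in% c(379L, 76L, 24L)) {
    rlang::abort("expected_dim must be 379, 76 or 24")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      colClasses = "numeric", strip.white = TRUE),
    warning = function(w) rlang::abort(paste0("failed to parse matrix: ", conditionMessage(w))),
    error = function(e) rlang::abort(paste0("non-numeric or malformed cell in ", path)))
  m <- as.matrix(tab)
  dimnames(m) <- NULL
  if (nrow(m) != expected_dim || ncol(m) != expected_dim) {
    rlang::abort(sprintf("expected a %d x %d matrix, got %d x %d",
                         expected_dim, expected_dim, nrow(m), ncol(m)))
  }
  scale <- c(`379` = "wholebrain379", `76` = "fine76", `24` = "coarse24")[[as.character(expected_dim)]]
  connectome(m, scale = scale, subject_id = subject_id, tol = tol)
}

#' Write a connectome as delimited text
#'
#' Writes the weight matrix as comma-separated dense text at full double
#' precision, so that [read_connectome()] round-trips it within 1e-12
#' relative error.
#'
#' @param x A `connectome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path) {
  stopifnot(inherits(x, "connectome"))
  m <- unclass(x)
  lines <- apply(m, 1L, function(r) paste(format(r, digits = 17, trim = TRUE,
                                                 scientific = FALSE),
                                          collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a subject covariate table
#'
#' Expects a CSV/TSV with named columns `subject_id`, `group` (`ALL`/`HC`),
#' `age` (years, positive) and `sex` (`M`/`F`).
#'
#' @param path File path (delimiter inferred from the header line).
#' @return A tibble with validated, typed columns.
#' @export
read_covariates <- function(path) {
  tab <- read_delim_auto(path)
  validate_covariates(tab)
}

validate_covariates <- function(tab) {
  required <- c("subject_id", "group", "age", "sex")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    rlang::abort(paste0("covariate table missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  tab <- tibble::as_tibble(tab)
  tab$subject_id <- as.character(tab$subject_id)
  if (anyDuplicated(tab$subject_id)) {
    rlang::abort("duplicate subject_id in covariate table")
  }
  if (!all(tab$group %in% c("ALL", "HC"))) {
    rlang::abort("group must be one of {ALL, HC}")
  }
  if (!all(tab$sex %in% c("M", "F"))) {
    rlang::abort("sex must be one of {M, F}")
  }
  tab$age <- as.numeric(tab$age)
  if (anyNA(tab$age) || any(tab$age <= 0)) {
    rlang::abort("age must be positive")
  }
  tab
}

#' Read a region-volume table
#'
#' Expects a CSV/TSV with named columns `wholebrain_index` (0-based region
#' index) and `volume` (mm^3, positive), one row per parcellation region.
#'
#' @param path File path.
#' @return A tibble with validated columns.
#' @export
read_volumes <- function(path) {
  tab <- read_delim_auto(path)
  validate_volumes(tab)
}

validate_volumes <- function(tab) {
  required <- c("wholebrain_index", "volume")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    rlang::abort(paste0("volume table missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  tab <- tibble::as_tibble(tab)
  tab$wholebrain_index <- as.integer(tab$wholebrain_index)
  if (anyDuplicated(tab$wholebrain_index)) {
    rlang::abort("duplicate wholebrain_index in volume table")
  }
  tab$volume <- as.numeric(tab$volume)
  if (anyNA(tab$volume) || any(tab$volume <= 0)) {
    rlang::abort("volume must be positive")
  }
  tab
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
}
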