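# Core domain types. All containers are base matrices with drug identifiers
# as dimnames plus a class tag and a few attributes; heavy math internally
# works on the unclassed matrix and re-wraps the result.

new_ddi_matrix <- function(values, ids, class, extra = list()) {
  values <- as.matrix(values)
  dimnames(values) <- list(ids, ids)
  attributes(values) <- c(attributes(values), extra)
  class(values) <- c(class, "ddigip_matrix", class(values))
  values
}

#' Construct a symmetric drug-drug interaction matrix
#'
#' The adjacency matrix Y of the known DDI network: `values[i, j] = 1` when
#' drugs i and j are known to interact. After KNN cold-start filling the
#' matrix becomes real-valued (`binary = FALSE`). Self-interactions are
#' structurally excluded: the diagonal is always zero.
#'
#' @param values square numeric matrix, symmetric with zero diagonal.
#' @param ids character vector of unique drug identifiers (row/col names).
#' @param binary logical; if `TRUE`, entries must all be 0 or 1.
#' @return an `interaction_matrix` object.
#' @export
interaction_matrix <- function(values, ids = rownames(values), binary = NULL) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- paste0("drug", seq_len(nrow(values)))
  if (is.null(binary)) binary <- all(values %in% c(0, 1))
  x <- new_ddi_matrix(values, ids, "interaction_matrix",
                      list(binary = isTRUE(binary)))
  validate_interaction_matrix(x)
  x
}

#' Construct a binary drug feature matrix
#'
#' One row per drug; columns are presence/absence bits of chemical
#' substructures, targets, transporters, enzymes, pathways, indications and
#' side-effect terms, concatenated into one vector per drug.
#'
#' @param values numeric matrix with entries in \{0, 1\}, one row per drug.
#' @param ids drug identifiers, one per row.
#' @param feature_names optional column names.
#' @param missing named logical vector flagging drugs whose feature row was
#'   absent from the input and zero-filled during alignment; such drugs are
#'   excluded from KNN cold-start imputation.
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(values, ids = rownames(values),
                           feature_names = colnames(values),
                           missing = NULL) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- paste0("drug", seq_len(nrow(values)))
  if (is.null(missing)) missing <- stats::setNames(rep(FALSE, nrow(values)), ids)
  values <- matrix(as.numeric(values), nrow(values), ncol(values))
  rownames(values) <- ids
  colnames(values) <- feature_names
  attr(values, "missing") <- missing
  class(values) <- c("feature_matrix", "ddigip_matrix", class(values))
  validate_feature_matrix(values)
  values
}

#' Construct a drug-drug similarity (kernel) matrix
#'
#' @param values symmetric numeric matrix of pairwise similarities.
#' @param ids drug identifiers.
#' @param kind `"gip"` (Gaussian interaction profile kernel; entries in
#'   (0, 1], unit diagonal) or `"pearson"` (feature correlation; entries in
#'   \[-1, 1\]).
#' @param degenerate named logical vector flagging drugs with an undefined
#'   similarity row (constant feature vector under `kind = "pearson"`);
#'   their entries are set to 0.
#' @return a `kernel_matrix` object.
#' @export
kernel_matrix <- function(values, ids = rownames(values),
                          kind = c("gip", "pearson"), degenerate = NULL) {
  kind <- match.arg(kind)
  if (is.null(ids)) ids <- paste0("drug", seq_len(nrow(values)))
  if (is.null(degenerate)) degenerate <- stats::setNames(rep(FALSE, nrow(values)), ids)
  x <- new_ddi_matrix(values, ids, "kernel_matrix",
                      list(kind = kind, degenerate = degenerate))
  validate_kernel_matrix(x)
  x
}

#' Construct a prediction score matrix
#'
#' Holds the symmetric matrix of RLS interaction scores Y_p.
#' @param values symmetric numeric matrix of pair scores.
#' @param ids drug identifiers.
#' @return a `prediction_matrix` object.
#' @export
prediction_matrix <- function(values, ids = rownames(values)) {
  if (is.null(ids)) ids <- paste0("drug", seq_len(nrow(values)))
  x <- new_ddi_matrix(values, ids, "prediction_matrix")
  validate_prediction_matrix(x)
  x
}

#' Drug identifiers of a ddigip container
#' @param x any ddigip matrix object.
#' @return character vector of drug ids.
#' @export
drug_ids <- function(x) rownames(x)

as_plain_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "binary") <- NULL
  attr(y, "kind") <- NULL
  attr(y, "degenerate") <- NULL
  attr(y, "missing") <- NULL
  y
}

check_square_symmetric <- function(x, what, tol = 1e-8) {
  if (nrow(x) != ncol(x)) {
    ddigip_abort(sprintf("%s must be square", what), "invalid_matrix")
  }
  m <- as_plain_matrix(x)
  if (nrow(m) > 0 && max(abs(m - t(m))) > tol) {
    ddigip_abort(sprintf("%s must be symmetric", what), "invalid_matrix")
  }
  ids <- rownames(x)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    ddigip_abort(sprintf("%s must carry unique non-empty drug ids", what),
                 "invalid_ids")
  }
  invisible(x)
}

#' Validate a ddigip container against its type invariants
#'
#' Each validator checks the structural invariants of its type (symmetry,
#' zero diagonal, binary entries, kernel ranges) and signals a classed
#' error on violation. `validate_ddi_object()` dispatches on class.
#'
#' @param x the object to validate.
#' @return the object, invisibly, if valid.
#' @export
validate_interaction_matrix <- function(x) {
  check_square_symmetric(x, "interaction matrix")
  m <- as_plain_matrix(x)
  if (nrow(m) > 0 && any(diag(m) != 0)) {
    ddigip_abort("interaction matrix must have a zero diagonal (no self-interactions)",
                 "invalid_matrix")
  }
  if (isTRUE(attr(x, "binary")) && !all(m %in% c(0, 1))) {
    ddigip_abort("binary interaction matrix has entries outside {0, 1}",
                 "invalid_matrix")
  }
  invisible(x)
}

#' @rdname validate_interaction_matrix
#' @export
validate_feature_matrix <- function(x) {
  m <- as_plain_matrix(x)
  if (!all(m %in% c(0, 1))) {
    ddigip_abort("feature matrix entries must be 0 or 1", "invalid_matrix")
  }
  ids <- rownames(x)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    ddigip_abort("feature matrix must carry unique non-empty drug ids",
                 "invalid_ids")
  }
  miss <- attr(x, "missing")
  if (length(miss) != nrow(m)) {
    ddigip_abort("feature matrix `missing` flag must have one entry per drug",
                 "invalid_matrix")
  }
  invisible(x)
}

#' @rdname validate_interaction_matrix
#' @export
validate_kernel_matrix <- function(x) {
  check_square_symmetric(x, "kernel matrix")
  m <- as_plain_matrix(x)
  kind <- attr(x, "kind")
  deg <- which(attr(x, "degenerate"))
  ok <- setdiff(seq_len(nrow(m)), deg)
  if (identical(kind, "gip")) {
    if (any(m <= 0) || any(m > 1 + 1e-12)) {
      ddigip_abort("GIP kernel entries must lie in (0, 1]", "invalid_matrix")
    }
    if (any(abs(diag(m) - 1) > 1e-12)) {
      ddigip_abort("GIP kernel diagonal must be exactly 1", "invalid_matrix")
    }
  } else if (identical(kind, "pearson")) {
    if (any(m < -1 - 1e-12) || any(m > 1 + 1e-12)) {
      ddigip_abort("Pearson similarity entries must lie in [-1, 1]",
                   "invalid_matrix")
    }
    if (length(ok) && any(abs(diag(m)[ok] - 1) > 1e-12)) {
      ddigip_abort("Pearson similarity diagonal must be 1 for non-degenerate drugs",
                   "invalid_matrix")
    }
  }
  invisible(x)
}

#' @rdname validate_interaction_matrix
#' @export
validate_prediction_matrix <- function(x) {
  check_square_symmetric(x, "prediction matrix")
  if (any(!is.finite(as_plain_matrix(x)))) {
    ddigip_abort("prediction matrix has non-finite entries", "invalid_matrix")
  }
  invisible(x)
}

#' @rdname validate_interaction_matrix
#' @export
validate_ddi_object <- function(x) {
  if (inherits(x, "interaction_matrix")) return(validate_interaction_matrix(x))
  if (inherits(x, "feature_matrix")) return(validate_feature_matrix(x))
  if (inherits(x, "kernel_matrix")) return(validate_kernel_matrix(x))
  if (inherits(x, "prediction_matrix")) return(validate_prediction_matrix(x))
  ddigip_abort("not a ddigip container", "invalid_matrix")
}

#' @export
print.ddigip_matrix <- function(x, ...) {
  cls <- class(x)[1]
  cat(sprintf("<%s> %d drugs", cls, nrow(x)))
  if (inherits(x, "feature_matrix")) cat(sprintf(" x %d features", ncol(x)))
  if (!is.null(attr(x, "kind"))) cat(sprintf(" [%s]", attr(x, "kind")))
  cat("\n")
  print(as_plain_matrix(x)[seq_len(min(6L, nrow(x))),
                           seq_len(min(6L, ncol(x))), drop = FALSE])
  invisible(x)
}
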