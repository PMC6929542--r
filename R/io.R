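# Readers/writers for the two plain-text inputs (edge list, feature table)
# and the ranked-pair output, plus index alignment between them.

sniff_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

split_fields <- function(lines, sep) {
  strsplit(lines, sep, fixed = TRUE)
}

#' Read a DDI edge list
#'
#' One undirected interacting drug pair per line, two identifier columns,
#' comma-separated for `.csv` files and tab-separated otherwise. Duplicate
#' pairs and both orderings of a pair collapse to a single edge.
#'
#' @param path path to the edge list.
#' @param drug_ids optional character vector of drug identifiers fixing the
#'   matrix universe; drugs with no listed edge get all-zero rows. When
#'   omitted the universe is the sorted set of ids seen in the file.
#' @param header logical; `TRUE` if the first line is a header to skip.
#' @param sep field separator; defaults to sniffing the file extension.
#' @return a binary [interaction_matrix()].
#' @export
read_edge_list <- function(path, drug_ids = NULL, header = FALSE, sep = NULL) {
  if (!file.exists(path)) {
    ddigip_abort(sprintf("edge list file not found: %s", path), "missing_file")
  }
  sep <- sep %||% sniff_sep(path)
  lines <- readLines(path, warn = FALSE)
  offset <- 0L
  if (header && length(lines) >= 1L) {
    lines <- lines[-1L]
    offset <- 1L
  }
  lines_keep <- which(nzchar(trimws(lines)))
  fields <- split_fields(lines[lines_keep], sep)
  pairs <- matrix(character(), 0L, 2L)
  for (k in seq_along(fields)) {
    f <- trimws(fields[[k]])
    f <- f[nzchar(f)]
    lineno <- lines_keep[k] + offset
    if (length(f) != 2L) {
      ddigip_abort(sprintf("line %d: expected two drug identifiers, found %d",
                           lineno, length(f)), "malformed_edge")
    }
    if (f[1] == f[2]) {
      ddigip_abort(sprintf("line %d: self-interaction '%s,%s' is not allowed",
                           lineno, f[1], f[2]), "self_interaction")
    }
    pairs <- rbind(pairs, f)
  }
  if (is.null(drug_ids)) {
    drug_ids <- sort(unique(as.vector(pairs)))
  } else {
    if (anyDuplicated(drug_ids)) {
      ddigip_abort("`drug_ids` contains duplicates", "invalid_ids")
    }
    unknown <- setdiff(unique(as.vector(pairs)), drug_ids)
    if (length(unknown)) {
      ddigip_abort(sprintf("edge list names drugs absent from `drug_ids`: %s",
                           paste(unknown, collapse = ", ")), "unknown_drug")
    }
  }
  n <- length(drug_ids)
  Y <- matrix(0, n, n, dimnames = list(drug_ids, drug_ids))
  if (nrow(pairs)) {
    i <- match(pairs[, 1], drug_ids)
    j <- match(pairs[, 2], drug_ids)
    Y[cbind(i, j)] <- 1
    Y[cbind(j, i)] <- 1
  }
  interaction_matrix(Y, drug_ids, binary = TRUE)
}

#' Read a binary drug feature table
#'
#' Delimited table whose first column (`drug_id`) holds the drug identifier
#' and whose remaining columns are 0/1 feature bits.
#'
#' @param path path to the table.
#' @param header logical; `TRUE` (default) if the first line names columns.
#' @param sep field separator; defaults to sniffing the file extension.
#' @return a [feature_matrix()] with a drug index in file row order.
#' @export
read_feature_table <- function(path, header = TRUE, sep = NULL) {
  if (!file.exists(path)) {
    ddigip_abort(sprintf("feature table file not found: %s", path),
                 "missing_file")
  }
  sep <- sep %||% sniff_sep(path)
  df <- tryCatch(
    utils::read.table(path, header = header, sep = sep,
                      colClasses = "character", check.names = FALSE,
                      strip.white = TRUE),
    error = function(e) {
      ddigip_abort(sprintf("cannot parse feature table %s: %s",
                           path, conditionMessage(e)), "malformed_table")
    })
  if (nrow(df) == 0L) {
    ddigip_abort("feature table contains no drugs", "empty_table")
  }
  if (ncol(df) < 2L) {
    ddigip_abort("feature table needs a drug_id column plus >= 1 feature column",
                 "malformed_table")
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    ddigip_abort(sprintf("duplicated drug id in feature table: %s", dup),
                 "duplicate_drug")
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(matrix(!(vals %in% c("0", "1")), nrow(vals)), arr.ind = TRUE)
  if (nrow(bad)) {
    ddigip_abort(sprintf(
      "non-binary feature cell '%s' at drug %s, column %s",
      vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
      colnames(vals)[bad[1, 2]] %||% bad[1, 2]), "non_binary_cell")
  }
  storage.mode(vals) <- "numeric"
  feature_matrix(vals, ids = ids, feature_names = colnames(vals))
}

#' Align an interaction matrix and a feature matrix onto one drug index
#'
#' Both outputs share the sorted union of the two id sets. Drugs absent from
#' the interaction input get all-zero interaction rows; drugs absent from
#' the feature input get all-zero feature rows flagged `missing`, which
#' excludes them from KNN cold-start imputation downstream.
#'
#' @param interactions an [interaction_matrix()].
#' @param features a [feature_matrix()].
#' @return list with elements `interactions` and `features` on the shared
#'   index.
#' @export
align_drug_data <- function(interactions, features) {
  validate_interaction_matrix(interactions)
  validate_feature_matrix(features)
  ids <- sort(union(drug_ids(interactions), drug_ids(features)))
  n <- length(ids)

  Y <- matrix(0, n, n, dimnames = list(ids, ids))
  common_y <- intersect(ids, drug_ids(interactions))
  Y[common_y, common_y] <- as_plain_matrix(interactions)[common_y, common_y]

  f <- ncol(features)
  V <- matrix(0, n, f, dimnames = list(ids, colnames(features)))
  common_v <- intersect(ids, drug_ids(features))
  V[common_v, ] <- as_plain_matrix(features)[common_v, , drop = FALSE]
  missing <- stats::setNames(!(ids %in% common_v), ids)

  list(interactions = interaction_matrix(Y, ids, binary = attr(interactions, "binary")),
       features = feature_matrix(V, ids = ids, feature_names = colnames(features),
                                 missing = missing))
}

#' Write top-ranked candidate drug pairs
#'
#' Ranks all unordered pairs not known to interact by descending predicted
#' score (ties broken lexicographically by drug ids) and writes the top
#' `top` rows as TSV with columns `rank`, `drug_id_1`, `drug_id_2`, `score`.
#'
#' @param pred a [prediction_matrix()].
#' @param known the binary [interaction_matrix()] of known DDIs; known pairs
#'   are excluded from the candidate list.
#' @param path output file path.
#' @param top number of rows to write; truncated to the number of candidate
#'   pairs.
#' @return invisibly, the written data frame.
#' @export
write_ranked_pairs <- function(pred, known, path, top = 100L) {
  validate_prediction_matrix(pred)
  validate_interaction_matrix(known)
  if (!identical(drug_ids(pred), drug_ids(known))) {
    ddigip_abort("prediction and known-interaction matrices must share one drug index",
                 "index_mismatch")
  }
  ids <- drug_ids(pred)
  P <- as_plain_matrix(pred)
  K <- as_plain_matrix(known)
  ut <- which(upper.tri(P) & K == 0, arr.ind = TRUE)
  df <- data.frame(drug_id_1 = ids[ut[, 1]], drug_id_2 = ids[ut[, 2]],
                   score = P[ut], stringsAsFactors = FALSE)
  df <- df[order(-df$score, df$drug_id_1, df$drug_id_2), , drop = FALSE]
  df <- utils::head(df, max(0L, as.integer(top)))
  out <- data.frame(rank = seq_len(nrow(df)), df, row.names = NULL)
  out$score <- sprintf("%.6f", out$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Write a square similarity matrix as TSV
#'
#' Drug ids appear as the first row and first column; values are printed
#' with 6 decimal places.
#'
#' @param x a [kernel_matrix()] or [prediction_matrix()].
#' @param path output file path.
#' @return invisibly, `NULL`.
#' @export
write_similarity_matrix <- function(x, path) {
  m <- as_plain_matrix(x)
  out <- cbind(drug_id = rownames(m),
               as.data.frame(apply(m, 2, function(col) sprintf("%.6f", col))))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Write an interaction matrix back to an edge list
#'
#' Inverse of [read_edge_list()] for binary matrices: writes each unordered
#' interacting pair (i < j in id order) once.
#'
#' @param Y a binary [interaction_matrix()].
#' @param path output file path.
#' @param sep field separator; defaults to sniffing the file extension.
#' @return invisibly, the number of edges written.
#' @export
write_edge_list <- function(Y, path, sep = NULL) {
  validate_interaction_matrix(Y)
  sep <- sep %||% sniff_sep(path)
  ids <- drug_ids(Y)
  m <- as_plain_matrix(Y)
  ut <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  lines <- paste(ids[ut[, 1]], ids[ut[, 2]], sep = sep)
  writeLines(lines, path)
  invisible(length(lines))
}
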