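# The DDIGIP scoring core: KNN cold-start fill, GIP kernel, RLS solve,
# symmetrization, composed into the end-to-end predictor.

#' Parameters of the DDIGIP predictor
#'
#' @param sigma RLS regularization parameter, > 0; default 1.
#' @param gamma_prime GIP bandwidth multiplier, > 0; default 1.
#' @param k_neighbors number of nearest neighbours K used by the cold-start
#'   fill; default 9 (the grid-search optimum on the original benchmark).
#' @param knn_enabled logical; apply the KNN fill when features are
#'   available. Default `TRUE`.
#' @return a `ddigip_params` list.
#' @export
ddigip_params <- function(sigma = 1, gamma_prime = 1, k_neighbors = 9L,
                          knn_enabled = TRUE) {
  stopifnot_scalar_number(sigma, "sigma", positive = TRUE)
  stopifnot_scalar_number(gamma_prime, "gamma_prime", positive = TRUE)
  if (!is.numeric(k_neighbors) || length(k_neighbors) != 1L ||
      k_neighbors < 1 || k_neighbors != round(k_neighbors)) {
    ddigip_abort("`k_neighbors` must be a positive integer", "invalid_parameter")
  }
  structure(list(sigma = sigma, gamma_prime = gamma_prime,
                 k_neighbors = as.integer(k_neighbors),
                 knn_enabled = isTRUE(knn_enabled)),
            class = "ddigip_params")
}

#' KNN cold-start fill for new drugs
#'
#' A "new drug" is one whose row of the interaction matrix is all zero. For
#' each new drug i with usable features, its initial interaction scores are
#' the similarity-weighted average of its K most feature-similar neighbours'
#' interaction profiles:
#' `Y'[i, j] = sum_{l in K_set} S[i, l] * y[l, j] / sum_{l in K_set} S[i, l]`.
#' Neighbours are restricted to drugs with at least one known interaction
#' (imputing from other empty rows would only propagate zeros). Filled
#' values are written symmetrically; when two new drugs face each other the
#' two independently computed values are averaged. Drugs flagged
#' feature-missing or feature-degenerate are left untouched.
#'
#' @param Y a binary [interaction_matrix()].
#' @param S the Pearson feature [kernel_matrix()] on the same drug index.
#' @param K number of neighbours; when fewer are eligible, all are used
#'   with a warning. A non-positive similarity-weight sum leaves the row
#'   zero with a warning (the weighted average is undefined).
#' @return an [interaction_matrix()] (real-valued where filled), zero
#'   diagonal, rows of non-new drugs bit-identical to the input.
#' @export
knn_fill <- function(Y, S, K = 9L) {
  validate_interaction_matrix(Y)
  validate_kernel_matrix(S)
  if (!identical(drug_ids(Y), drug_ids(S))) {
    ddigip_abort("interaction and similarity matrices must share one drug index",
                 "index_mismatch")
  }
  if (K < 1) ddigip_abort("`K` must be >= 1", "invalid_parameter")
  ids <- drug_ids(Y)
  m <- as_plain_matrix(Y)
  s <- as_plain_matrix(S)
  degenerate <- attr(S, "degenerate") %||% rep(FALSE, nrow(m))
  is_new <- rowSums(abs(m)) == 0
  eligible <- which(!is_new)
  fill_targets <- which(is_new & !degenerate)
  if (!length(fill_targets) || !length(eligible)) {
    return(interaction_matrix(m, ids, binary = attr(Y, "binary")))
  }
  fills <- list()
  for (i in fill_targets) {
    sims <- s[i, eligible]
    ord <- order(-sims, ids[eligible])
    k_use <- min(as.integer(K), length(eligible))
    if (k_use < K) {
      ddigip_warn(sprintf(
        "drug %s: only %d eligible neighbours (< K = %d); using all",
        ids[i], length(eligible), K), "few_neighbors")
    }
    sel <- eligible[ord[seq_len(k_use)]]
    w <- s[i, sel]
    denom <- sum(w)
    if (denom <= 0) {
      ddigip_warn(sprintf(
        "drug %s: non-positive neighbour similarity sum; row left zero",
        ids[i]), "undefined_fill")
      next
    }
    row <- as.vector(w %*% m[sel, , drop = FALSE]) / denom
    row[i] <- 0
    fills[[as.character(i)]] <- row
  }
  out <- m
  filled <- as.integer(names(fills))
  for (i in filled) {
    out[i, ] <- fills[[as.character(i)]]
    out[, i] <- fills[[as.character(i)]]
  }
  # two filled drugs facing each other: average the two independent values
  if (length(filled) > 1L) {
    for (a in seq_along(filled)) {
      for (b in seq_along(filled)) {
        if (a < b) {
          i <- filled[a]; j <- filled[b]
          v <- (fills[[as.character(i)]][j] + fills[[as.character(j)]][i]) / 2
          out[i, j] <- v
          out[j, i] <- v
        }
      }
    }
  }
  diag(out) <- 0
  interaction_matrix(out, ids, binary = all(out %in% c(0, 1)))
}

#' Regularized least squares (RLS) interaction scores
#'
#' Solves the kernel ridge scoring `Yhat = G (G + sigma I)^{-1} Y` through a
#' symmetric positive-definite (Cholesky) factorization — no explicit
#' inverse is formed — then symmetrizes: `Y_p = (Yhat + t(Yhat)) / 2`.
#'
#' @param G a PSD [kernel_matrix()] (typically from [gip_kernel()]).
#' @param Y an [interaction_matrix()] on the same drug index.
#' @param sigma regularization parameter, > 0.
#' @return a symmetric [prediction_matrix()] of pair scores.
#' @export
rls_scores <- function(G, Y, sigma = 1) {
  validate_kernel_matrix(G)
  validate_interaction_matrix(Y)
  stopifnot_scalar_number(sigma, "sigma", positive = TRUE)
  if (!identical(drug_ids(G), drug_ids(Y))) {
    ddigip_abort("kernel and interaction matrices must share one drug index",
                 "index_mismatch")
  }
  g <- as_plain_matrix(G)
  y <- as_plain_matrix(Y)
  if (any(!is.finite(g)) || any(!is.finite(y))) {
    ddigip_abort("non-finite entries in kernel or interaction matrix",
                 "non_finite")
  }
  A <- g
  diag(A) <- diag(A) + sigma
  U <- chol(A)  # A = G + sigma I is SPD for sigma > 0
  X <- backsolve(U, forwardsolve(t(U), y))  # X = (G + sigma I)^{-1} Y
  Yhat <- g %*% X
  Yp <- (Yhat + t(Yhat)) / 2
  prediction_matrix(Yp, drug_ids(Y))
}

#' End-to-end DDIGIP prediction
#'
#' The composed pipeline: (1) if enabled and features are available, impute
#' initial scores for new drugs via [knn_fill()] using the Pearson feature
#' similarity; (2) compute the GIP kernel of the (possibly filled) matrix;
#' (3) score all pairs with the RLS classifier. The same filled matrix is
#' used both inside the kernel and as the label matrix of the RLS solve.
#'
#' @param Y a binary [interaction_matrix()].
#' @param features optional [feature_matrix()] aligned to `Y` (required for
#'   the cold-start fill).
#' @param params a [ddigip_params()] object.
#' @param feature_sim optional precomputed Pearson [kernel_matrix()];
#'   bypasses recomputation when scoring many masked copies of one network.
#' @return a [prediction_matrix()] of interaction scores.
#' @export
ddigip_predict <- function(Y, features = NULL, params = ddigip_params(),
                           feature_sim = NULL) {
  stopifnot(inherits(params, "ddigip_params"))
  validate_interaction_matrix(Y)
  if (params$knn_enabled && (!is.null(features) || !is.null(feature_sim))) {
    S <- feature_sim %||% pearson_similarity(features)
    if (!identical(drug_ids(Y), drug_ids(S))) {
      ddigip_abort("features must be aligned to the interaction matrix (see align_drug_data)",
                   "index_mismatch")
    }
    Y <- knn_fill(Y, S, params$k_neighbors)
  }
  G <- gip_kernel(Y, params$gamma_prime)
  rls_scores(G, Y, params$sigma)
}
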