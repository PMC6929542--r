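# Drug-drug similarity: the Gaussian interaction profile (GIP) kernel on
# interaction profiles, and Pearson correlation of binary feature vectors.

#' Gaussian interaction profile (GIP) kernel of drugs
#'
#' Computes `G[i, j] = exp(-gamma_d * ||yd_i - yd_j||^2)` where `yd_i` is
#' the interaction profile (row i) of the DDI matrix `Y` and the bandwidth
#' is normalized by the mean squared profile norm:
#' `gamma_d = gamma_prime / mean_i(||yd_i||^2)`. The normalization makes the
#' kernel scale-free in `Y`. The mean runs over all drugs, including
#' all-zero rows. The kernel is well-defined for real-valued (KNN-filled)
#' profiles, not only binary ones.
#'
#' @param Y an [interaction_matrix()] (symmetric, zero diagonal) with at
#'   least one nonzero entry.
#' @param gamma_prime bandwidth multiplier, > 0; default 1.
#' @return a [kernel_matrix()] of kind `"gip"`: symmetric, unit diagonal,
#'   entries in (0, 1].
#' @export
gip_kernel <- function(Y, gamma_prime = 1) {
  validate_interaction_matrix(Y)
  stopifnot_scalar_number(gamma_prime, "gamma_prime", positive = TRUE)
  m <- as_plain_matrix(Y)
  if (any(!is.finite(m))) {
    ddigip_abort("interaction matrix has non-finite entries", "non_finite")
  }
  sq_norms <- rowSums(m^2)
  mean_norm <- mean(sq_norms)
  if (mean_norm == 0) {
    ddigip_abort("degenerate network: no known interactions, GIP bandwidth undefined",
                 "degenerate_network")
  }
  gamma_d <- gamma_prime / mean_norm
  # squared profile distances ||yd_i - yd_j||^2 via the Gram matrix
  gram <- tcrossprod(m)
  d2 <- outer(sq_norms, sq_norms, "+") - 2 * gram
  d2[d2 < 0] <- 0  # clamp tiny negatives from cancellation
  G <- exp(-gamma_d * d2)
  G <- (G + t(G)) / 2
  diag(G) <- 1
  kernel_matrix(G, drug_ids(Y), kind = "gip")
}

#' Pearson feature similarity of drugs
#'
#' Correlates each pair of binary feature vectors across the F feature
#' positions. Drugs with a constant vector (all-0 or all-1) have undefined
#' correlation; their rows, columns and diagonal entries are set to 0 and
#' the drug is flagged `degenerate` so that KNN cold-start skips it rather
#' than imputing from no evidence. Drugs flagged feature-`missing` by
#' [align_drug_data()] are treated the same way.
#'
#' @param V a [feature_matrix()] with at least 2 drugs and 2 features.
#' @return a [kernel_matrix()] of kind `"pearson"`, entries in \[-1, 1\].
#' @export
pearson_similarity <- function(V) {
  validate_feature_matrix(V)
  if (ncol(V) < 2L) {
    ddigip_abort("Pearson similarity needs >= 2 feature positions",
                 "too_few_features")
  }
  if (nrow(V) < 2L) {
    ddigip_abort("Pearson similarity needs >= 2 drugs", "too_few_drugs")
  }
  m <- as_plain_matrix(V)
  sds <- apply(m, 1, stats::sd)
  degenerate <- (sds == 0) | (attr(V, "missing") %||% rep(FALSE, nrow(m)))
  S <- suppressWarnings(stats::cor(t(m)))
  S[degenerate, ] <- 0
  S[, degenerate] <- 0
  S[!is.finite(S)] <- 0
  S <- (S + t(S)) / 2
  ok <- !degenerate
  diag(S)[ok] <- 1
  names(degenerate) <- rownames(m)
  kernel_matrix(S, drug_ids(V), kind = "pearson", degenerate = degenerate)
}
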