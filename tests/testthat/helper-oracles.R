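# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (explicit inverses, two-pass statistics,
# threshold sweeps) and share no code with the implementation paths they
# check.

# AUC by brute-force ROC threshold sweep with trapezoidal integration.
oracle_auc_sweep <- function(pos, neg) {
  thr <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Pearson correlation by explicit two-pass covariance / SD computation.
oracle_pearson <- function(V) {
  n <- nrow(V)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      vi <- V[i, ] - mean(V[i, ])
      vj <- V[j, ] - mean(V[j, ])
      S[i, j] <- sum(vi * vj) / sqrt(sum(vi^2) * sum(vj^2))
    }
  }
  S
}

# RLS scoring with an explicitly formed matrix inverse.
oracle_rls <- function(G, Y, sigma) {
  Yhat <- G %*% solve(G + sigma * diag(nrow(G))) %*% Y
  (Yhat + t(Yhat)) / 2
}

# GIP kernel by scalar evaluation of the defining formulas, entry by entry.
oracle_gip <- function(Y, gamma_prime = 1) {
  n <- nrow(Y)
  gamma_d <- gamma_prime / mean(rowSums(Y^2))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      G[i, j] <- exp(-gamma_d * sum((Y[i, ] - Y[j, ])^2))
    }
  }
  G
}

# Random symmetric binary interaction matrix with >= 1 edge.
random_interactions <- function(n, p = 0.3) {
  repeat {
    m <- matrix(0, n, n)
    ut <- which(upper.tri(m))
    m[ut] <- stats::rbinom(length(ut), 1, p)
    m <- m + t(m)
    if (any(m == 1)) break
  }
  interaction_matrix(m, sprintf("d%02d", seq_len(n)), binary = TRUE)
}

# Random PSD kernel with unit diagonal and entries in (0, 1]: a Gaussian
# kernel over random points, i.e. the same shape a GIP kernel takes.
random_psd_kernel <- function(n, d = 4) {
  X <- matrix(stats::rnorm(n * d), n, d)
  D2 <- as.matrix(stats::dist(X))^2
  K <- exp(-D2 / stats::median(D2[D2 > 0]))
  K <- (K + t(K)) / 2
  diag(K) <- 1
  K
}

# The two-drug worked example: single known interaction between A and B.
two_drug_network <- function() {
  interaction_matrix(matrix(c(0, 1, 1, 0), 2, 2), c("A", "B"), binary = TRUE)
}

tmp_text_file <- function(lines, ext = ".csv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
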