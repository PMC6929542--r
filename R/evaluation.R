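# Evaluation protocols: repeated k-fold cross-validation over known
# interaction pairs, de novo (leave-one-drug-out) validation, rank-based
# AUC, and the K grid search.

#' Partition known interaction pairs into cross-validation folds
#'
#' The unordered known pairs (i < j with `Y[i, j] = 1`) are partitioned
#' uniformly at random into `n_folds` near-equal folds (sizes differ by at
#' most 1), independently for each repeat, reproducibly from `seed`.
#' Partitioning over unordered pairs — not matrix cells — guarantees a test
#' edge can never leak into training via its mirror cell.
#'
#' @param Y a binary [interaction_matrix()] with at least `n_folds` known
#'   pairs.
#' @param n_folds number of folds, >= 2.
#' @param repeats number of independent repeats; default 1.
#' @param seed integer RNG seed.
#' @return a `ddigip_fold_plan`: the pair list plus a pairs-by-repeats fold
#'   assignment matrix.
#' @export
make_folds <- function(Y, n_folds, repeats = 1L, seed = 1L) {
  validate_interaction_matrix(Y)
  if (!is.numeric(n_folds) || n_folds < 2) {
    ddigip_abort("`n_folds` must be >= 2", "invalid_parameter")
  }
  m <- as_plain_matrix(Y)
  ut <- which(upper.tri(m) & m == 1, arr.ind = TRUE)
  n_pairs <- nrow(ut)
  if (n_pairs < n_folds) {
    ddigip_abort(sprintf("only %d known pairs but %d folds requested",
                         n_pairs, n_folds), "too_few_pairs")
  }
  assignment <- with_seed(seed, {
    vapply(seq_len(repeats), function(r) {
      sample(rep(seq_len(n_folds), length.out = n_pairs))
    }, integer(n_pairs))
  })
  structure(list(
    n_folds = as.integer(n_folds),
    repeats = as.integer(repeats),
    seed = as.integer(seed),
    pairs = data.frame(i = ut[, 1], j = ut[, 2],
                       drug_id_1 = drug_ids(Y)[ut[, 1]],
                       drug_id_2 = drug_ids(Y)[ut[, 2]],
                       stringsAsFactors = FALSE),
    assignment = matrix(assignment, nrow = n_pairs, ncol = repeats)
  ), class = "ddigip_fold_plan")
}

#' Rank-based AUC (Wilcoxon-Mann-Whitney statistic)
#'
#' `P(score_pos > score_neg) + 0.5 * P(tie)`, computed from midranks; equal
#' to the area under the ROC curve built from all rank thresholds.
#'
#' @param pos_scores scores of true (positive) pairs; non-empty.
#' @param neg_scores scores of candidate (negative) pairs; non-empty.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    ddigip_abort("both score lists must be non-empty", "empty_scores")
  }
  if (any(!is.finite(c(pos_scores, neg_scores)))) {
    ddigip_abort("scores must be finite", "non_finite")
  }
  np <- length(pos_scores)
  nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

eval_report <- function(protocol, aucs, params, seed = NULL, extra = list()) {
  structure(c(list(
    protocol = protocol,
    auc_per_fold = aucs,
    auc_mean = mean(aucs),
    auc_sd = if (length(aucs) > 1L) stats::sd(aucs) else NA_real_,
    params = params,
    seed = seed
  ), extra), class = "ddigip_eval")
}

#' @export
print.ddigip_eval <- function(x, ...) {
  cat(sprintf("<ddigip_eval> protocol=%s  AUC mean=%.4f sd=%s  (%d folds)\n",
              x$protocol, x$auc_mean,
              ifelse(is.na(x$auc_sd), "NA", sprintf("%.4f", x$auc_sd)),
              length(x$auc_per_fold)))
  if (!is.null(x$pooled_auc)) cat(sprintf("  pooled AUC = %.4f\n", x$pooled_auc))
  invisible(x)
}

#' Repeated k-fold cross-validation of the DDIGIP predictor
#'
#' For each repeat and fold: zero BOTH symmetric cells of every test pair
#' to form the training matrix, re-run the full predictor on it (the GIP
#' kernel and any KNN fill are recomputed from the masked matrix), then
#' score test pairs against the candidate universe — all unordered pairs
#' that are 0 in the ORIGINAL matrix. Training positives appear on neither
#' side of the ranking. AUC is computed per fold and aggregated as
#' mean +/- SD across repeats x folds.
#'
#' @param Y a binary [interaction_matrix()].
#' @param features optional aligned [feature_matrix()] enabling cold-start
#'   fill inside folds (a drug whose edges all fall in the test fold
#'   becomes "new" and is imputed).
#' @param params a [ddigip_params()].
#' @param plan a fold plan from [make_folds()] built from `Y`.
#' @param predictor scoring function `(Y, features, params, feature_sim)`
#'   returning a [prediction_matrix()]; default [ddigip_predict()]. Exposed
#'   so harness tests can instrument the masking or substitute oracles.
#' @return a `ddigip_eval` report with per-fold AUCs, mean and SD.
#' @export
cross_validate <- function(Y, features = NULL, params = ddigip_params(),
                           plan = make_folds(Y, 5L),
                           predictor = ddigip_predict) {
  validate_interaction_matrix(Y)
  stopifnot(inherits(plan, "ddigip_fold_plan"))
  m <- as_plain_matrix(Y)
  ids <- drug_ids(Y)
  S <- if (!is.null(features) && params$knn_enabled) {
    pearson_similarity(features)
  } else NULL
  neg_idx <- which(upper.tri(m) & m == 0)
  pair_cells <- cbind(plan$pairs$i, plan$pairs$j)

  aucs <- numeric(0)
  labels <- character(0)
  for (r in seq_len(plan$repeats)) {
    fold_of <- plan$assignment[, r]
    for (f in seq_len(plan$n_folds)) {
      test <- which(fold_of == f)
      Ytr <- m
      Ytr[pair_cells[test, , drop = FALSE]] <- 0
      Ytr[pair_cells[test, c(2, 1), drop = FALSE]] <- 0
      if (all(Ytr == 0)) {
        ddigip_abort(sprintf("removing fold %d (repeat %d) empties the network",
                             f, r), "degenerate_network")
      }
      pred <- predictor(interaction_matrix(Ytr, ids, binary = TRUE),
                        features, params, S)
      p <- as_plain_matrix(pred)
      pos <- p[pair_cells[test, , drop = FALSE]]
      neg <- p[neg_idx]
      aucs <- c(aucs, auc_rank(pos, neg))
      labels <- c(labels, sprintf("rep%d_fold%d", r, f))
    }
  }
  names(aucs) <- labels
  eval_report(sprintf("cv%d", plan$n_folds), aucs, params, seed = plan$seed,
              extra = list(n_folds = plan$n_folds, repeats = plan$repeats))
}

#' De novo (leave-one-drug-out) validation
#'
#' For each drug with at least one known interaction, in turn: zero its
#' entire row and column, re-run the predictor (the KNN fill treats the
#' drug as new and imputes its row from feature similarity), and rank its
#' true partners (positives) against its non-partners (negatives). Reports
#' per-drug AUCs (mean +/- SD) plus one pooled AUC over all drugs' scores
#' combined. Drugs with missing or degenerate features are skipped with a
#' warning and listed in the report.
#'
#' @param Y a binary [interaction_matrix()].
#' @param features aligned [feature_matrix()]; required (cold start needs
#'   features).
#' @param params a [ddigip_params()]. With `knn_enabled = FALSE` the fill
#'   is skipped, which serves as the no-cold-start baseline.
#' @param predictor see [cross_validate()].
#' @return a `ddigip_eval` report with fields `per_drug`, `pooled_auc`,
#'   `skipped`.
#' @export
denovo_validate <- function(Y, features, params = ddigip_params(),
                            predictor = ddigip_predict) {
  validate_interaction_matrix(Y)
  if (is.null(features)) {
    ddigip_abort("de novo validation requires a feature matrix", "missing_features")
  }
  validate_feature_matrix(features)
  if (!identical(drug_ids(Y), drug_ids(features))) {
    ddigip_abort("features must be aligned to the interaction matrix", "index_mismatch")
  }
  m <- as_plain_matrix(Y)
  ids <- drug_ids(Y)
  S <- pearson_similarity(features)
  degenerate <- attr(S, "degenerate")
  degree <- rowSums(m)
  targets <- which(degree > 0)

  per_drug <- numeric(0)
  skipped <- character(0)
  all_pos <- numeric(0)
  all_neg <- numeric(0)
  for (i in targets) {
    if (degenerate[i]) {
      ddigip_warn(sprintf("drug %s skipped: features missing or degenerate", ids[i]),
                  "skipped_drug")
      skipped <- c(skipped, ids[i])
      next
    }
    Ytr <- m
    Ytr[i, ] <- 0
    Ytr[, i] <- 0
    pred <- predictor(interaction_matrix(Ytr, ids, binary = TRUE),
                      features, params, S)
    p <- as_plain_matrix(pred)
    pos <- p[i, m[i, ] == 1]
    neg <- p[i, m[i, ] == 0 & seq_len(ncol(m)) != i]
    per_drug <- c(per_drug, stats::setNames(auc_rank(pos, neg), ids[i]))
    all_pos <- c(all_pos, pos)
    all_neg <- c(all_neg, neg)
  }
  if (!length(per_drug)) {
    ddigip_abort("no drug could be evaluated de novo", "no_evaluable_drug")
  }
  eval_report("denovo", per_drug, params,
              extra = list(pooled_auc = auc_rank(all_pos, all_neg),
                           per_drug = data.frame(drug_id = names(per_drug),
                                                 auc = unname(per_drug),
                                                 stringsAsFactors = FALSE),
                           skipped = skipped))
}

#' Grid search over the number of KNN neighbours K
#'
#' Runs [denovo_validate()] for each candidate K (duplicates removed) and
#' returns the pooled-AUC curve with the argmax.
#'
#' @param Y a binary [interaction_matrix()].
#' @param features aligned [feature_matrix()].
#' @param params a [ddigip_params()]; its `k_neighbors` field is overridden
#'   by each grid value.
#' @param k_values non-empty vector of candidate K values.
#' @return a data frame `k`, `pooled_auc`, `mean_auc` with attribute
#'   `best_k` (smallest K attaining the maximal pooled AUC).
#' @export
grid_search_k <- function(Y, features, params = ddigip_params(),
                          k_values = 1:15) {
  if (!length(k_values)) {
    ddigip_abort("`k_values` must be non-empty", "invalid_parameter")
  }
  ks <- sort(unique(as.integer(k_values)))
  rows <- lapply(ks, function(k) {
    p <- params
    p$k_neighbors <- k
    rep_k <- denovo_validate(Y, features, p)
    data.frame(k = k, pooled_auc = rep_k$pooled_auc, mean_auc = rep_k$auc_mean)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_k") <- out$k[which.max(out$pooled_auc)]
  out
}
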