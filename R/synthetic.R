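# Synthetic benchmark generator. Emulates the statistical structure the
# predictor assumes: drugs fall into latent groups, pairs from compatible
# groups interact much more often than background, and binary feature
# vectors are noisy copies of a group prototype — so feature similarity is
# informative of shared interaction structure.

#' Configuration of the synthetic DDI benchmark generator
#'
#' Defaults are sized so that a full repeated 5-fold cross-validation and a
#' de novo sweep run in seconds on one CPU while leaving clear group
#' structure for the predictor to recover.
#'
#' @param n_drugs number of drugs; default 120.
#' @param n_groups number of latent groups; default 6.
#' @param p_in interaction probability for pairs whose groups are
#'   compatible; default 0.35.
#' @param p_out background interaction probability; default 0.02.
#' @param n_features number of binary feature bits; default 300.
#' @param proto_density probability a group-prototype bit is 1; default 0.2.
#' @param flip_prob per-bit noise probability when copying the prototype to
#'   a drug; 0 gives identical within-group features, 0.5 destroys all
#'   feature signal; default 0.05.
#' @param seed integer RNG seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_drugs = 120L, n_groups = 6L, p_in = 0.35,
                         p_out = 0.02, n_features = 300L,
                         proto_density = 0.2, flip_prob = 0.05, seed = 1L) {
  if (n_groups > n_drugs) {
    ddigip_abort("`n_groups` must not exceed `n_drugs`", "invalid_parameter")
  }
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1)) {
    ddigip_abort("need 0 <= p_out <= p_in <= 1", "invalid_parameter")
  }
  if (flip_prob < 0 || flip_prob > 0.5) {
    ddigip_abort("`flip_prob` must lie in [0, 0.5]", "invalid_parameter")
  }
  structure(list(n_drugs = as.integer(n_drugs), n_groups = as.integer(n_groups),
                 p_in = p_in, p_out = p_out, n_features = as.integer(n_features),
                 proto_density = proto_density, flip_prob = flip_prob,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic DDI network with informative drug features
#'
#' Procedure: (1) each drug draws a group uniformly; (2) each group is
#' compatible with itself and one randomly chosen partner group (the
#' relation is symmetrized); (3) each unordered drug pair interacts with
#' probability `p_in` if its groups are compatible, else `p_out`; (4) each
#' group draws a prototype bit vector with density `proto_density` and each
#' drug copies its group's prototype with independent per-bit flips at
#' `flip_prob`. Compatibility — rather than pure within-group assortativity
#' — makes interaction PROFILES (partner sets), not mere co-membership,
#' carry the signal, which is exactly the structure the GIP kernel uses.
#'
#' @param config a [synth_config()].
#' @return list with `interactions` (binary [interaction_matrix()]),
#'   `features` ([feature_matrix()]), and `truth` (latent group assignment,
#'   group partner map, and the full compatibility matrix).
#' @export
generate_ddi_data <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    n <- config$n_drugs
    g <- config$n_groups
    ids <- sprintf("D%04d", seq_len(n))
    groups <- sample.int(g, n, replace = TRUE)

    partner <- vapply(seq_len(g), function(k) {
      if (g == 1L) 1L else sample(setdiff(seq_len(g), k), 1L)
    }, integer(1))
    compat <- diag(g) > 0
    for (k in seq_len(g)) {
      compat[k, partner[k]] <- TRUE
      compat[partner[k], k] <- TRUE
    }

    Y <- matrix(0, n, n)
    ut <- which(upper.tri(Y), arr.ind = TRUE)
    pr <- ifelse(compat[cbind(groups[ut[, 1]], groups[ut[, 2]])],
                 config$p_in, config$p_out)
    edge <- stats::rbinom(nrow(ut), 1L, pr)
    Y[ut] <- edge
    Y[ut[, c(2, 1)]] <- edge

    proto <- matrix(stats::rbinom(g * config$n_features, 1L, config$proto_density),
                    g, config$n_features)
    V <- proto[groups, , drop = FALSE]
    flips <- matrix(stats::rbinom(n * config$n_features, 1L, config$flip_prob),
                    n, config$n_features)
    V <- abs(V - flips)  # XOR with the noise mask

    list(
      interactions = interaction_matrix(Y, ids, binary = TRUE),
      features = feature_matrix(V, ids = ids,
                                feature_names = sprintf("f%04d", seq_len(config$n_features))),
      truth = list(groups = stats::setNames(groups, ids),
                   partner = partner, compat = compat,
                   config = config)
    )
  })
}

#' Hold out one drug as a "new" drug
#'
#' Returns a copy of the network with the drug's row and column zeroed plus
#' the list of removed pairs — the fixture for single-drug cold-start
#' experiments.
#'
#' @param Y a binary [interaction_matrix()].
#' @param drug identifier of a drug with at least one known interaction.
#' @return list with `interactions` (masked copy) and `held_pairs` (data
#'   frame of removed pairs).
#' @export
holdout_new_drug <- function(Y, drug) {
  validate_interaction_matrix(Y)
  ids <- drug_ids(Y)
  if (!drug %in% ids) {
    ddigip_abort(sprintf("unknown drug: %s", drug), "unknown_drug")
  }
  m <- as_plain_matrix(Y)
  i <- match(drug, ids)
  partners <- which(m[i, ] != 0)
  if (!length(partners)) {
    ddigip_abort(sprintf("drug %s has no known interactions to hold out", drug),
                 "no_interactions")
  }
  m[i, ] <- 0
  m[, i] <- 0
  list(interactions = interaction_matrix(m, ids, binary = attr(Y, "binary")),
       held_pairs = data.frame(drug_id_1 = pmin(drug, ids[partners]),
                               drug_id_2 = pmax(drug, ids[partners]),
                               stringsAsFactors = FALSE))
}
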