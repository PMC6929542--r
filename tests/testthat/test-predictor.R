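make_fill_fixture <- function() {
  # n1 is a new drug (no edges); a and b are its candidate neighbours
  # (both eligible: a-t and a-b are known edges); t is the probe partner.
  # y[a, t] = 1, y[b, t] = 0, so the K=2 fill at (n1, t) is 0.8/(0.8+0.2).
  ids <- c("a", "b", "n1", "t")
  Y <- matrix(0, 4, 4, dimnames = list(ids, ids))
  Y["a", "t"] <- Y["t", "a"] <- 1
  Y["a", "b"] <- Y["b", "a"] <- 1
  S <- diag(4)
  dimnames(S) <- list(ids, ids)
  S["n1", "a"] <- S["a", "n1"] <- 0.8
  S["n1", "b"] <- S["b", "n1"] <- 0.2
  S["n1", "t"] <- S["t", "n1"] <- 0.05
  list(Y = interaction_matrix(Y, ids, binary = TRUE),
       S = kernel_matrix(S, ids, kind = "pearson"))
}

test_that("knn_fill computes similarity-weighted neighbour averages", {
  fx <- make_fill_fixture()
  # K=1: single neighbour a (S=0.8), weights cancel -> copy of a's profile
  Y1 <- knn_fill(fx$Y, fx$S, K = 1)
  expect_equal(Y1["n1", "t"], 1)
  expect_equal(Y1["t", "n1"], 1)  # symmetric write
  # K=2: neighbours a (0.8, y_at=1) and b (0.2, y_bt=0)
  Y2 <- knn_fill(fx$Y, fx$S, K = 2)
  expect_equal(Y2["n1", "t"], 0.8 * 1 / (0.8 + 0.2))
  # rows of drugs with known interactions are untouched except at the
  # filled drug's column, where the symmetric write lands
  keep <- setdiff(drug_ids(fx$Y), "n1")
  expect_identical(unclass(Y2)["a", keep], unclass(fx$Y)["a", keep])
  expect_equal(diag(unclass(Y2)), setNames(rep(0, 4), drug_ids(fx$Y)))
})

test_that("knn_fill warns when neighbours are scarce or weights degenerate", {
  fx <- make_fill_fixture()
  expect_warning(Y9 <- knn_fill(fx$Y, fx$S, K = 9),
                 class = "ddigip_warning_few_neighbors")
  expect_gt(Y9["n1", "t"], 0)

  # all-negative similarity to every eligible neighbour: row left zero
  ids <- drug_ids(fx$Y)
  Sneg <- unclass(fx$S)[, ]
  Sneg["n1", ] <- -0.5; Sneg[, "n1"] <- -0.5; Sneg["n1", "n1"] <- 1
  Sneg <- kernel_matrix(Sneg, ids, kind = "pearson")
  expect_warning(Yn <- knn_fill(fx$Y, Sneg, K = 2),
                 class = "ddigip_warning_undefined_fill")
  expect_true(all(unclass(Yn)["n1", ] == 0))
})

test_that("knn_fill skips feature-degenerate drugs and bounds filled values", {
  fx <- make_fill_fixture()
  ids <- drug_ids(fx$Y)
  deg <- setNames(c(FALSE, FALSE, TRUE, FALSE), ids)
  Sdeg <- kernel_matrix(unclass(fx$S)[, ], ids, kind = "pearson",
                        degenerate = deg)
  Yd <- knn_fill(fx$Y, Sdeg, K = 2)
  expect_true(all(unclass(Yd)["n1", ] == 0))

  # with positive neighbour similarities, filled entries are convex
  # combinations of {0,1} and stay inside [0,1]
  set.seed(23)
  for (rep in 1:20) {
    n <- 12
    Y <- unclass(random_interactions(n, 0.3))[, ]
    Y[1, ] <- 0; Y[, 1] <- 0
    S <- abs(random_psd_kernel(n))
    ids <- sprintf("d%02d", 1:n)
    out <- knn_fill(interaction_matrix(Y, ids),
                    kernel_matrix(S, ids, kind = "pearson"), K = 4)
    expect_true(all(unclass(out) >= 0 & unclass(out) <= 1))
    validate_interaction_matrix(out)
  }
})

test_that("rls_scores solves the regularized system exactly on closed forms", {
  # G = I, sigma = 1: (I + I)^{-1} halves the labels
  ids <- c("a", "b", "c")
  G <- kernel_matrix(diag(3), ids, kind = "pearson")
  Y <- interaction_matrix(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3), ids)
  expect_equal(unclass(rls_scores(G, Y, 1))[, ], unclass(Y)[, ] / 2,
               ignore_attr = TRUE, tolerance = 1e-12)

  # 2x2 hand inversion: Yp[1,2] = (2 - e^-4) / (4 - e^-4)
  a <- exp(-2)
  G2 <- kernel_matrix(matrix(c(1, a, a, 1), 2, 2), c("A", "B"), kind = "gip")
  Yp <- rls_scores(G2, two_drug_network(), 1)
  expect_equal(Yp["A", "B"], (2 - exp(-4)) / (4 - exp(-4)), tolerance = 1e-12)

  # linear in Y: all-zero labels give all-zero scores
  Y0 <- interaction_matrix(matrix(0, 2, 2), c("A", "B"))
  expect_true(all(unclass(rls_scores(G2, Y0, 1)) == 0))
})

test_that("rls_scores validates sigma and finiteness", {
  G <- kernel_matrix(diag(2), c("A", "B"), kind = "pearson")
  expect_error(rls_scores(G, two_drug_network(), sigma = 0),
               class = "ddigip_error_invalid_parameter")
  expect_error(rls_scores(G, two_drug_network(), sigma = -1),
               class = "ddigip_error_invalid_parameter")
})

test_that("rls_scores agrees with the explicit-inverse oracle", {
  set.seed(29)
  for (rep in 1:40) {
    n <- sample(5:20, 1)
    G <- random_psd_kernel(n)
    ids <- sprintf("d%02d", 1:n)
    Y <- random_interactions(n, 0.3)
    sigma <- runif(1, 0.2, 3)
    got <- unclass(rls_scores(kernel_matrix(G, ids, kind = "gip"),
                              interaction_matrix(unclass(Y)[, ], ids),
                              sigma))[, ]
    want <- oracle_rls(G, unclass(Y)[, ], sigma)
    expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-8)
  }
})

test_that("RLS scoring shrinks: spectral bound and sigma-monotonicity", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    G <- random_psd_kernel(n)
    ids <- sprintf("d%02d", 1:n)
    Y <- random_interactions(n, 0.4)
    K <- kernel_matrix(G, ids, kind = "gip")
    Ym <- interaction_matrix(unclass(Y)[, ], ids)
    # eigenvalues of G (G + sigma I)^-1 lie in [0, 1) for sigma > 0
    H <- G %*% solve(G + diag(n))
    ev <- Re(eigen(H, only.values = TRUE)$values)
    expect_true(all(ev >= -1e-10 & ev < 1))
    f1 <- norm(unclass(rls_scores(K, Ym, 0.5))[, ], "F")
    f2 <- norm(unclass(rls_scores(K, Ym, 2.0))[, ], "F")
    expect_lte(f1, norm(unclass(Y)[, ], "F") + 1e-10)
    expect_lte(f2, f1 + 1e-10)  # stronger regularization shrinks harder
  }
})

test_that("ddigip_predict composes fill, kernel and RLS as specified", {
  # no new drugs, no features: identical to rls(gip(Y), Y)
  set.seed(37)
  Y <- random_interactions(8, 0.5)
  p1 <- ddigip_predict(Y)
  p2 <- rls_scores(gip_kernel(Y), Y, 1)
  expect_equal(unclass(p1)[, ], unclass(p2)[, ], ignore_attr = TRUE)

  # two-drug worked example end-to-end with defaults
  Yp <- ddigip_predict(two_drug_network())
  expect_equal(Yp["A", "B"], (2 - exp(-4)) / (4 - exp(-4)), tolerance = 1e-9)

  # all-zero network without the cold-start path is degenerate
  empty <- interaction_matrix(matrix(0, 3, 3), c("a", "b", "c"))
  expect_error(ddigip_predict(empty), class = "ddigip_error_degenerate_network")
})

test_that("ddigip_predict is equivariant under drug-index permutation", {
  set.seed(41)
  sim <- generate_ddi_data(synth_config(n_drugs = 25, n_features = 60, seed = 5))
  Y <- sim$interactions; V <- sim$features
  params <- ddigip_params(k_neighbors = 3)
  p <- unclass(ddigip_predict(Y, V, params))[, ]
  perm <- sample(nrow(Y))
  ids_p <- drug_ids(Y)[perm]
  Yp <- interaction_matrix(unclass(Y)[perm, perm], ids_p)
  Vp <- feature_matrix(unclass(V)[perm, , drop = FALSE], ids_p)
  pp <- unclass(ddigip_predict(Yp, Vp, params))[, ]
  expect_equal(pp, p[perm, perm], ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("the cold-start fill feeds both the kernel and the label matrix", {
  fx <- make_fill_fixture()
  filled <- knn_fill(fx$Y, fx$S, K = 2)
  manual <- rls_scores(gip_kernel(filled), filled, 1)
  auto <- ddigip_predict(fx$Y, feature_sim = fx$S,
                         params = ddigip_params(k_neighbors = 2))
  expect_equal(unclass(auto)[, ], unclass(manual)[, ], ignore_attr = TRUE)
})
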