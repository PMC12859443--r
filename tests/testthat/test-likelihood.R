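test_that("transition probabilities: identity at t = 0, closed form, stationary limit", {
  mk <- build_model("MK", 2)
  expect_equal(transition_probabilities(mk, 0), diag(3), tolerance = 1e-12)
  # equal-rates 3-state chain under unit mean rate: P_ii(t) = 1/3 + (2/3) e^(-1.5 t)
  for (t in c(0.1, 0.5, 1, 2)) {
    P <- transition_probabilities(mk, t)
    expect_equal(diag(P), rep(1 / 3 + 2 / 3 * exp(-1.5 * t), 3),
                 tolerance = 1e-12)
    expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-10)
    expect_true(all(P >= 0))
  }
  # ergodic limit: every row approaches the stationary frequencies
  m <- random_model("COG", 3, seed = 77)
  Pinf <- transition_probabilities(m, 500)
  for (i in 1:7) expect_equal(Pinf[i, ], m$pi, tolerance = 1e-8,
                              ignore_attr = TRUE)
  expect_error(transition_probabilities(mk, -1), ">= 0")
})

test_that("two-taxon column likelihoods match the closed form", {
  mk <- build_model("MK", 2)
  tr <- two_taxon_tree(0.6, 0.4)      # total path length 1.0
  m <- as_bitvector(matrix(c(0L, 0L), 2, 1, dimnames = list(c("a", "b"), "c1")), 2)
  ll <- log_likelihood(tr, m, mk)
  expect_equal(ll, log((1 / 3) * (1 / 3 + (2 / 3) * exp(-1.5))),
               tolerance = 1e-10)
  # zero-length limit: identical state, both branches ~0 -> Q[s]
  tr0 <- two_taxon_tree(1e-9, 1e-9)
  expect_equal(log_likelihood(tr0, m, mk), log(1 / 3), tolerance = 1e-6)
})

test_that("a fully missing column contributes exactly zero log-likelihood", {
  mk <- build_model("MK", 2)
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.1,c:0.3,d:0.2);")
  m1 <- as_bitvector(matrix(c(0L, 1L, 2L, 0L), 4, 1,
                            dimnames = list(letters[1:4], "c1")), 2)
  both <- as_bitvector(cbind(unclass(m1),
                             c2 = rep(NA_integer_, 4)), 2)
  expect_equal(log_likelihood(tr, both, mk), log_likelihood(tr, m1, mk),
               tolerance = 1e-12)
})

test_that("pruning equals brute-force summation on random small instances", {
  set.seed(99)
  for (rep in 1:20) {
    kind <- sample(c("MK", "GTR", "COGs", "COG"), 1)
    kappa <- sample(2:3, 1)
    model <- random_model(kind, kappa, seed = 300 + rep)
    ntaxa <- sample(3:5, 1)
    tr <- random_tree(ntaxa, 0.3, seed = 400 + rep)
    sim <- simulate_matrix(tr, model, 3, missing_prob = 0.2, seed = 500 + rep)
    expect_equal(log_likelihood(tr, sim, model), brute_loglik(tr, sim, model),
                 tolerance = 1e-10)
  }
})

test_that("likelihood is invariant under re-rooting and column permutation; compression is exact", {
  model <- random_model("COG", 3, seed = 13)
  tr <- random_tree(7, 0.2, seed = 14)
  sim <- simulate_matrix(tr, model, 40, 0.1, seed = 15)
  ll <- log_likelihood(tr, sim, model)
  rooted <- ape::root(tr, outgroup = "t3", resolve.root = TRUE)
  expect_equal(log_likelihood(rooted, sim, model), ll, tolerance = 1e-9)
  perm <- subset_columns(sim, sample(ncol(sim)))
  expect_equal(log_likelihood(tr, perm, model), ll, tolerance = 1e-10)
  expect_equal(log_likelihood(tr, sim, model, compress = FALSE), ll,
               tolerance = 1e-10)
})

test_that("likelihood input validation: taxa and symbol mismatches", {
  model <- build_model("MK", 2)
  tr <- random_tree(4, 0.2, seed = 1)
  sim <- simulate_matrix(tr, model, 5, 0, seed = 2)
  rownames(sim) <- paste0("x", 1:4)
  expect_error(log_likelihood(tr, sim, model), "taxa")
  sim2 <- simulate_matrix(tr, build_model("MK", 3), 5, 0, seed = 3)
  expect_error(log_likelihood(tr, sim2, model), "kappa")
})

test_that("branch-length optimization recovers the closed-form two-taxon distance", {
  mk <- build_model("MK", 2)
  # 3-state equal-rates chain: P(differ)(t) = (2/3)(1 - e^(-1.5 t)),
  # so the ML distance for a fraction p of differing columns is
  # t = -log(1 - 1.5 p) / 1.5
  n <- 300; ndiff <- 60
  m <- as_bitvector(matrix(c(rep(0L, n), rep(0L, n - ndiff), rep(1L, ndiff)),
                           2, n, byrow = TRUE,
                           dimnames = list(c("a", "b"), NULL)), 2)
  colnames(m) <- paste0("c", 1:n)
  fit <- optimize_branch_lengths(two_taxon_tree(0.1, 0.1), m, mk)
  t_hat <- sum(fit$edge.length)
  t_closed <- -log(1 - 1.5 * ndiff / n) / 1.5
  expect_equal(t_hat, t_closed, tolerance = 1e-4)
  # identical columns across taxa push the length to the lower bound
  m0 <- subset_columns(m, 1:(n - ndiff))
  fit0 <- optimize_branch_lengths(two_taxon_tree(0.1, 0.1), m0, mk)
  expect_lte(sum(fit0$edge.length), 2.1e-6)
  # already-optimal lengths are a fixed point
  fit2 <- optimize_branch_lengths(fit, m, mk)
  expect_lt(abs(attr(fit2, "loglik") - attr(fit, "loglik")), 1e-6)
})

test_that("branch-length optimization never decreases the likelihood on larger trees", {
  model <- random_model("COGs", 3, seed = 21)
  tr <- random_tree(8, 0.15, seed = 22)
  sim <- simulate_matrix(tr, model, 80, 0.05, seed = 23)
  scrambled <- tr
  scrambled$edge.length <- rep(0.5, nrow(tr$edge))
  ll0 <- log_likelihood(scrambled, sim, model)
  fit <- optimize_branch_lengths(scrambled, sim, model)
  expect_gt(attr(fit, "loglik"), ll0)
  expect_true(all(fit$edge.length >= 1e-6 & fit$edge.length <= 100))
})

test_that("model optimization: MK is a no-op, single-column input converges, recovery works", {
  mk <- build_model("MK", 2)
  tr <- random_tree(5, 0.2, seed = 31)
  sim <- simulate_matrix(tr, mk, 30, 0, seed = 32)
  out <- optimize_model(tr, sim, mk)
  expect_identical(out$model$Q, mk$Q)
  expect_equal(out$loglik, log_likelihood(tr, sim, mk))
  # degenerate single-column input: flat likelihood must not error
  one <- subset_columns(sim, 1)
  cogs <- build_model("COGs", 2)
  expect_no_error(optimize_model(tr, one, cogs))
  # likelihood is non-decreasing against the starting model
  gen <- build_model("COGs", 2, list(pi_nu = c(0.3, 0.05),
                                     lambda_plus = 1, lambda_zero = 0.2))
  sim2 <- simulate_matrix(random_tree(8, 0.15, seed = 33), gen, 300, 0, seed = 34)
  tr2 <- random_tree(8, 0.15, seed = 33)
  fit <- optimize_model(tr2, sim2, build_model("COGs", 2))
  expect_gte(fit$loglik, log_likelihood(tr2, sim2, build_model("COGs", 2)) - 1e-9)
})
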