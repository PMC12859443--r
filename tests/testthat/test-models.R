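test_that("popcount handles strings, vectors and symbol indices", {
  expect_identical(popcount("101"), 2L)
  expect_identical(popcount("000"), 0L)
  expect_identical(popcount("111111"), 6L)
  expect_identical(popcount(c(1, 0, 1, 1)), 3L)
  expect_identical(popcount(0L, kappa = 3), 1L)   # index 0 -> 001
  expect_identical(popcount(6L, kappa = 3), 3L)   # index 6 -> 111
})

test_that("rate classes follow the one-bit / multi-bit rules", {
  # COG: 001 vs 011 differ in one bit, smaller state has size 1
  expect_identical(rate_class(0, 2, "COG", 3), "lambda_1")
  # COG: 001 vs 110 differ in three bits -> structurally zero
  expect_identical(rate_class(0, 5, "COG", 3), "zero")
  # COGs: 01 vs 10 differ in two bits -> lambda_0
  expect_identical(rate_class(0, 1, "COGs", 2), "lambda_0")
  expect_identical(rate_class(0, 1, "MK", 2), "shared")
  expect_identical(rate_class(0, 1, "GTR", 2), rate_class(1, 0, "GTR", 2))
  expect_error(rate_class(2, 2, "COG", 3), "diagonal")
})

test_that("free-parameter counts reproduce the published table", {
  expect_identical(free_parameter_count("GTR", 3), 36L)
  expect_identical(free_parameter_count("MK", 4), 0L)
  expect_identical(free_parameter_count("BIN"), 1L)
  for (k in 2:6) {
    expect_identical(free_parameter_count("COG", k), 2L * k)
    expect_identical(free_parameter_count("COGs", k), k + 1L)
    expect_identical(free_parameter_count("GTR", k),
                     as.integer(2^k * (2^k - 1) / 2 + 2^k))
  }
  # the alternative counting convention stays behind its flag
  expect_identical(free_parameter_count("COGs", 3, convention = "independent"), 3L)
  expect_error(free_parameter_count("GTR"), "kappa")
})

test_that("built models satisfy detailed balance, stationarity and unit mean rate", {
  cases <- expand.grid(kind = c("BIN", "MK", "GTR", "COGs", "COG"),
                       kappa = 2:4, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cases))) {
    m <- random_model(cases$kind[r], cases$kappa[r], seed = 1000 + r)
    flux <- m$pi * m$Q                      # pi_i q(i,j)
    expect_lt(max(abs(flux - t(flux))), 1e-12)
    expect_lt(abs(sum(m$pi * -diag(m$Q)) - 1), 1e-12)
    expect_lt(max(abs(m$pi %*% m$Q)), 1e-10)
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
    expect_true(all(rowSums(m$Q) < 1e-10))
  }
})

test_that("kappa = 3 symmetry layouts: frequencies by popcount, COGs two rates, COG one-bit support", {
  mCOG <- random_model("COG", 3, seed = 5)
  nu <- vapply(0:6, popcount, 0L, kappa = 3)
  # frequencies take exactly 3 distinct values placed by popcount
  expect_identical(length(unique(round(mCOG$pi, 14))), 3L)
  for (v in 1:3)
    expect_identical(length(unique(round(mCOG$pi[nu == v], 14))), 1L)
  mCOGs <- random_model("COGs", 3, seed = 6)
  offs <- mCOGs$exch[upper.tri(mCOGs$exch)]
  expect_lte(length(unique(round(offs, 14))), 2L)
  # COG off-diagonal support is exactly the one-bit-difference pairs
  xorbits <- function(i, j) sum(as.integer(intToBits(bitwXor(i, j))))
  for (i in 1:6) for (j in (i + 1):7) {
    if (xorbits(i, j) > 1) expect_identical(mCOG$Q[i, j], 0)
    else expect_gt(mCOG$Q[i, j], 0)
  }
})

test_that("COG with uniform frequencies and equal lambdas matches MK on the one-bit support", {
  cog <- build_model("COG", 3, list(pi_nu = c(1, 1, 1) / 7, lambda = c(1, 1)))
  mk <- build_model("MK", 3)
  # compare the unnormalized generators (q = lambda * pi_j): identical on
  # one-bit pairs, zero elsewhere for COG
  qc <- cog$Q * cog$scale
  qm <- mk$Q * mk$scale
  xorbits <- function(i, j) sum(as.integer(intToBits(bitwXor(i, j))))
  for (i in 1:6) for (j in (i + 1):7) {
    if (xorbits(i, j) == 1) {
      expect_equal(qc[i, j], qm[i, j], tolerance = 1e-12)
    } else {
      expect_identical(qc[i, j], 0)
    }
  }
})

test_that("COGs with equal rates and uniform frequencies reduces exactly to MK", {
  cogs <- build_model("COGs", 2, list(pi_nu = c(1, 1) / 3,
                                      lambda_plus = 1, lambda_zero = 1))
  mk <- build_model("MK", 2)
  expect_equal(cogs$Q, mk$Q, tolerance = 1e-14)
  expect_equal(cogs$pi, mk$pi, tolerance = 1e-14)
})

test_that("model nesting at the generator level: GTR reproduces COGs and the COG limit", {
  cogs <- random_model("COGs", 3, seed = 31)
  # row-wise upper-triangle extraction
  S <- 7
  rates <- numeric(S * (S - 1) / 2)
  kk <- 0
  for (i in 1:(S - 1)) for (j in (i + 1):S) {
    kk <- kk + 1
    rates[kk] <- cogs$exch[i, j]
  }
  gtr_as_cogs <- build_model("GTR", 3, list(pi = cogs$pi, rates = rates))
  expect_equal(gtr_as_cogs$Q, cogs$Q, tolerance = 1e-12)
  cog <- random_model("COG", 3, seed = 32)
  kk <- 0
  for (i in 1:(S - 1)) for (j in (i + 1):S) {
    kk <- kk + 1
    rates[kk] <- cog$exch[i, j]
  }
  gtr_as_cog <- build_model("GTR", 3, list(pi = cog$pi, rates = rates))
  expect_equal(gtr_as_cog$Q, cog$Q, tolerance = 1e-12)
})

test_that("model construction rejects invalid parameters", {
  expect_error(build_model("COG", 3, list(pi_nu = c(-1, 1, 1))), "positive")
  expect_error(build_model("COG", 3, list(lambda = c(-1, 1))), "negative")
  expect_error(build_model("COG", 7), "kappa")
  expect_error(build_model("GTR", 3, list(rates = rep(1, 5))), "exchangeabilit")
})

test_that("model JSON serialization carries kind, parameters and k", {
  m <- build_model("COG", 3, list(pi_nu = c(0.2, 0.06, 0.02), lambda = c(2, 1)))
  js <- jsonlite::fromJSON(model_to_json(m))
  expect_identical(js$kind, "COG")
  expect_identical(js$kappa, 3L)
  expect_identical(js$k, 6L)
  expect_equal(js$pi_nu, m$pi_nu, tolerance = 1e-12)
})
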