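test_that("inventory takes per-concept unions, sorts classes, drops unattested concepts", {
  ds <- tiny_dataset()
  expect_warning(inv <- build_inventory(ds), "moon")
  expect_identical(inv$concepts, c("hand", "sun", "dog"))
  expect_identical(inv$classes[["hand"]], c("a", "b", "c"))
  expect_identical(unname(inv$kappa), c(3L, 2L, 3L))
})

test_that("binary encoding places 1/0 within attested pairs and dashes whole missing groups", {
  ds <- tiny_dataset()
  suppressWarnings(inv <- build_inventory(ds))
  bm <- encode_binary(ds, inv)
  expect_identical(ncol(bm), sum(inv$kappa))
  # l1 hand = {a,b} over (a,b,c) -> 1 1 0
  expect_identical(unname(bm["l1", attr(bm, "concept") == "hand"]),
                   c("1", "1", "0"))
  # l3 hand = {c} -> 0 0 1
  expect_identical(unname(bm["l3", attr(bm, "concept") == "hand"]),
                   c("0", "0", "1"))
  # l2 has no word for no concept here; construct one: drop l2's dog entry
  tab <- data.frame(language = "l1", concept = "c1", class = c("a", "b"))
  ds2 <- cognate_dataset(c("l1", "l2"), "c1", tab)
  bm2 <- encode_binary(ds2, build_inventory(ds2))
  expect_identical(unname(bm2["l2", ]), c("-", "-"))
})

test_that("state_to_symbol follows the MSB-first pointer formula and inverts exactly", {
  ord <- c("A", "B", "C")
  expect_identical(state_to_symbol("C", ord), 0L)   # 001 -> 1 - 1
  expect_identical(state_to_symbol("A", ord), 3L)   # 100 -> 4 - 1
  expect_identical(state_to_symbol(c("A", "B", "C"), ord), 6L)  # 111 -> 7 - 1
  expect_error(state_to_symbol(character(0), ord), "empty")
  expect_error(state_to_symbol("Z", ord), "outside")
  # bijection over all non-empty subsets, kappa = 2..6
  for (k in 2:6) {
    ordk <- letters[seq_len(k)]
    idx <- vapply(seq_len(2^k - 1), function(n) {
      st <- ordk[as.logical(bitwAnd(n, as.integer(2^((k - 1):0))))]
      state_to_symbol(st, ordk)
    }, 0L)
    expect_setequal(idx, 0:(2^k - 2))
    for (i in 0:(2^k - 2)) {
      st <- symbol_to_state(i, ordk)
      expect_identical(state_to_symbol(st, ordk), i)
    }
    # the all-ones state sits at the top index
    expect_identical(state_to_symbol(ordk, ordk), as.integer(2^k - 2))
  }
})

test_that("kappa partition groups 2..6 and reports exclusions", {
  classes <- list(c1 = c("a", "b"), c2 = c("a", "b", "c"), c3 = c("x", "y"),
                  c4 = "only", c5 = letters[1:7])
  inv <- structure(list(concepts = names(classes), classes = classes,
                        kappa = lengths(classes)),
                   class = "concept_inventory")
  part <- kappa_partition(inv)
  expect_identical(part$subsets[["2"]], c("c1", "c3"))
  expect_identical(part$subsets[["3"]], "c2")
  expect_setequal(part$excluded$concept, c("c4", "c5"))
  # kappa = 6 is admissible (63 symbols fit the 64-symbol alphabet)
  inv6 <- structure(list(concepts = "c", classes = list(c = letters[1:6]),
                         kappa = c(c = 6L)), class = "concept_inventory")
  expect_identical(kappa_partition(inv6)$subsets[["6"]], "c")
})

test_that("bit-vector encoding matches the pointer formula and rejects kappa outside [2, 6]", {
  tab <- data.frame(language = c("l1", "l2", "l2"),
                    concept = "c1", class = c("a", "a", "b"))
  ds <- cognate_dataset(c("l1", "l2", "l3"), "c1", tab)
  inv <- build_inventory(ds)
  bv <- encode_bitvector(ds, inv, 2)
  expect_identical(unclass(bv)[, "c1"], c(l1 = 1L, l2 = 2L, l3 = NA_integer_))
  expect_error(encode_bitvector(ds, inv, 7), "64")
  expect_error(encode_bitvector(ds, inv, 1), "signal")
  expect_error(encode_bitvector(ds, inv, 3), "empty")
})

test_that("binary and bit-vector encodings agree on popcounts per pair", {
  cfg <- simulation_config(n_taxa = 6,
                           concepts_per_kappa = c(`2` = 8, `3` = 8),
                           missing_prob = 0.15, seed = 42)
  ds <- simulate_cognate_dataset(cfg)
  suppressWarnings(inv <- build_inventory(ds))
  bm <- encode_binary(ds, inv)
  for (k in c(2L, 3L)) {
    concepts <- inv$concepts[inv$kappa == k]
    if (length(concepts) == 0) next
    bv <- encode_bitvector(ds, inv, k)
    bv <- subset_columns(bv, intersect(colnames(bv), concepts))
    for (co in colnames(bv)) for (l in rownames(bv)) {
      seg <- bm[l, attr(bm, "concept") == co]
      idx <- unclass(bv)[l, co]
      if (is.na(idx)) expect_true(all(seg == "-"))
      else expect_identical(sum(seg == "1"), popcount(idx, kappa = k))
    }
  }
  # column counts: binary has sum(kappa) columns, bit-vector the subset size
  expect_identical(ncol(bm), sum(inv$kappa))
})

test_that("phylip write/read round trips both dialects and validates symbols", {
  ds <- tiny_dataset()
  suppressWarnings(inv <- build_inventory(ds))
  bm <- encode_binary(ds, inv)
  p1 <- withr::local_tempfile(fileext = ".phy")
  write_phylip(bm, p1)
  back <- read_phylip(p1, "binary")
  expect_identical(as.vector(unclass(back)), as.vector(unclass(bm)))
  expect_identical(rownames(back), rownames(bm))

  # a kappa = 2 matrix with a missing entry
  tab <- data.frame(language = c("l1", "l2", "l2"),
                    concept = "c1", class = c("a", "a", "b"))
  dsm <- cognate_dataset(c("l1", "l2", "l3"), "c1", tab)
  bv <- encode_bitvector(dsm, build_inventory(dsm), 2)
  p2 <- withr::local_tempfile(fileext = ".phy")
  write_phylip(bv, p2)
  bv2 <- read_phylip(p2, "multistate", kappa = 2)
  expect_identical(as.vector(unclass(bv2)), as.vector(unclass(bv)))
  expect_identical(rownames(bv2), rownames(bv))

  # the all-missing entry survives as '-'
  lines <- readLines(p2)
  expect_true(any(grepl("-", lines, fixed = TRUE)))
  # symbol outside the kappa alphabet rejected
  writeLines(c("2 1", "a Z", "b 0"), p2)
  expect_error(read_phylip(p2, "multistate", kappa = 2), "outside")
  # duplicate taxa rejected
  writeLines(c("2 1", "a 0", "a 1"), p2)
  expect_error(read_phylip(p2, "multistate", kappa = 2), "duplicate")
})
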