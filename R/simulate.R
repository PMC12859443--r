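#' Random unrooted tree
#'
#' Uniformly sampled unrooted binary topology with i.i.d. exponential branch
#' lengths. Deterministic given `seed`.
#'
#' @param n_taxa number of taxa (>= 3); tips are labeled `t1..tn`.
#' @param branch_mean mean of the exponential branch-length distribution
#'   (expected substitutions per column).
#' @param seed integer seed.
#' @return an `ape` `phylo` tree.
#' @export
random_tree <- function(n_taxa, branch_mean = 0.1, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  if (n_taxa < 3) stop("a tree needs at least 3 taxa")
  if (branch_mean <= 0) stop("branch_mean must be positive")
  set.seed(as.integer(seed))
  tr <- ape::rtopology(n_taxa, rooted = FALSE,
                       tip.label = paste0("t", seq_len(n_taxa)))
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / branch_mean)
  tr
}

#' Simulate a character matrix under a model
#'
#' Forward simulation of the continuous-time Markov chain: per column a
#' root state is drawn from the stationary frequencies and states are
#' propagated along branches with the transition probabilities `P(t)`.
#' Each tip entry is independently masked to missing with probability
#' `missing_prob` (an exogenous masking process; no mechanistic loss model
#' is implied).
#'
#' @param tree a `phylo` tree with branch lengths.
#' @param model a `subst_model` (kind BIN yields a `binary_matrix` with one
#'   presence/absence column per site; other kinds yield a
#'   `bitvector_matrix`).
#' @param n_columns number of columns (concepts) to simulate.
#' @param missing_prob per-entry missing probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a `bitvector_matrix` (or `binary_matrix` for BIN) with rows in
#'   the tree's tip order; simulated concepts are named `c1..cn` with
#'   concept-scoped class labels (`c7_a`, `c7_b`, ...).
#' @export
simulate_matrix <- function(tree, model, n_columns, missing_prob = 0, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(inherits(model, "subst_model"), n_columns >= 1,
            missing_prob >= 0, missing_prob <= 1)
  set.seed(as.integer(seed))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  edge <- tr$edge
  root <- edge[nrow(edge), 1]
  S <- model$S
  states <- matrix(NA_integer_, max(edge), n_columns)
  states[root, ] <- sample.int(S, n_columns, replace = TRUE, prob = model$pi)
  for (e in rev(seq_len(nrow(edge)))) {   # root-to-tips
    p <- edge[e, 1]; v <- edge[e, 2]
    P <- .pmat(model, tr$edge.length[e])
    sv <- integer(n_columns)
    for (s in seq_len(S)) {
      idx <- which(states[p, ] == s)
      if (length(idx))
        sv[idx] <- sample.int(S, length(idx), replace = TRUE, prob = P[s, ])
    }
    states[v, ] <- sv
  }
  tips <- states[seq_len(ntip), , drop = FALSE]
  if (missing_prob > 0)
    tips[matrix(stats::runif(length(tips)) < missing_prob,
                nrow(tips), ncol(tips))] <- NA_integer_
  rownames(tips) <- tr$tip.label
  colnames(tips) <- paste0("c", seq_len(n_columns))
  if (model$kind == "BIN") {
    ch <- matrix("-", nrow(tips), ncol(tips), dimnames = dimnames(tips))
    ch[!is.na(tips)] <- c("0", "1")[tips[!is.na(tips)]]
    return(structure(ch, concept = colnames(tips),
                     cls = rep("1", ncol(tips)),
                     class = c("binary_matrix", "matrix", "array")))
  }
  kap <- model$kappa
  class_orders <- lapply(colnames(tips), function(co)
    paste0(co, "_", letters[seq_len(kap)]))
  names(class_orders) <- colnames(tips)
  structure(tips - 1L, kappa = kap, class_orders = class_orders,
            alphabet = default_alphabet(),
            class = c("bitvector_matrix", "matrix", "array"))
}

#' Simulation configuration
#'
#' Bundles the settings of [simulate_cognate_dataset()]. The defaults
#' emulate the statistical shape of empirical cognate benchmark data:
#' per-pair state sizes heavily skewed to \eqn{\nu = 1} (strongly
#' decreasing per-size frequencies), small kappa-subsets whose sizes shrink
#' with kappa, a moderate missing-data fraction, and one-bit-change rates
#' that decrease with the smaller state's size.
#'
#' @param n_taxa number of languages (default 16).
#' @param concepts_per_kappa named integer vector: concepts to simulate per
#'   kappa (names "2".."6").
#' @param kind generating model kind for the bit-vector columns (default
#'   `"COG"`).
#' @param params_per_kappa optional named list (names "2".."6") of
#'   parameter lists passed to [build_model()]; defaults per kappa:
#'   `pi_nu` proportional to `12^-(nu-1)` and, for COG, `lambda = 1/nu`.
#' @param missing_prob per-entry missing probability (default 0.1).
#' @param branch_mean mean branch length of the random tree (default 0.1).
#' @param tree optional fixed `phylo` tree (overrides `n_taxa`/`branch_mean`).
#' @param seed mandatory master seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_taxa = 16,
                              concepts_per_kappa = c(`2` = 50, `3` = 30,
                                                     `4` = 20, `5` = 12,
                                                     `6` = 8),
                              kind = "COG", params_per_kappa = NULL,
                              missing_prob = 0.1, branch_mean = 0.1,
                              tree = NULL, seed) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(all(concepts_per_kappa >= 0),
            missing_prob >= 0, missing_prob <= 1)
  kk <- as.integer(names(concepts_per_kappa))
  if (anyNA(kk) || any(kk < 2 | kk > 6))
    stop("concepts_per_kappa must be named by kappa values in [2, 6]")
  structure(list(n_taxa = n_taxa, concepts_per_kappa = concepts_per_kappa,
                 kind = kind, params_per_kappa = params_per_kappa,
                 missing_prob = missing_prob, branch_mean = branch_mean,
                 tree = tree, seed = as.integer(seed)),
            class = "simulation_config")
}

.default_sim_params <- function(kind, kappa) {
  nu <- seq_len(kappa)
  params <- list(pi_nu = 12^-(nu - 1))
  if (kind == "COG") params$lambda <- 1 / seq_len(kappa - 1)
  if (kind == "COGs") { params$lambda_plus <- 1; params$lambda_zero <- 0.1 }
  params
}

#' Simulate a full cognate dataset
#'
#' Simulates bit-vector columns per kappa-subset under the configured model
#' and decodes the symbols back into concept-scoped cognate-class sets,
#' yielding a `cognate_dataset` that the wordlist and encoding modules can
#' round-trip. Missing simulated entries become empty assignments
#' (\eqn{\nu = 0}).
#'
#' @param config a [simulation_config()].
#' @return a `cognate_dataset` with attributes `tree` (the generating tree)
#'   and `matrices` (the simulated `bitvector_matrix` per kappa).
#' @export
simulate_cognate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  subseeds <- sample.int(.Machine$integer.max - 1L,
                         length(config$concepts_per_kappa) + 1L)
  tree <- config$tree
  if (is.null(tree))
    tree <- random_tree(config$n_taxa, config$branch_mean, subseeds[1])
  langs <- tree$tip.label
  matrices <- list()
  all_concepts <- character(0)
  assign_rows <- list()
  cid <- 0L
  for (i in seq_along(config$concepts_per_kappa)) {
    k <- as.integer(names(config$concepts_per_kappa)[i])
    nct <- config$concepts_per_kappa[i]
    if (nct == 0) next
    params <- config$params_per_kappa[[as.character(k)]]
    if (is.null(params)) params <- .default_sim_params(config$kind, k)
    mod <- build_model(config$kind, k, params)
    m <- simulate_matrix(tree, mod, nct, config$missing_prob,
                         seed = subseeds[i + 1L])
    concepts <- paste0("c", cid + seq_len(nct))
    cid <- cid + as.integer(nct)
    colnames(m) <- concepts
    names(attr(m, "class_orders")) <- concepts
    attr(m, "class_orders") <- lapply(concepts, function(co)
      paste0(co, "_", letters[seq_len(k)]))
    names(attr(m, "class_orders")) <- concepts
    matrices[[as.character(k)]] <- m
    all_concepts <- c(all_concepts, concepts)
    for (j in seq_along(concepts)) {
      ord <- attr(m, "class_orders")[[j]]
      for (l in seq_along(langs)) {
        idx <- unclass(m)[l, j]
        assign_rows[[length(assign_rows) + 1L]] <-
          if (is.na(idx)) NULL else data.frame(language = langs[l],
                                               concept = concepts[j],
                                               class = symbol_to_state(idx, ord),
                                               stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, assign_rows)
  ds <- cognate_dataset(langs, all_concepts, tab)
  attr(ds, "tree") <- tree
  attr(ds, "matrices") <- matrices
  ds
}
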