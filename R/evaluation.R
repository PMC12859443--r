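#' Akaike information criterion
#'
#' `AIC = 2k - 2 loglik`; lower is better. Only comparable between fits on
#' the same data representation.
#'
#' @param loglik finite log-likelihood.
#' @param k free-parameter count (non-negative integer).
#' @return numeric AIC score.
#' @export
aic <- function(loglik, k) {
  stopifnot(is.finite(loglik), k >= 0)
  2 * k - 2 * loglik
}

#' Compare substitution models on one matrix
#'
#' Runs a full tree search per model kind (all with the same seed) and
#' tabulates log-likelihood, free-parameter count and AIC. AIC scores are
#' only meaningful within one data representation, so requesting BIN on a
#' bit-vector matrix (or any other kind on a binary matrix) is rejected.
#'
#' @param matrix a `bitvector_matrix` (kinds MK/GTR/COGs/COG) or
#'   `binary_matrix` (kind BIN).
#' @param kinds character vector of model kinds.
#' @param seed master seed shared across kinds.
#' @param ... passed to [run_search()] (e.g. `n_random`, `n_parsimony`,
#'   `control`).
#' @return a `model_comparison`: data.frame with columns `model`, `loglik`,
#'   `k`, `AIC`, ordered as requested; the fits are attached as attribute
#'   `fits`.
#' @export
compare_models <- function(matrix, kinds = c("MK", "GTR", "COGs", "COG"),
                           seed, ...) {
  if (missing(seed)) stop("an explicit seed is required")
  kinds <- match.arg(kinds, c("BIN", "MK", "GTR", "COGs", "COG"),
                     several.ok = TRUE)
  if (inherits(matrix, "bitvector_matrix") && "BIN" %in% kinds)
    stop("BIN results on binary matrices cannot be compared with bit-vector ",
         "models: representations differ")
  if (inherits(matrix, "binary_matrix") && any(kinds != "BIN"))
    stop("only BIN applies to the binary representation")
  fits <- lapply(kinds, function(kind)
    run_search(matrix, kind, seed = seed, ...))
  names(fits) <- kinds
  out <- data.frame(model = kinds,
                    loglik = vapply(fits, `[[`, 0, "loglik"),
                    k = vapply(fits, function(f) f$model$k, 0L),
                    AIC = vapply(fits, `[[`, 0, "aic"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fits") <- fits
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model comparison (lower AIC is better):\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Cross-validation relative error
#'
#' `e = (llh_test_rel - llh_train_rel) / llh_train_rel` with per-column
#' normalized log-likelihoods. Large positive values indicate that the
#' fitted tree and parameters generalize poorly (overfitting /
#' overparameterization).
#'
#' @param llh_train_rel per-column training log-likelihood (negative).
#' @param llh_test_rel per-column test log-likelihood.
#' @return relative error e.
#' @export
relative_error <- function(llh_train_rel, llh_test_rel) {
  (llh_test_rel - llh_train_rel) / llh_train_rel
}

#' Cross-validation overparameterization diagnostic
#'
#' Repeatedly splits the matrix's columns into a training part
#' (`floor(ratio * ncol)` columns, sampled without replacement) and a test
#' part, fits tree and parameters on the training columns with a full
#' search, evaluates the test log-likelihood on the fitted tree and
#' parameters with no re-optimization, and reports the per-fold relative
#' error and its mean. Matrices with fewer than `min_columns` columns are
#' rejected as too small for a meaningful split.
#'
#' @param matrix a `bitvector_matrix` or `binary_matrix`.
#' @param model model kind or built `subst_model`.
#' @param ratio training fraction (default 0.6, a 60:40 split).
#' @param folds number of random splits (default 10).
#' @param min_columns minimum column count (default 10).
#' @param seed master seed; per-fold sub-seeds are derived deterministically.
#' @param n_random,n_parsimony search starts per fold (defaults 10 + 10).
#' @param control search controls, passed to [run_search()].
#' @param force_identical_split if `TRUE` the test set is forced equal to
#'   the training set (a self-consistency check: e is then exactly 0).
#' @return a `crossval_result`: list with `records` (one row per fold:
#'   `fold`, `seed`, `n_train`, `n_test`, `llh_train_rel`, `llh_test_rel`,
#'   `e`) and `mean_e`.
#' @export
crossval <- function(matrix, model, ratio = 0.6, folds = 10,
                     min_columns = 10, seed, n_random = 10, n_parsimony = 10,
                     control = list(), force_identical_split = FALSE) {
  if (missing(seed)) stop("an explicit seed is required")
  nc <- ncol(matrix)
  if (nc < min_columns)
    stop("matrix has ", nc, " columns; fewer than ", min_columns,
         " is too small for cross-validation")
  model0 <- .resolve_model(matrix, model)
  set.seed(as.integer(seed))
  fseeds <- sample.int(.Machine$integer.max - 1L, folds)
  recs <- vector("list", folds)
  for (f in seq_len(folds)) {
    set.seed(fseeds[f])
    train_idx <- sort(sample.int(nc, floor(ratio * nc)))
    test_idx <- if (force_identical_split) train_idx else setdiff(seq_len(nc), train_idx)
    train <- subset_columns(matrix, train_idx)
    test <- subset_columns(matrix, test_idx)
    fit <- run_search(train, model0, n_random = n_random,
                      n_parsimony = n_parsimony, seed = fseeds[f],
                      control = control)
    llh_train_rel <- fit$loglik / ncol(train)
    llh_test <- log_likelihood(fit$tree, test, fit$model)
    llh_test_rel <- llh_test / ncol(test)
    recs[[f]] <- data.frame(fold = f, seed = fseeds[f],
                            n_train = ncol(train), n_test = ncol(test),
                            llh_train_rel = llh_train_rel,
                            llh_test_rel = llh_test_rel,
                            e = relative_error(llh_train_rel, llh_test_rel))
  }
  records <- do.call(rbind, recs)
  structure(list(records = records, mean_e = mean(records$e)),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf("cross-validation over %d folds: mean relative error e = %.4f\n",
              nrow(x$records), x$mean_e))
  print.data.frame(x$records, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Shannon entropy profile of a character matrix
#'
#' Per-column Shannon entropy (log base 2 by default) of the empirical
#' distribution over non-missing symbols, and the total over columns. An
#' all-missing column contributes 0; an entirely missing matrix yields
#' total 0 with a warning.
#'
#' @param matrix a `binary_matrix`, `bitvector_matrix` or plain character
#'   matrix (`-` = missing).
#' @param base logarithm base (default 2: bits).
#' @return an `entropy_profile`: list with `per_column` and `total`.
#' @export
matrix_entropy <- function(matrix, base = 2) {
  ch <- if (is.character(matrix)) {
    m <- matrix; m[is.na(m)] <- "-"; m
  } else .matrix_chars(matrix)
  per <- apply(ch, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return(0)
    p <- table(col) / length(col)
    -sum(p * log(p)) / log(base)
  })
  if (all(ch == "-")) warning("matrix is entirely missing; total entropy is 0")
  structure(list(per_column = as.numeric(per), total = sum(per)),
            class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  cat(sprintf("entropy profile: %d columns, total = %.4f bits\n",
              length(x$per_column), x$total))
  invisible(x)
}

#' Dataset shape diagnostics
#'
#' Profiles the properties that govern whether the bit-vector models are
#' identifiable on a dataset: the distribution of \eqn{\nu} (state sizes,
#' including \eqn{\nu = 0} missing) over all language-concept pairs, the
#' kappa-subset sizes, the per-kappa concepts-over-languages ratio, and the
#' symbol occurrence counts in each kappa-subset's bit-vector matrix.
#'
#' @param dataset a `cognate_dataset`.
#' @param inventory a `concept_inventory` built from the dataset.
#' @return list with `nu_distribution` (named proportions),
#'   `kappa_sizes` (named integer), `concepts_over_languages` (named
#'   numeric) and `symbol_counts` (named list of per-symbol counts, indexed
#'   by the 0-based symbol).
#' @export
dataset_diagnostics <- function(dataset, inventory) {
  stopifnot(inherits(dataset, "cognate_dataset"),
            inherits(inventory, "concept_inventory"))
  nu <- nu_values(dataset)
  nu_dist <- table(factor(nu, levels = 0:max(nu))) / length(nu)
  part <- kappa_partition(inventory)
  sizes <- vapply(part$subsets, length, 0L)
  ratio <- sizes / length(dataset$languages)
  counts <- lapply(names(part$subsets), function(kc) {
    k <- as.integer(kc)
    bv <- encode_bitvector(dataset, inventory, k)
    tab <- table(factor(unclass(bv), levels = 0:(2^k - 2)))
    stats::setNames(as.integer(tab), names(tab))
  })
  names(counts) <- names(part$subsets)
  list(nu_distribution = stats::setNames(as.numeric(nu_dist), names(nu_dist)),
       kappa_sizes = sizes,
       concepts_over_languages = ratio,
       symbol_counts = counts)
}
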