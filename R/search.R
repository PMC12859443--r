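.resolve_model <- function(matrix, model) {
  if (inherits(model, "subst_model")) return(model)
  kind <- match.arg(model, c("BIN", "MK", "GTR", "COGs", "COG"))
  if (inherits(matrix, "binary_matrix")) {
    if (kind != "BIN")
      stop(kind, " requires the bit-vector representation; binary matrices use BIN")
    build_model("BIN")
  } else {
    if (kind == "BIN")
      stop("BIN operates on binary matrices, not on the bit-vector representation")
    build_model(kind, attr(matrix, "kappa"))
  }
}

.admissible_symbols <- function(matrix) {
  if (inherits(matrix, "bitvector_matrix")) {
    attr(matrix, "alphabet")[seq_len(2^attr(matrix, "kappa") - 1)]
  } else c("0", "1")
}

.parsimony_start <- function(matrix, taxa) {
  ch <- .matrix_chars(matrix)
  pd <- phangorn::phyDat(ch, type = "USER",
                         levels = .admissible_symbols(matrix),
                         ambiguity = "-")
  tr <- phangorn::random.addition(pd)
  ape::unroot(tr)
}

.random_start <- function(taxa) {
  ape::rtopology(length(taxa), rooted = FALSE, tip.label = sample(taxa))
}

.hill_climb <- function(tree, data, model, control = list()) {
  ctl <- utils::modifyList(list(tol_outer = 1e-5, bl_tol = 1e-6,
                                bl_rounds = 20, quick_rounds = 2,
                                max_iter = 50, min_bl = 1e-6, max_bl = 100),
                           control)
  free <- length(.pack_params(model)) > 0
  ll <- -Inf
  iters <- 0L
  repeat {
    iters <- iters + 1L
    eng <- .engine(tree, data, model$S)
    b <- .optimize_bl(eng, eng$len, model, tol = ctl$bl_tol,
                      rounds = ctl$bl_rounds, min_bl = ctl$min_bl,
                      max_bl = ctl$max_bl)
    len <- b$len
    ll_new <- b$loglik
    if (free) {
      om <- .optimize_model_core(eng, len, model)
      model <- om$model
      ll_new <- om$loglik
    }
    tree <- eng$tree
    tree$edge.length <- len
    # NNI sweep: evaluate neighbors with a quick branch-length polish
    best_nb <- NULL; best_ll <- ll_new
    if (length(tree$tip.label) > 3) {
      nbs <- phangorn::nni(tree)
      for (i in seq_along(nbs)) {
        engn <- .engine(nbs[[i]], data, model$S)  # [[ restores tip labels
        bn <- .optimize_bl(engn, engn$len, model, tol = ctl$bl_tol,
                           rounds = ctl$quick_rounds, min_bl = ctl$min_bl,
                           max_bl = ctl$max_bl)
        if (bn$loglik > best_ll + 1e-6) {
          best_ll <- bn$loglik
          best_nb <- engn$tree
          best_nb$edge.length <- bn$len
        }
      }
    }
    if (!is.null(best_nb) && iters < ctl$max_iter) {
      tree <- best_nb
      ll <- best_ll
    } else {
      if (ll_new - ll < ctl$tol_outer || iters >= ctl$max_iter) {
        ll <- max(ll, ll_new)
        break
      }
      ll <- ll_new
    }
  }
  list(tree = tree, model = model, loglik = ll, iterations = iters)
}

#' Maximum-likelihood tree search
#'
#' Runs independent hill-climbing searches from random topologies and from
#' randomized stepwise-addition parsimony trees (defaults 10 + 10,
#' mirroring the standard search configuration), and returns the start with
#' the best final log-likelihood. Each start alternates branch-length
#' optimization, model-parameter optimization and a nearest-neighbor
#' interchange sweep until no improving move remains. Deterministic given
#' `seed`; ties between equally likely starts are broken by the earliest
#' start index.
#'
#' @param matrix a `binary_matrix` or `bitvector_matrix` with at least 4 taxa.
#' @param model a model kind string (`"BIN"`, `"MK"`, `"GTR"`, `"COGs"`,
#'   `"COG"`) or a built `subst_model` used as the starting point.
#' @param n_random number of random-topology starts.
#' @param n_parsimony number of randomized-addition parsimony starts.
#' @param seed master seed (mandatory); per-start sub-seeds are derived
#'   deterministically.
#' @param control list of search controls (see `.hill_climb` defaults):
#'   `tol_outer`, `bl_tol`, `bl_rounds`, `quick_rounds`, `max_iter`,
#'   `min_bl`, `max_bl`.
#' @return a `cogvec_fit`: list with `tree`, `model`, `loglik`,
#'   `aic` (`2k - 2 loglik` with the model's Table-style k), and `starts`
#'   (per-start table with type, sub-seed and final log-likelihood).
#' @examples
#' \donttest{
#' tr <- random_tree(6, 0.15, seed = 1)
#' m <- simulate_matrix(tr, build_model("MK", 2), 50, 0.05, seed = 2)
#' fit <- run_search(m, "MK", n_random = 2, n_parsimony = 2, seed = 3)
#' fit$loglik
#' }
#' @export
run_search <- function(matrix, model, n_random = 10, n_parsimony = 10,
                       seed, control = list()) {
  if (missing(seed)) stop("an explicit seed is required")
  model0 <- .resolve_model(matrix, model)
  taxa <- rownames(matrix)
  if (length(taxa) < 4) stop("tree search requires at least 4 taxa")
  n_starts <- n_random + n_parsimony
  if (n_starts < 1) stop("at least one search start is required")
  data <- .pattern_data(matrix, model0)
  set.seed(as.integer(seed))
  sseeds <- sample.int(.Machine$integer.max - 1L, n_starts)
  fits <- vector("list", n_starts)
  types <- rep(c("random", "parsimony"), c(n_random, n_parsimony))
  for (i in seq_len(n_starts)) {
    set.seed(sseeds[i])
    start_tree <- if (types[i] == "random") .random_start(taxa)
                  else .parsimony_start(matrix, taxa)
    start_tree$edge.length <- rep(0.1, nrow(start_tree$edge))
    fits[[i]] <- .hill_climb(start_tree, data, model0, control)
  }
  lls <- vapply(fits, `[[`, 0, "loglik")
  best <- which.max(lls)           # which.max takes the earliest maximum
  starts <- data.frame(start = seq_len(n_starts), type = types,
                       seed = sseeds, loglik = lls,
                       iterations = vapply(fits, `[[`, 0L, "iterations"))
  out <- fits[[best]]
  structure(list(tree = out$tree, model = out$model, loglik = out$loglik,
                 aic = aic(out$loglik, out$model$k), starts = starts,
                 seed = seed),
            class = "cogvec_fit")
}

#' @export
print.cogvec_fit <- function(x, ...) {
  cat(sprintf("cogvec_fit: %s%s on %d taxa; loglik = %.4f, AIC = %.4f (k = %d)\n",
              x$model$kind,
              if (!is.null(x$model$kappa)) paste0(" (kappa = ", x$model$kappa, ")") else "",
              length(x$tree$tip.label), x$loglik, x$aic, x$model$k))
  cat(sprintf("  %d search starts; best = start %d (%s)\n",
              nrow(x$starts), which.max(x$starts$loglik),
              x$starts$type[which.max(x$starts$loglik)]))
  invisible(x)
}
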