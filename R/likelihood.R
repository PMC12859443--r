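#' Transition probability matrix
#'
#' \eqn{P(t) = \exp(Gt)} for a model's normalized generator, computed from
#' the cached spectral decomposition of the reversible generator. Rows sum
#' to 1 and entries are non-negative (tiny negative round-off is clamped).
#'
#' @param model a `subst_model`.
#' @param t branch length (expected substitutions per column), `t >= 0`.
#' @return an S x S stochastic matrix.
#' @export
transition_probabilities <- function(model, t) {
  stopifnot(inherits(model, "subst_model"))
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  .pmat(model, t)
}

.pmat <- function(model, t) {
  P <- model$eig$V %*% (exp(model$eig$values * t) * model$eig$W)
  P[P < 0] <- 0
  rs <- rowSums(P)
  if (any(!is.finite(rs) | rs <= 0))
    stop("non-finite transition probabilities (degenerate model parameters)")
  P / rs
}

.colmax <- function(M) {
  mx <- M[1, ]
  if (nrow(M) > 1) for (s in 2:nrow(M)) mx <- pmax(mx, M[s, ])
  mx
}

.state_codes <- function(matrix, model) {
  # integer states 1..S, NA = missing, rows = taxa
  if (inherits(matrix, "bitvector_matrix")) {
    if (model$kind == "BIN")
      stop("BIN operates on binary matrices, not on the bit-vector representation")
    kap <- attr(matrix, "kappa")
    if (!is.null(model$kappa) && model$kappa != kap)
      stop("matrix kappa (", kap, ") does not match model kappa (", model$kappa, ")")
    codes <- unclass(matrix) + 1L
    if (any(codes > model$S, na.rm = TRUE))
      stop("symbol index outside the model's state space")
    codes
  } else if (inherits(matrix, "binary_matrix")) {
    if (model$kind != "BIN")
      stop(model$kind, " operates on bit-vector matrices, not on the binary representation")
    ch <- unclass(matrix)
    codes <- matrix(NA_integer_, nrow(ch), ncol(ch), dimnames = dimnames(ch))
    codes[ch == "0"] <- 1L
    codes[ch == "1"] <- 2L
    if (any(is.na(codes) & ch != "-")) stop("binary matrix entries must be 0, 1 or -")
    codes
  } else stop("matrix must be a binary_matrix or bitvector_matrix")
}

.pattern_data <- function(matrix, model, compress = TRUE) {
  codes <- .state_codes(matrix, model)
  taxa <- rownames(codes)
  if (is.null(taxa)) stop("matrix must have taxon row names")
  if (compress && ncol(codes) > 1) {
    key <- apply(codes, 2, paste, collapse = ",")
    ui <- which(!duplicated(key))
    w <- as.numeric(table(factor(key, levels = key[ui])))
    codes <- codes[, ui, drop = FALSE]
  } else {
    w <- rep(1, ncol(codes))
  }
  list(states = codes, w = w, taxa = taxa, ncol_total = sum(w))
}

.tip_partial <- function(states, S) {
  P <- length(states)
  M <- matrix(0, S, P)
  ok <- !is.na(states)
  M[cbind(states[ok], which(ok))] <- 1
  M[, !ok] <- 1
  M
}

.engine <- function(tree, data, S) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  if (!setequal(tr$tip.label, data$taxa))
    stop("tree taxa and matrix taxa differ")
  perm <- match(tr$tip.label, data$taxa)
  states <- data$states[perm, , drop = FALSE]
  list(edge = tr$edge, len = tr$edge.length, ntip = ntip,
       root = tr$edge[nrow(tr$edge), 1], S = S, P = ncol(states),
       w = data$w, tipp = lapply(seq_len(ntip), function(i)
         .tip_partial(states[i, ], S)),
       tree = tr)
}

# Felsenstein pruning over pattern-compressed columns.
# Returns the log-likelihood; with partials = TRUE also the per-node
# conditional likelihood matrices D and their per-pattern log-scales.
.peel <- function(eng, len, model, partials = FALSE) {
  edge <- eng$edge
  nn <- max(edge)
  D <- vector("list", nn)
  sc <- vector("list", nn)
  zero <- rep(0, eng$P)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; v <- edge[e, 2]
    if (v <= eng$ntip) { cl <- eng$tipp[[v]]; scv <- zero }
    else { cl <- D[[v]]; scv <- sc[[v]] }
    contrib <- .pmat(model, len[e]) %*% cl
    if (is.null(D[[p]])) { D[[p]] <- contrib; sc[[p]] <- scv }
    else { D[[p]] <- D[[p]] * contrib; sc[[p]] <- sc[[p]] + scv }
    if (min(D[[p]]) < 1e-200) {      # rare: rescale columns against underflow
      mx <- .colmax(D[[p]])
      mx[mx == 0] <- 1
      D[[p]] <- D[[p]] / rep(mx, each = eng$S)
      sc[[p]] <- sc[[p]] + log(mx)
    }
  }
  lik <- colSums(model$pi * D[[eng$root]])
  ll <- sum(eng$w * (log(lik) + sc[[eng$root]]))
  if (!partials) return(ll)
  list(loglik = ll, D = D, sc = sc)
}

#' Phylogenetic log-likelihood
#'
#' Likelihood of a character matrix on an (unrooted) tree under a
#' substitution model, computed by Felsenstein pruning with per-column
#' pattern compression. Missing entries contribute all-ones conditional
#' vectors, so a fully missing column contributes exactly 0.
#'
#' @param tree an `ape` `phylo` tree with branch lengths; tip labels must
#'   match the matrix's taxa.
#' @param matrix a `binary_matrix` (BIN) or `bitvector_matrix` (other kinds).
#' @param model a `subst_model`.
#' @param compress pattern-compress identical columns (result unchanged).
#' @return log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(tree, matrix, model, compress = TRUE) {
  data <- .pattern_data(matrix, model, compress = compress)
  eng <- .engine(tree, data, model$S)
  .peel(eng, eng$len, model)
}

# One-pass branch-length optimization round: fresh postorder partials, then
# a root-to-tip walk optimizing each branch by Brent on the spectral edge
# likelihood  sum_k exp(mu_k t) * [V'(pi*A)]_k [W D]_k.
.bl_round <- function(eng, len, model, min_bl, max_bl) {
  edge <- eng$edge
  nb <- nrow(edge)
  ch_edges <- split(seq_len(nb), edge[, 1])
  pe <- .peel(eng, len, model, partials = TRUE)
  D <- pe$D; sc <- pe$sc
  V <- model$eig$V; W <- model$eig$W; vals <- model$eig$values
  nn <- max(edge)
  R <- vector("list", nn); scR <- vector("list", nn)
  zero <- rep(0, eng$P)
  R[[eng$root]] <- matrix(1, eng$S, eng$P); scR[[eng$root]] <- zero
  for (e in rev(seq_len(nb))) {
    p <- edge[e, 1]; v <- edge[e, 2]
    A <- R[[p]]; scA <- scR[[p]]
    for (u in setdiff(ch_edges[[as.character(p)]], e)) {
      uu <- edge[u, 2]
      if (uu <= eng$ntip) { clu <- eng$tipp[[uu]]; scu <- zero }
      else { clu <- D[[uu]]; scu <- sc[[uu]] }
      A <- A * (.pmat(model, len[u]) %*% clu)
      scA <- scA + scu
    }
    if (min(A) < 1e-200) {
      mx <- .colmax(A)
      mx[mx == 0] <- 1
      A <- A / rep(mx, each = eng$S); scA <- scA + log(mx)
    }
    if (v <= eng$ntip) { Dv <- eng$tipp[[v]]; scv <- zero }
    else { Dv <- D[[v]]; scv <- sc[[v]] }
    tg <- t(crossprod(V, model$pi * A) * (W %*% Dv))   # P x S
    f <- function(t) {
      lik <- tg %*% exp(vals * t)
      lik[lik < 1e-300] <- 1e-300
      sum(eng$w * log(lik))
    }
    # Brent in log-length space: the profile flattens for large t, which
    # traps a linear-scale golden section on the plateau
    opt <- stats::optimize(function(lt) f(exp(lt)),
                           c(log(min_bl), log(max_bl)), maximum = TRUE,
                           tol = 1e-6)
    cand <- c(exp(opt$maximum), len[e], min_bl)
    fc <- c(opt$objective, f(len[e]), f(min_bl))
    len[e] <- cand[which.max(fc)]
    if (v > eng$ntip) {
      Rv <- .pmat(model, len[e]) %*% A
      mx <- .colmax(Rv)
      if (any(mx < 1e-200)) {
        mx[mx == 0] <- 1
        Rv <- Rv / rep(mx, each = eng$S); scA <- scA + log(mx)
      }
      R[[v]] <- Rv; scR[[v]] <- scA
    }
  }
  len
}

.optimize_bl <- function(eng, len, model, tol = 1e-6, rounds = 20,
                         min_bl = 1e-6, max_bl = 100) {
  ll <- .peel(eng, len, model)
  for (r in seq_len(rounds)) {
    len <- .bl_round(eng, len, model, min_bl, max_bl)
    ll_new <- .peel(eng, len, model)
    if (!is.finite(ll_new)) stop("non-finite likelihood during branch-length optimization")
    if (ll_new - ll < tol) { ll <- max(ll, ll_new); break }
    ll <- ll_new
  }
  list(len = len, loglik = ll)
}

#' Optimize branch lengths
#'
#' Iterated per-branch Brent optimization (root-to-tip sweeps over the
#' spectral edge-likelihood form) until a full round improves the
#' log-likelihood by less than `tol`. Lengths are constrained to
#' `[min_bl, max_bl]`.
#'
#' @inheritParams log_likelihood
#' @param tol convergence tolerance in log units (default 1e-6).
#' @param rounds maximum number of sweeps.
#' @param min_bl,max_bl branch-length bounds (defaults 1e-6 and 100).
#' @return the tree (postorder) with updated branch lengths; the achieved
#'   log-likelihood is attached as attribute `loglik`.
#' @export
optimize_branch_lengths <- function(tree, matrix, model, tol = 1e-6,
                                    rounds = 20, min_bl = 1e-6, max_bl = 100) {
  data <- .pattern_data(matrix, model)
  eng <- .engine(tree, data, model$S)
  res <- .optimize_bl(eng, eng$len, model, tol, rounds, min_bl, max_bl)
  out <- eng$tree
  out$edge.length <- res$len
  attr(out, "loglik") <- res$loglik
  out
}

# -- model-parameter optimization ------------------------------------------

.pack_params <- function(model) {
  p <- model$params
  switch(model$kind,
         MK = numeric(0),
         BIN = log(model$pi[2] / model$pi[1]),
         GTR = {
           r <- pmax(p$rates, 1e-8)
           c(log(model$pi[-1] / model$pi[1]), log(r[-1] / r[1]))
         },
         COGs = c(log(model$pi_nu[-1] / model$pi_nu[1]),
                  log(max(p$lambda_zero, 1e-10) / p$lambda_plus)),
         COG = {
           l <- pmax(p$lambda, 1e-8)
           c(log(model$pi_nu[-1] / model$pi_nu[1]),
             if (model$kappa > 2) log(l[-1] / l[1]) else numeric(0))
         })
}

.unpack_params <- function(kind, kappa, theta) {
  S <- .n_states(kind, kappa)
  switch(kind,
         MK = list(),
         BIN = list(pi = exp(c(0, theta))),
         GTR = {
           nf <- S - 1
           list(pi = exp(c(0, theta[seq_len(nf)])),
                rates = exp(c(0, theta[-seq_len(nf)])))
         },
         COGs = list(pi_nu = exp(c(0, theta[seq_len(kappa - 1)])),
                     lambda_plus = 1,
                     lambda_zero = exp(theta[kappa])),
         COG = list(pi_nu = exp(c(0, theta[seq_len(kappa - 1)])),
                    lambda = exp(c(0, theta[-seq_len(kappa - 1)]))))
}

.optimize_model_core <- function(eng, len, model, maxit = 500) {
  theta0 <- .pack_params(model)
  ll0 <- .peel(eng, len, model)
  if (!is.finite(ll0))
    stop("non-finite likelihood at the starting parameters (",
         model$kind, ", kappa = ", model$kappa %||% "-", ")")
  if (length(theta0) == 0)
    return(list(model = model, loglik = ll0, convergence = 0L))
  obj <- function(th) {
    ll <- tryCatch({
      m <- build_model(model$kind, model$kappa,
                       .unpack_params(model$kind, model$kappa, th))
      .peel(eng, len, m)
    }, error = function(e) -Inf)   # degenerate corners of the search box
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  fit <- stats::optim(theta0, obj, method = "L-BFGS-B",
                      lower = -25, upper = 25,
                      control = list(maxit = maxit, factr = 1e7))
  if (-fit$value >= ll0) {
    model <- build_model(model$kind, model$kappa,
                         .unpack_params(model$kind, model$kappa, fit$par))
    ll0 <- -fit$value
  }
  list(model = model, loglik = ll0, convergence = fit$convergence)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Optimize model parameters on a fixed tree
#'
#' Bounded quasi-Newton (L-BFGS-B) maximization of the log-likelihood over
#' the model's free parameters, on an unconstrained transform: frequencies
#' via log-ratios on their simplex (binomially weighted for the per-size
#' frequencies of COG/COGs) and rates via log-ratios with the first
#' exchangeability class fixed to 1 (the generator's unit-rate
#' normalization absorbs the overall scale). MK has no free parameters and
#' is returned unchanged. The returned log-likelihood never decreases
#' relative to the input model.
#'
#' @inheritParams log_likelihood
#' @param maxit maximum optimizer iterations.
#' @return list with `model` (fitted `subst_model`), `loglik` and
#'   `convergence` (0 = converged).
#' @export
optimize_model <- function(tree, matrix, model, maxit = 500) {
  data <- .pattern_data(matrix, model)
  eng <- .engine(tree, data, model$S)
  .optimize_model_core(eng, eng$len, model, maxit = maxit)
}
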