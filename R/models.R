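#' Population count of a bit vector
#'
#' Number of 1 bits. Accepts a bit string such as `"101"`, a 0/1 integer or
#' logical vector, or a 0-based symbol index together with `kappa`.
#'
#' @param b bit vector (string or 0/1 vector), or symbol index if `kappa`
#'   is given.
#' @param kappa if supplied, `b` is interpreted as a 0-based symbol index
#'   for a concept with `kappa` classes (bit vector value `b + 1`).
#' @return integer.
#' @export
popcount <- function(b, kappa = NULL) {
  if (!is.null(kappa)) {
    n <- as.integer(b) + 1L
    return(sum(as.integer(intToBits(n))))
  }
  if (is.character(b)) b <- as.integer(strsplit(b, "")[[1]])
  sum(as.integer(b) == 1L)
}

.bitvec <- function(index, kappa) {
  # 0-based symbol index -> 0/1 vector, MSB (first class) first
  as.integer(intToBits(as.integer(index) + 1L))[kappa:1]
}

#' Exchangeability class of a state pair
#'
#' Classifies the unordered pair of symbols `i`, `j` (0-based indices) under
#' a model kind. COGs distinguishes one-bit differences (`"lambda_plus"`)
#' from multi-bit differences (`"lambda_0"`). COG assigns `"lambda_<nu>"`
#' to one-bit differences, where `nu` is the size (popcount) of the smaller
#' state, and `"zero"` to multi-bit differences (that rate is pinned to 0).
#' MK puts every pair in one `"shared"` class; GTR gives every unordered
#' pair its own class.
#'
#' @param i,j distinct 0-based symbol indices.
#' @param kind one of `"MK"`, `"GTR"`, `"COGs"`, `"COG"`.
#' @param kappa number of cognate classes (fixes the state space).
#' @return a class label string.
#' @export
rate_class <- function(i, j, kind = c("MK", "GTR", "COGs", "COG"), kappa) {
  kind <- match.arg(kind)
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("diagonal entries have no rate class")
  S <- 2^kappa - 1
  if (i < 0 || j < 0 || i >= S || j >= S) stop("symbol index out of range")
  bi <- .bitvec(i, kappa); bj <- .bitvec(j, kappa)
  d <- sum(bi != bj)
  switch(kind,
         MK = "shared",
         GTR = paste0("pair_", min(i, j) + 1L, "_", max(i, j) + 1L),
         COGs = if (d == 1) "lambda_plus" else "lambda_0",
         COG = if (d == 1) paste0("lambda_", min(sum(bi), sum(bj))) else "zero")
}

#' Free-parameter counts by model
#'
#' The default `"table"` convention is the one used for AIC throughout:
#' BIN 1; MK 0; GTR \eqn{2^\kappa(2^\kappa-1)/2 + 2^\kappa}; COG
#' \eqn{2\kappa}; COGs \eqn{\kappa+1}. An alternative `"independent"`
#' convention counts only independently optimizable quantities (simplex and
#' scale constraints subtracted) and is available behind the flag but never
#' used by default.
#'
#' @param kind model kind, one of `"BIN"`, `"MK"`, `"GTR"`, `"COGs"`, `"COG"`.
#' @param kappa number of cognate classes (ignored for BIN, required
#'   otherwise; must be in `[2, 6]`).
#' @param convention `"table"` (default) or `"independent"`.
#' @return integer k.
#' @examples
#' free_parameter_count("GTR", kappa = 3)  # 36
#' free_parameter_count("COG", kappa = 3)  # 6
#' @export
free_parameter_count <- function(kind = c("BIN", "MK", "GTR", "COGs", "COG"),
                                 kappa = NULL,
                                 convention = c("table", "independent")) {
  kind <- match.arg(kind)
  convention <- match.arg(convention)
  if (kind != "BIN") {
    if (is.null(kappa)) stop("kappa is required for kind = ", kind)
    if (kappa < 2 || kappa > 6) stop("kappa must be in [2, 6]")
  }
  if (convention == "table") {
    switch(kind,
           BIN = 1L,
           MK = 0L,
           GTR = as.integer(2^kappa * (2^kappa - 1) / 2 + 2^kappa),
           COG = as.integer(2 * kappa),
           COGs = as.integer(kappa + 1))
  } else {
    S <- if (is.null(kappa)) 2L else as.integer(2^kappa - 1)
    switch(kind,
           BIN = 1L,
           MK = 0L,
           GTR = as.integer((S - 1) + (S * (S - 1) / 2 - 1)),
           COG = as.integer((kappa - 1) + max(kappa - 2, 0)),
           COGs = as.integer((kappa - 1) + 1))
  }
}

.n_states <- function(kind, kappa) {
  if (kind == "BIN") 2L else as.integer(2^kappa - 1)
}

# rate-class layouts are fixed per (kind, kappa); memoize them so repeated
# model construction inside optimizers stays cheap
.layout_cache <- new.env(parent = emptyenv())

.rate_layout <- function(kind, kappa) {
  key <- paste0(kind, ".", kappa %||% 0)
  hit <- .layout_cache[[key]]
  if (!is.null(hit)) return(hit)
  S <- .n_states(kind, kappa)
  labels <- matrix(NA_character_, S, S)
  pair <- matrix(NA_integer_, S, S)
  if (kind != "BIN") {
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      labels[i, j] <- labels[j, i] <- rate_class(i - 1L, j - 1L, kind, kappa)
      pair[i, j] <- pair[j, i] <- .pair_index(i, j, S)
    }
  }
  out <- list(labels = labels, pair = pair)
  assign(key, out, envir = .layout_cache)
  out
}

.exch_matrix <- function(kind, kappa, params) {
  # symmetric exchangeability matrix from the kind's rate classes
  S <- .n_states(kind, kappa)
  if (kind == "BIN") {
    x <- matrix(0, 2, 2)
    x[1, 2] <- x[2, 1] <- 1
    return(x)
  }
  lay <- .rate_layout(kind, kappa)
  x <- matrix(0, S, S)
  off <- !is.na(lay$labels)
  x[off] <- switch(kind,
    MK = 1,
    GTR = params$rates[lay$pair[off]],
    COGs = ifelse(lay$labels[off] == "lambda_plus",
                  params$lambda_plus, params$lambda_zero),
    COG = {
      v <- numeric(sum(off))
      lab <- lay$labels[off]
      nz <- lab != "zero"
      v[nz] <- params$lambda[as.integer(sub("lambda_", "", lab[nz]))]
      v
    })
  x
}

.pair_index <- function(i, j, S) {
  # row-wise upper-triangle index of unordered pair (i < j), 1-based
  as.integer((i - 1) * S - i * (i - 1) / 2 + (j - i))
}

.frequencies <- function(kind, kappa, params) {
  S <- .n_states(kind, kappa)
  if (kind == "BIN") {
    pi <- params$pi
    if (is.null(pi)) pi <- c(0.5, 0.5)
    if (length(pi) != 2) stop("BIN needs two base frequencies")
  } else if (kind %in% c("MK", "GTR")) {
    pi <- params$pi
    if (is.null(pi)) pi <- rep(1 / S, S)
    if (length(pi) != S) stop(kind, " needs ", S, " base frequencies")
  } else {
    pi_nu <- params$pi_nu
    if (is.null(pi_nu)) pi_nu <- rep(1, kappa)
    if (length(pi_nu) != kappa) stop(kind, " needs ", kappa, " per-size frequencies pi_nu")
    if (any(pi_nu <= 0)) stop("pi_nu values must be positive")
    # one frequency per state size nu; normalization sums binomial multiplicities
    pi_nu <- pi_nu / sum(choose(kappa, seq_len(kappa)) * pi_nu)
    nu <- vapply(seq_len(S), function(s) sum(.bitvec(s - 1L, kappa)), 0L)
    pi <- pi_nu[nu]
    attr(pi, "pi_nu") <- pi_nu
  }
  if (any(pi <= 0) || any(!is.finite(pi)))
    stop("base frequencies must be strictly positive and finite")
  if (sum(pi) <= 0) stop("base frequencies are not normalizable")
  structure(pi / sum(pi), pi_nu = attr(pi, "pi_nu"))
}

#' Build a substitution model
#'
#' Constructs a time-reversible continuous-time Markov model on the state
#' space of non-empty bit vectors (or on \{0, 1\} for BIN). Instantaneous
#' rates are `q(i, j) = x(i, j) * pi[j]` with a symmetric exchangeability
#' `x` determined by the kind's rate classes (see [rate_class()]), which
#' guarantees detailed balance. The generator is rescaled so the expected
#' substitution rate at stationarity is 1; branch lengths are therefore
#' expected substitutions per column.
#'
#' Parameters by kind (all rates must be non-negative; frequencies positive):
#' \describe{
#'   \item{BIN}{`pi` (length 2).}
#'   \item{MK}{none; uniform frequencies, equal rates.}
#'   \item{GTR}{`pi` (length `2^kappa - 1`), `rates` (one per unordered
#'     state pair, row-wise upper triangle).}
#'   \item{COGs}{`pi_nu` (length `kappa`, one frequency per state size;
#'     normalized so that `sum(choose(kappa, nu) * pi_nu) = 1`),
#'     `lambda_plus` (> 0), `lambda_zero` (>= 0).}
#'   \item{COG}{`pi_nu` as for COGs; `lambda` (length `kappa - 1`, rates
#'     for one-bit changes indexed by the smaller state's size). Multi-bit
#'     rates are structurally zero.}
#' }
#'
#' @param kind model kind.
#' @param kappa number of cognate classes; `NULL` for BIN.
#' @param params named list of parameters (see Details); missing entries
#'   default to the uniform/equal-rate model.
#' @return a `subst_model`: list with `kind`, `kappa`, `S`, `pi`
#'   (stationary frequencies), `pi_nu` (COG/COGs), `params`, `exch`
#'   (symmetric exchangeabilities), `Q` (normalized generator), `scale`
#'   (normalization constant), `k` (free-parameter count) and `eig`
#'   (cached spectral decomposition used for transition probabilities).
#' @examples
#' m <- build_model("COG", kappa = 3,
#'                  params = list(pi_nu = c(0.2, 0.06, 0.02), lambda = c(2, 1)))
#' m$pi                              # stationary frequencies by popcount
#' sum(m$pi * -diag(m$Q))            # unit expected substitution rate
#' @export
build_model <- function(kind = c("BIN", "MK", "GTR", "COGs", "COG"),
                        kappa = NULL, params = list()) {
  kind <- match.arg(kind)
  if (kind == "BIN") kappa <- NULL
  else {
    if (is.null(kappa)) stop("kappa is required for kind = ", kind)
    if (kappa < 2 || kappa > 6) stop("kappa must be in [2, 6]")
    kappa <- as.integer(kappa)
  }
  S <- .n_states(kind, kappa)
  if (kind == "GTR") {
    if (is.null(params$rates)) params$rates <- rep(1, S * (S - 1) / 2)
    if (length(params$rates) != S * (S - 1) / 2)
      stop("GTR needs ", S * (S - 1) / 2, " exchangeabilities")
    if (any(params$rates < 0)) stop("negative exchangeability")
  }
  if (kind == "COGs") {
    if (is.null(params$lambda_plus)) params$lambda_plus <- 1
    if (is.null(params$lambda_zero)) params$lambda_zero <- 1
    if (params$lambda_plus <= 0) stop("lambda_plus must be positive")
    if (params$lambda_zero < 0) stop("lambda_zero must be non-negative")
  }
  if (kind == "COG") {
    if (is.null(params$lambda)) params$lambda <- rep(1, kappa - 1)
    if (length(params$lambda) != kappa - 1)
      stop("COG needs ", kappa - 1, " lambda values (one per smaller-state size)")
    if (any(params$lambda < 0)) stop("negative lambda")
  }
  pi <- .frequencies(kind, kappa, params)
  pi_nu <- attr(pi, "pi_nu")
  pi <- as.numeric(pi)
  x <- .exch_matrix(kind, kappa, params)
  Q <- x * rep(pi, each = S)        # q(i, j) = x(i, j) * pi[j]
  diag(Q) <- -rowSums(Q)
  scale <- sum(pi * -diag(Q))
  if (!is.finite(scale) || scale <= 0)
    stop("degenerate model: expected substitution rate is not positive")
  Q <- Q / scale
  model <- structure(list(kind = kind, kappa = kappa, S = S, pi = pi,
                          pi_nu = pi_nu, params = params, exch = x,
                          Q = Q, scale = scale,
                          k = free_parameter_count(kind, kappa)),
                     class = "subst_model")
  model$eig <- .model_eigen(model)
  model
}

.model_eigen <- function(model) {
  # reversible generator: D^{1/2} Q D^{-1/2} is symmetric (D = diag(pi)),
  # giving a numerically stable spectral form P(t) = V exp(Lt) W
  sq <- sqrt(model$pi)
  B <- model$Q * (sq %o% (1 / sq))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       V = e$vectors / sq,          # D^{-1/2} U
       W = t(e$vectors) * rep(sq, each = length(sq)))  # U' D^{1/2}
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("subst_model %s%s: %d states, k = %d\n", x$kind,
              if (!is.null(x$kappa)) paste0(" (kappa = ", x$kappa, ")") else "",
              x$S, x$k))
  if (!is.null(x$pi_nu))
    cat("  pi_nu:", paste(signif(x$pi_nu, 4), collapse = " "), "\n")
  if (x$kind == "COG")
    cat("  lambda:", paste(signif(x$params$lambda, 4), collapse = " "),
        "(multi-bit rates fixed at 0)\n")
  if (x$kind == "COGs")
    cat("  lambda_plus:", signif(x$params$lambda_plus, 4),
        " lambda_zero:", signif(x$params$lambda_zero, 4), "\n")
  invisible(x)
}

#' Serialize a model to JSON
#'
#' @param model a `subst_model`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to file).
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "subst_model"))
  doc <- list(kind = model$kind, kappa = model$kappa, states = model$S,
              pi = model$pi, pi_nu = model$pi_nu,
              params = model$params, k = model$k,
              normalization = model$scale)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
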