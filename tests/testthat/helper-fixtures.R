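# shared fixtures and independent oracles, built in code

# small wordlist: 3 languages x 4 concepts with polymorphism and missing data
tiny_dataset <- function() {
  tab <- data.frame(
    language = c("l1", "l1", "l2", "l1", "l2", "l3", "l3", "l1", "l2", "l3"),
    concept  = c("hand", "hand", "hand", "sun", "sun", "sun", "hand", "dog", "dog", "dog"),
    class    = c("a", "b", "a", "x", "y", "y", "c", "p", "q", "r"),
    stringsAsFactors = FALSE)
  cognate_dataset(c("l1", "l2", "l3"), c("hand", "sun", "dog", "moon"), tab)
}

# brute-force likelihood: explicit summation over all ancestral (and missing
# tip) state assignments; independent of the pruning implementation
brute_loglik <- function(tree, matrix, model) {
  codes <- if (inherits(matrix, "bitvector_matrix")) unclass(matrix) + 1L
           else matrix(match(unclass(matrix), c("0", "1")),
                       nrow(matrix), ncol(matrix), dimnames = dimnames(matrix))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  root <- tr$edge[nrow(tr$edge), 1]
  nn <- max(tr$edge)
  S <- model$S
  Pm <- lapply(seq_len(nrow(tr$edge)), function(e)
    transition_probabilities(model, tr$edge.length[e]))
  codes <- codes[tr$tip.label, , drop = FALSE]
  ints <- (ntip + 1):nn
  grid <- as.matrix(expand.grid(rep(list(1:S), length(ints))))
  total <- 0
  for (col in seq_len(ncol(codes))) {
    tipst <- codes[, col]
    tg <- as.matrix(expand.grid(lapply(seq_len(ntip), function(i)
      if (is.na(tipst[i])) 1:S else tipst[i])))
    Lcol <- 0
    for (g in seq_len(nrow(grid))) {
      st <- integer(nn)
      st[ints] <- grid[g, ]
      for (h in seq_len(nrow(tg))) {
        st[seq_len(ntip)] <- tg[h, ]
        pr <- model$pi[st[root]]
        for (e in seq_len(nrow(tr$edge)))
          pr <- pr * Pm[[e]][st[tr$edge[e, 1]], st[tr$edge[e, 2]]]
        Lcol <- Lcol + pr
      }
    }
    total <- total + log(Lcol)
  }
  total
}

# wrap a plain integer matrix (0-based symbols, NA missing) as bitvector_matrix
as_bitvector <- function(m, kappa) {
  class_orders <- rep(list(letters[seq_len(kappa)]), ncol(m))
  names(class_orders) <- colnames(m)
  structure(m, kappa = as.integer(kappa), class_orders = class_orders,
            alphabet = default_alphabet(),
            class = c("bitvector_matrix", "matrix", "array"))
}

two_taxon_tree <- function(t1, t2) {
  ape::read.tree(text = sprintf("(a:%g,b:%g);", t1, t2))
}

random_model <- function(kind, kappa, seed) {
  set.seed(seed)
  S <- if (kind == "BIN") 2L else as.integer(2^kappa - 1)
  params <- switch(kind,
    BIN = list(pi = stats::runif(2, 0.2, 1)),
    MK = list(),
    GTR = list(pi = stats::runif(S, 0.05, 1),
               rates = stats::runif(S * (S - 1) / 2, 0.1, 2)),
    COGs = list(pi_nu = stats::runif(kappa, 0.05, 1),
                lambda_plus = stats::runif(1, 0.2, 2),
                lambda_zero = stats::runif(1, 0, 1)),
    COG = list(pi_nu = stats::runif(kappa, 0.05, 1),
               lambda = stats::runif(kappa - 1, 0.2, 2)))
  build_model(kind, if (kind == "BIN") NULL else kappa, params)
}
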