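#' Default multistate symbol alphabet
#'
#' An ordered list of 64 distinct printable symbols used to represent bit
#' vectors in multistate character matrices: digits 0-9, then A-Z, then a-z,
#' then `!` and `*`. The missing symbol `-` is never part of the alphabet.
#' A concept with \eqn{\kappa} cognate classes needs \eqn{2^\kappa - 1}
#' symbols, so the 64-symbol cap limits \eqn{\kappa} to 6.
#'
#' @return character vector of length 64.
#' @export
default_alphabet <- function() {
  c(as.character(0:9), LETTERS, letters, "!", "*")
}

.check_alphabet <- function(alphabet) {
  if (anyDuplicated(alphabet)) stop("alphabet symbols must be distinct")
  if ("-" %in% alphabet) stop("'-' is reserved for missing data")
  if (length(alphabet) > 64) stop("alphabet is limited to 64 symbols")
  if (any(nchar(alphabet) != 1)) stop("alphabet symbols must be single characters")
  alphabet
}

#' Build the concept inventory
#'
#' For each concept, collects the union of cognate classes assigned across
#' all languages (\eqn{V_c}), sorted lexicographically, and its size
#' \eqn{\kappa}. Concepts attested in no language are dropped with a warning.
#'
#' @param dataset a `cognate_dataset`.
#' @return a `concept_inventory`: list with `concepts` (character),
#'   `classes` (named list of sorted class vectors) and `kappa` (named
#'   integer).
#' @export
build_inventory <- function(dataset) {
  stopifnot(inherits(dataset, "cognate_dataset"))
  if (length(dataset$concepts) == 0) stop("dataset has no concepts")
  classes <- lapply(dataset$concepts, function(co) {
    v <- unique(unlist(dataset$assignments[, co], use.names = FALSE))
    sort(v, method = "radix")
  })
  names(classes) <- dataset$concepts
  empty <- lengths(classes) == 0
  if (any(empty)) {
    warning("dropping concept(s) with no attested word: ",
            paste(dataset$concepts[empty], collapse = ", "))
    classes <- classes[!empty]
  }
  structure(list(concepts = names(classes), classes = classes,
                 kappa = lengths(classes)),
            class = "concept_inventory")
}

#' @export
print.concept_inventory <- function(x, ...) {
  cat(sprintf("concept_inventory: %d concepts; kappa range [%d, %d]\n",
              length(x$concepts), min(x$kappa), max(x$kappa)))
  print(table(kappa = x$kappa))
  invisible(x)
}

#' Binary (presence/absence) encoding
#'
#' Builds the binary character matrix with one column per (concept, class)
#' pair. An entry is `"1"` if the class is present for the language, `"0"`
#' if the pair has at least one word but not this class, and `"-"` across
#' the whole column group of a concept when the pair is missing
#' (\eqn{\nu = 0}).
#'
#' @param dataset a `cognate_dataset`.
#' @param inventory a `concept_inventory` built from the same dataset.
#' @return a `binary_matrix`: character matrix (languages x columns) with
#'   attributes `concept` and `cls` giving each column's concept and class.
#' @export
encode_binary <- function(dataset, inventory) {
  stopifnot(inherits(dataset, "cognate_dataset"),
            inherits(inventory, "concept_inventory"))
  col_concept <- rep(inventory$concepts, inventory$kappa)
  col_class <- unlist(inventory$classes, use.names = FALSE)
  m <- matrix("-", length(dataset$languages), length(col_concept),
              dimnames = list(dataset$languages,
                              paste(col_concept, col_class, sep = ":")))
  for (co in inventory$concepts) {
    jj <- which(col_concept == co)
    for (i in seq_along(dataset$languages)) {
      v <- dataset$assignments[[i, co]]
      if (length(v))
        m[i, jj] <- ifelse(inventory$classes[[co]] %in% v, "1", "0")
    }
  }
  structure(m, concept = col_concept, cls = col_class,
            class = c("binary_matrix", "matrix", "array"))
}

#' Map a state (set of classes) to its symbol index
#'
#' The state is written as a bit vector over the concept's ordered classes
#' (leftmost bit = first class, read as the most significant bit), the bit
#' vector is read as a binary integer, and 1 is subtracted because the
#' all-zero vector (missing) is skipped when assigning symbols. The result
#' is a 0-based index into the symbol alphabet.
#'
#' @param state character vector of present classes (non-empty).
#' @param class_order the concept's ordered class vector.
#' @param alphabet symbol alphabet (checked for capacity).
#' @return 0-based integer symbol index in `[0, 2^kappa - 2]`.
#' @examples
#' state_to_symbol("C", c("A", "B", "C"))           # 001 -> 0
#' state_to_symbol("A", c("A", "B", "C"))           # 100 -> 3
#' symbol_to_state(3, c("A", "B", "C"))             # "A"
#' @export
state_to_symbol <- function(state, class_order, alphabet = default_alphabet()) {
  .check_alphabet(alphabet)
  k <- length(class_order)
  if (2^k - 1 > length(alphabet))
    stop("kappa = ", k, " needs ", 2^k - 1, " symbols; alphabet has ",
         length(alphabet))
  state <- unique(as.character(state))
  if (length(state) == 0) stop("empty state has no symbol (encode as missing)")
  if (!all(state %in% class_order))
    stop("state contains class(es) outside the concept's class order")
  bits <- as.integer(class_order %in% state)
  idx <- sum(bits * 2^((k - 1):0)) - 1L
  as.integer(idx)
}

#' Decode a symbol index back to its state
#'
#' Inverse of [state_to_symbol()].
#'
#' @param index 0-based symbol index.
#' @param class_order the concept's ordered class vector.
#' @return character vector of present classes.
#' @export
symbol_to_state <- function(index, class_order) {
  k <- length(class_order)
  n <- as.integer(index) + 1L
  if (n < 1L || n > 2^k - 1) stop("symbol index out of range for kappa = ", k)
  bits <- as.integer(intToBits(n))[k:1]
  class_order[bits == 1L]
}

#' Partition concepts into kappa-subsets
#'
#' Groups concepts by their number of cognate classes \eqn{\kappa}. Concepts
#' with \eqn{\kappa = 1} carry no topological signal and concepts with
#' \eqn{\kappa > 6} would exceed the 64-symbol alphabet; both are excluded
#' and listed in the report.
#'
#' @param inventory a `concept_inventory`.
#' @return list with `subsets` (named list, names "2".."6", of concept
#'   vectors) and `excluded` (data.frame with `concept`, `kappa`, `reason`).
#' @export
kappa_partition <- function(inventory) {
  stopifnot(inherits(inventory, "concept_inventory"))
  k <- inventory$kappa
  keep <- k >= 2 & k <= 6
  subsets <- split(inventory$concepts[keep], k[keep])
  excluded <- data.frame(concept = inventory$concepts[!keep],
                         kappa = unname(k[!keep]),
                         reason = ifelse(k[!keep] < 2,
                                         "kappa = 1: no topological signal",
                                         "kappa > 6: exceeds 64-symbol alphabet"),
                         stringsAsFactors = FALSE)
  list(subsets = subsets, excluded = excluded)
}

#' Bit-vector encoding of a kappa-subset
#'
#' Builds the multistate character matrix with one column per concept of the
#' given \eqn{\kappa}. Entries are 0-based symbol indices in
#' `[0, 2^kappa - 2]` (see [state_to_symbol()]); missing pairs are `NA`.
#'
#' @param dataset a `cognate_dataset`.
#' @param inventory a `concept_inventory` built from the same dataset.
#' @param kappa number of cognate classes, in `[2, 6]`.
#' @param alphabet symbol alphabet used for PHYLIP interchange.
#' @return a `bitvector_matrix`: integer matrix (languages x concepts) with
#'   attributes `kappa`, `class_orders` (named list) and `alphabet`.
#' @export
encode_bitvector <- function(dataset, inventory, kappa,
                             alphabet = default_alphabet()) {
  stopifnot(inherits(dataset, "cognate_dataset"),
            inherits(inventory, "concept_inventory"))
  .check_alphabet(alphabet)
  if (kappa < 2 || kappa > 6)
    stop("kappa = ", kappa, " not supported: 2^kappa - 1 = ", 2^kappa - 1,
         " symbols needed, alphabet allows at most 64 (kappa <= 6),",
         " and kappa = 1 concepts carry no signal")
  concepts <- inventory$concepts[inventory$kappa == kappa]
  if (length(concepts) == 0) stop("kappa-subset for kappa = ", kappa, " is empty")
  m <- matrix(NA_integer_, length(dataset$languages), length(concepts),
              dimnames = list(dataset$languages, concepts))
  for (co in concepts) {
    ord <- inventory$classes[[co]]
    for (i in seq_along(dataset$languages)) {
      v <- dataset$assignments[[i, co]]
      if (length(v))
        m[i, co] <- state_to_symbol(v, ord, alphabet)
    }
  }
  structure(m, kappa = as.integer(kappa),
            class_orders = inventory$classes[concepts],
            alphabet = alphabet,
            class = c("bitvector_matrix", "matrix", "array"))
}

#' Subset columns of an encoded matrix
#'
#' Keeps the matrix class and its column-linked attributes consistent.
#'
#' @param m a `binary_matrix` or `bitvector_matrix`.
#' @param j column indices.
#' @return matrix of the same class.
#' @export
subset_columns <- function(m, j) {
  if (inherits(m, "bitvector_matrix")) {
    structure(unclass(m)[, j, drop = FALSE], kappa = attr(m, "kappa"),
              class_orders = attr(m, "class_orders")[j],
              alphabet = attr(m, "alphabet"),
              class = class(m))
  } else if (inherits(m, "binary_matrix")) {
    structure(unclass(m)[, j, drop = FALSE],
              concept = attr(m, "concept")[j], cls = attr(m, "cls")[j],
              class = class(m))
  } else {
    m[, j, drop = FALSE]
  }
}

.matrix_chars <- function(m) {
  # character representation with '-' for missing, for any encoded matrix
  if (inherits(m, "bitvector_matrix")) {
    alpha <- attr(m, "alphabet")
    ch <- matrix("-", nrow(m), ncol(m), dimnames = dimnames(m))
    ok <- !is.na(unclass(m))
    ch[ok] <- alpha[unclass(m)[ok] + 1L]
    ch
  } else {
    ch <- unclass(m)
    ch[is.na(ch)] <- "-"
    ch
  }
}

#' Write a character matrix in relaxed PHYLIP format
#'
#' Header line `ntaxa ncols`, then one `name sequence` row per taxon. Binary
#' matrices use `0`, `1` and `-`; multistate matrices use the symbol
#' alphabet plus `-` for missing.
#'
#' @param matrix a `binary_matrix` or `bitvector_matrix`.
#' @param path output file path.
#' @export
write_phylip <- function(matrix, path) {
  taxa <- rownames(matrix)
  if (is.null(taxa) || anyDuplicated(taxa)) stop("taxon names must be present and unique")
  if (any(grepl("[[:space:]]", taxa))) stop("taxon names must be whitespace-free")
  ch <- .matrix_chars(matrix)
  lines <- c(paste(nrow(ch), ncol(ch)),
             paste(formatC(taxa, width = max(nchar(taxa)) + 2, flag = "-"),
                   apply(ch, 1, paste, collapse = "")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a relaxed PHYLIP character matrix
#'
#' @param path file path.
#' @param kind `"binary"` or `"multistate"`.
#' @param kappa required for `kind = "multistate"`: the number of cognate
#'   classes per concept, which fixes the admissible symbol range.
#' @param alphabet symbol alphabet for `kind = "multistate"`.
#' @return a `binary_matrix` or `bitvector_matrix`. For multistate reads the
#'   per-column class orders are not stored in PHYLIP; generic class labels
#'   (`a`, `b`, ...) are substituted.
#' @export
read_phylip <- function(path, kind = c("binary", "multistate"), kappa = NULL,
                        alphabet = default_alphabet()) {
  kind <- match.arg(kind)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  hdr <- as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]])
  if (length(hdr) != 2 || anyNA(hdr)) stop("malformed PHYLIP header")
  if (length(lines) - 1 != hdr[1]) stop("PHYLIP row count does not match header")
  parts <- strsplit(trimws(lines[-1]), "[[:space:]]+")
  taxa <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(taxa)) stop("duplicate taxon names in PHYLIP file")
  seqs <- vapply(parts, `[[`, "", 2)
  if (any(nchar(seqs) != hdr[2])) stop("sequence length does not match header")
  ch <- do.call(rbind, strsplit(seqs, ""))
  rownames(ch) <- taxa
  colnames(ch) <- paste0("col", seq_len(ncol(ch)))
  if (kind == "binary") {
    if (!all(ch %in% c("0", "1", "-"))) stop("binary PHYLIP may only contain 0, 1, -")
    structure(ch, concept = colnames(ch), cls = rep("1", ncol(ch)),
              class = c("binary_matrix", "matrix", "array"))
  } else {
    if (is.null(kappa)) stop("kappa is required to read a multistate matrix")
    .check_alphabet(alphabet)
    S <- 2^kappa - 1
    admissible <- alphabet[seq_len(S)]
    bad <- setdiff(unique(as.vector(ch)), c(admissible, "-"))
    if (length(bad))
      stop("symbol(s) outside the kappa = ", kappa, " alphabet: ",
           paste(bad, collapse = " "))
    idx <- matrix(match(ch, admissible) - 1L, nrow(ch), ncol(ch),
                  dimnames = dimnames(ch))
    class_orders <- rep(list(letters[seq_len(kappa)]), ncol(ch))
    names(class_orders) <- colnames(ch)
    structure(idx, kappa = as.integer(kappa), class_orders = class_orders,
              alphabet = alphabet,
              class = c("bitvector_matrix", "matrix", "array"))
  }
}
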