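#' Construct a cognate dataset
#'
#' A cognate dataset assigns to every (language, concept) pair a finite set of
#' cognate-class labels. An empty set encodes missing information (no word
#' recorded for that language and concept). The number of classes present for
#' one pair is called \eqn{\nu}; the number of classes attested for a concept
#' across all languages is called \eqn{\kappa}.
#'
#' Class labels are scoped per concept: the same label under two different
#' concepts denotes two different cognate classes.
#'
#' @param languages character vector of language identifiers (order is kept).
#' @param concepts character vector of concept identifiers (order is kept).
#' @param assignments a list-matrix (languages x concepts) whose cells are
#'   character vectors of class labels, or a data.frame with columns
#'   `language`, `concept`, `class` (one row per word).
#' @return An object of class `cognate_dataset` with fields `languages`,
#'   `concepts` and `assignments` (a languages x concepts matrix of character
#'   vectors; empty vector = missing).
#' @export
cognate_dataset <- function(languages, concepts, assignments) {
  languages <- as.character(languages)
  concepts <- as.character(concepts)
  if (anyDuplicated(languages)) stop("duplicate language identifiers")
  if (anyDuplicated(concepts)) stop("duplicate concept identifiers")
  if (is.data.frame(assignments)) {
    need <- c("language", "concept", "class")
    if (!all(need %in% names(assignments)))
      stop("assignment data.frame needs columns language, concept, class")
    bad_l <- setdiff(unique(assignments$language), languages)
    bad_c <- setdiff(unique(assignments$concept), concepts)
    if (length(bad_l) || length(bad_c))
      stop("assignment refers to unknown language or concept")
    m <- matrix(list(character(0)), length(languages), length(concepts),
                dimnames = list(languages, concepts))
    if (nrow(assignments)) {
      for (i in seq_len(nrow(assignments))) {
        l <- as.character(assignments$language[i])
        co <- as.character(assignments$concept[i])
        m[[l, co]] <- union(m[[l, co]], as.character(assignments$class[i]))
      }
    }
    assignments <- m
  }
  stopifnot(is.matrix(assignments),
            nrow(assignments) == length(languages),
            ncol(assignments) == length(concepts))
  dimnames(assignments) <- list(languages, concepts)
  assignments[] <- lapply(assignments, function(v) {
    v <- unique(as.character(v))
    v <- v[nzchar(v) & !is.na(v)]
    v
  })
  structure(list(languages = languages, concepts = concepts,
                 assignments = assignments),
            class = "cognate_dataset")
}

#' @export
print.cognate_dataset <- function(x, ...) {
  nu <- nu_values(x)
  cat(sprintf("cognate_dataset: %d languages x %d concepts; %.1f%% missing (nu = 0)\n",
              length(x$languages), length(x$concepts),
              100 * mean(nu == 0)))
  invisible(x)
}

#' Per-pair state sizes
#'
#' Number of cognate classes (\eqn{\nu}) per (language, concept) pair.
#'
#' @param dataset a `cognate_dataset`.
#' @return integer matrix, languages x concepts.
#' @export
nu_values <- function(dataset) {
  stopifnot(inherits(dataset, "cognate_dataset"))
  out <- matrix(lengths(dataset$assignments),
                length(dataset$languages), length(dataset$concepts),
                dimnames = list(dataset$languages, dataset$concepts))
  out
}

#' Read a cognate wordlist
#'
#' Two plain-text dialects are supported. `"long-tsv"` is a long table with
#' one row per word and columns `Language_ID`, `Parameter_ID` (the concept)
#' and `Cognateset_ID` (CLDF FormTable-compatible naming). `"matrix-tsv"` has
#' one row per language, one column per concept, and cells holding
#' comma-separated class labels; an empty cell means missing.
#'
#' Languages and concepts keep first-appearance order. Duplicate
#' (language, concept, class) rows collapse into one set element.
#'
#' @param path file path.
#' @param dialect `"long-tsv"` or `"matrix-tsv"`.
#' @return a [cognate_dataset()].
#' @export
read_wordlist <- function(path, dialect = c("long-tsv", "matrix-tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", fileEncoding = "UTF-8")
  if (nrow(tab) == 0) stop("empty wordlist: ", path)
  if (dialect == "long-tsv") {
    need <- c("Language_ID", "Parameter_ID", "Cognateset_ID")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("long-tsv wordlist lacks required column(s): ",
           paste(miss, collapse = ", "))
    langs <- unique(tab$Language_ID)
    cons <- unique(tab$Parameter_ID)
    cognate_dataset(langs, cons,
                    data.frame(language = tab$Language_ID,
                               concept = tab$Parameter_ID,
                               class = tab$Cognateset_ID,
                               stringsAsFactors = FALSE))
  } else {
    if (ncol(tab) < 2) stop("matrix-tsv wordlist needs a language column and at least one concept column")
    langs <- tab[[1]]
    cons <- names(tab)[-1]
    m <- matrix(list(character(0)), length(langs), length(cons),
                dimnames = list(langs, cons))
    for (j in seq_along(cons)) {
      cells <- tab[[j + 1]]
      for (i in seq_along(langs)) {
        v <- trimws(strsplit(cells[i], ",", fixed = TRUE)[[1]])
        m[[i, j]] <- unique(v[nzchar(v)])
      }
    }
    cognate_dataset(langs, cons, m)
  }
}

#' Write a cognate wordlist
#'
#' Inverse of [read_wordlist()]; a write followed by a read reproduces the
#' assignment map exactly (set equality per pair).
#'
#' @param dataset a `cognate_dataset`.
#' @param path output file path.
#' @param dialect `"long-tsv"` or `"matrix-tsv"`.
#' @export
write_wordlist <- function(dataset, path, dialect = c("long-tsv", "matrix-tsv")) {
  stopifnot(inherits(dataset, "cognate_dataset"))
  dialect <- match.arg(dialect)
  if (dialect == "long-tsv") {
    rows <- list()
    for (l in dataset$languages) for (co in dataset$concepts) {
      v <- dataset$assignments[[l, co]]
      if (length(v))
        rows[[length(rows) + 1L]] <- data.frame(Language_ID = l,
                                                Parameter_ID = co,
                                                Cognateset_ID = v,
                                                stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    if (is.null(tab)) stop("cannot write an entirely empty dataset as long-tsv")
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    cells <- matrix("", length(dataset$languages), length(dataset$concepts))
    for (i in seq_along(dataset$languages)) for (j in seq_along(dataset$concepts))
      cells[i, j] <- paste(dataset$assignments[[i, j]], collapse = ",")
    tab <- data.frame(Language_ID = dataset$languages, cells,
                      stringsAsFactors = FALSE, check.names = FALSE)
    names(tab) <- c("Language_ID", dataset$concepts)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Average coverage of a dataset
#'
#' Coverage of a language is the fraction of concepts for which it has at
#' least one word (\eqn{\nu \ge 1}); the dataset value is the unweighted mean
#' over languages.
#'
#' @param dataset a `cognate_dataset`.
#' @return a fraction in \[0, 1\].
#' @export
average_coverage <- function(dataset) {
  stopifnot(inherits(dataset, "cognate_dataset"))
  if (length(dataset$concepts) == 0) stop("coverage undefined: dataset has no concepts")
  if (length(dataset$languages) == 0) stop("coverage undefined: dataset has no languages")
  nu <- nu_values(dataset)
  mean(rowMeans(nu >= 1))
}

#' Data-inclusion criteria
#'
#' Checks a dataset against the benchmark inclusion thresholds: at least
#' `min_languages` languages, at least `min_concepts` concepts, average
#' coverage at least `min_avg_coverage`, and (optionally) at least as many
#' concepts as languages.
#'
#' @param dataset a `cognate_dataset`.
#' @param min_languages minimum language count (default 4).
#' @param min_concepts minimum concept count (default 85).
#' @param min_avg_coverage minimum average coverage (default 0.45).
#' @param require_concepts_ge_languages require `#concepts >= #languages`
#'   (default `TRUE`).
#' @return an `inclusion_report`: data.frame with one row per criterion
#'   (`criterion`, `observed`, `threshold`, `pass`) and an attribute
#'   `pass` giving the overall verdict.
#' @export
apply_inclusion_criteria <- function(dataset, min_languages = 4,
                                     min_concepts = 85,
                                     min_avg_coverage = 0.45,
                                     require_concepts_ge_languages = TRUE) {
  stopifnot(inherits(dataset, "cognate_dataset"))
  nl <- length(dataset$languages)
  nc <- length(dataset$concepts)
  cov <- if (nc > 0 && nl > 0) average_coverage(dataset) else 0
  rep <- data.frame(
    criterion = c("languages", "concepts", "avg_coverage", "concepts_ge_languages"),
    observed = c(nl, nc, cov, nc / max(nl, 1)),
    threshold = c(min_languages, min_concepts, min_avg_coverage, 1),
    pass = c(nl >= min_languages, nc >= min_concepts,
             cov >= min_avg_coverage,
             !require_concepts_ge_languages || nc >= nl),
    stringsAsFactors = FALSE)
  if (!require_concepts_ge_languages)
    rep <- rep[rep$criterion != "concepts_ge_languages", ]
  attr(rep, "pass") <- all(rep$pass)
  class(rep) <- c("inclusion_report", "data.frame")
  rep
}

#' @export
print.inclusion_report <- function(x, ...) {
  cat("inclusion report: overall", if (attr(x, "pass")) "PASS" else "FAIL", "\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
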