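# C-terminal k-mer peptide library construction and peptide -> source-protein
# bookkeeping.

#' Build a C-terminal k-mer peptide library from a proteome
#'
#' For every protein of length >= k, its C-terminal k-mer enters the library;
#' duplicated peptides collapse into one entry with merged source sets.
#' Proteins shorter than k, and peptides containing ambiguous residues
#' (anything outside the 20 standard one-letter codes), are excluded with a
#' message.
#'
#' @param proteome An [Biostrings::AAStringSet] or named character vector of
#'   protein sequences.
#' @param k Peptide length in residues (default 7).
#' @return An object of class `peptide_library`: list with `peptides`
#'   (character, sorted), `sources` (named list peptide -> protein ids) and
#'   `k`.
#' @export
build_cterm_library <- function(proteome, k = 7) {
  if (!is_count(k) || k < 1) stop("k must be a positive integer",
                                  call. = FALSE)
  seqs <- if (inherits(proteome, "AAStringSet")) {
    setNames(as.character(proteome), names(proteome))
  } else {
    proteome
  }
  if (length(seqs) == 0L) {
    warning("empty proteome: returning an empty library", call. = FALSE)
    return(structure(list(peptides = character(0), sources = list(),
                          k = as.integer(k)),
                     class = "peptide_library"))
  }
  if (is.null(names(seqs)) || anyNA(names(seqs))) {
    stop("proteome records must be named", call. = FALSE)
  }
  lens <- nchar(seqs)
  short <- lens < k
  if (any(short)) {
    message(sum(short), " protein(s) shorter than k = ", k, " skipped")
  }
  seqs <- seqs[!short]
  pep <- substr(seqs, nchar(seqs) - k + 1L, nchar(seqs))
  ok <- !grepl(paste0("[^", paste(AA20, collapse = ""), "]"), pep)
  if (any(!ok)) {
    message(sum(!ok), " peptide(s) with ambiguous residues excluded (",
            paste(head(unique(pep[!ok]), 3), collapse = ", "), " ...)")
  }
  pep <- pep[ok]
  sources <- split(names(pep), pep)
  peptides <- sort(names(sources))
  structure(list(peptides = peptides, sources = sources[peptides],
                 k = as.integer(k)),
            class = "peptide_library")
}

#' @export
print.peptide_library <- function(x, ...) {
  cat("peptide_library:", length(x$peptides), "distinct", x$k,
      "-mer peptide(s) from",
      length(unique(unlist(x$sources, use.names = FALSE))), "protein(s)\n")
  invisible(x)
}

#' Source proteins of a library peptide
#'
#' @param lib A [build_cterm_library] result.
#' @param peptide Amino-acid string.
#' @return Character vector of protein identifiers; empty if the peptide is
#'   not in the library.
#' @export
lookup_sources <- function(lib, peptide) {
  stopifnot(inherits(lib, "peptide_library"))
  src <- lib$sources[[peptide]]
  if (is.null(src)) character(0) else src
}

#' Write / read a peptide library as TSV
#'
#' Two columns: `peptide` and semicolon-joined `sources`.
#'
#' @param lib A `peptide_library`.
#' @param path TSV path.
#' @param k Peptide length (read only; inferred from the data when `NULL`).
#' @return `path` invisibly (write); a `peptide_library` (read).
#' @export
write_library_tsv <- function(lib, path) {
  stopifnot(inherits(lib, "peptide_library"))
  df <- data.frame(peptide = lib$peptides,
                   sources = vapply(lib$sources, paste, character(1),
                                    collapse = ";"),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_tsv
#' @export
read_library_tsv <- function(path, k = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  sources <- strsplit(df$sources, ";", fixed = TRUE)
  names(sources) <- df$peptide
  if (is.null(k)) k <- unique(nchar(df$peptide))
  stopifnot(length(k) == 1L)
  structure(list(peptides = df$peptide, sources = sources,
                 k = as.integer(k)),
            class = "peptide_library")
}
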