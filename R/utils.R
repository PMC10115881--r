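# Shared constants and small helpers.

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Fixed reverse-translation table
#'
#' One codon per residue (a common human codon for each amino acid). The
#' screen treats the peptide amino-acid sequence as its own barcode, so codon
#' degeneracy is irrelevant to the pipeline; a fixed single-codon table keeps
#' the read architecture deterministic.
#'
#' @return Named character vector mapping one-letter amino-acid codes to
#'   codons.
#' @export
default_codon_map <- function() {
  c(A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC",
    G = "GGC", H = "CAC", I = "ATC", K = "AAG", L = "CTG",
    M = "ATG", N = "AAC", P = "CCC", Q = "CAG", R = "CGC",
    S = "AGC", T = "ACC", V = "GTG", W = "TGG", Y = "TAC")
}

#' Default read architecture
#'
#' Fixed flanking adapter context used by the FASTQ generator and located by
#' the counting step. The peptide-coding window sits immediately between the
#' two flanks.
#'
#' @return List with elements `left` and `right`, the adapter sequences.
#' @export
default_flank_spec <- function() {
  list(left = "TCTAGAGGCGGC", right = "GGATCCTGACTG")
}

# Reverse-translate peptides with the fixed codon table; errors on residues
# without a codon.
reverse_translate <- function(peptides, codon_map = default_codon_map()) {
  vapply(peptides, function(p) {
    aa <- strsplit(p, "", fixed = TRUE)[[1]]
    bad <- setdiff(aa, names(codon_map))
    if (length(bad) > 0L) {
      stop("peptide '", p, "' has residue(s) without a codon mapping: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    paste(codon_map[aa], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming(): unequal lengths", call. = FALSE)
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# Mean per-base Phred (Sanger +33 encoding) for a vector of quality strings,
# chunked to bound memory. All strings must share one length within a call.
mean_phred <- function(qual) {
  n <- length(qual)
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  chunk <- 100000L
  for (i in seq(1L, n, by = chunk)) {
    j <- min(i + chunk - 1L, n)
    qs <- qual[i:j]
    lens <- nchar(qs)
    if (length(unique(lens)) == 1L) {
      ints <- utf8ToInt(paste(qs, collapse = "")) - 33L
      out[i:j] <- colMeans(matrix(ints, nrow = lens[1]))
    } else {
      out[i:j] <- vapply(qs, function(q) mean(utf8ToInt(q) - 33L), numeric(1),
                         USE.NAMES = FALSE)
    }
  }
  out
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == round(x)
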