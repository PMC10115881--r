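# FASTQ -> per-sample peptide count tables: mean-Phred quality filter,
# peptide-barcode extraction/translation/counting, per-sample normalization.

#' Filter reads on mean per-base Phred quality
#'
#' A read passes iff the arithmetic mean of its per-base Phred scores is
#' strictly greater than `min_mean_phred` (the screen's ">30" rule).
#'
#' @param reads A [fastq_records] object or FASTQ file path.
#' @param min_mean_phred Threshold (default 30; strict inequality).
#' @return List with `reads` (passing [fastq_records]) and `qc` (one-row
#'   data frame: `total`, `passed`, `failed_quality`).
#' @export
filter_reads <- function(reads, min_mean_phred = 30) {
  if (is.character(reads)) reads <- read_fastq(reads)
  stopifnot(inherits(reads, "fastq_records"))
  bad <- which(nchar(reads$sequence) != nchar(reads$quality))
  if (length(bad) > 0L) {
    stop("malformed FASTQ record '", reads$id[bad[1]],
         "': sequence/quality length mismatch", call. = FALSE)
  }
  keep <- mean_phred(reads$quality) > min_mean_phred
  list(reads = reads[keep, , drop = FALSE],
       qc = data.frame(total = length(keep), passed = sum(keep),
                       failed_quality = sum(!keep)))
}

# Translate coding windows (vector of 3k-mers) to peptides; returns NA for
# windows with stop codons, non-ACGT characters, or wrong length.
translate_windows <- function(windows, k) {
  out <- rep(NA_character_, length(windows))
  ok <- !is.na(windows) & nchar(windows) == 3L * k &
    !grepl("[^ACGT]", windows)
  if (any(ok)) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(windows[ok]), no.init.codon = TRUE))
    aa[grepl("*", aa, fixed = TRUE)] <- NA_character_
    out[ok] <- aa
  }
  out
}

#' Extract peptide barcodes from reads and count them
#'
#' Locates the peptide-coding window via the left flank adapter, translates
#' it with the standard genetic code, and matches the translated k-mer
#' exactly against the library. Reads whose flank is absent, whose window is
#' incomplete or contains a stop codon, or whose peptide is not in the
#' library are tallied as unmatched.
#'
#' @param reads Named list of passing [fastq_records] (one per sample), or a
#'   single `fastq_records` (treated as one sample `"S1"`).
#' @param lib A [build_cterm_library] result.
#' @param flank Adapter context (see [default_flank_spec()]); the coding
#'   window is the `3*k` bases following `flank$left`.
#' @param qc_filter Optional named list of per-sample quality-filter QC rows
#'   (from [filter_reads]) merged into the table's QC.
#' @return A [screen_count_table] (un-normalized).
#' @export
extract_and_count <- function(reads, lib, flank = default_flank_spec(),
                              qc_filter = NULL) {
  stopifnot(inherits(lib, "peptide_library"))
  if (inherits(reads, "fastq_records")) reads <- list(S1 = reads)
  samples <- names(reads)
  k <- lib$k
  counts <- matrix(0L, nrow = length(lib$peptides), ncol = length(samples),
                   dimnames = list(lib$peptides, samples))
  qc <- data.frame(sample = samples, total = NA_integer_,
                   passed = NA_integer_, failed_quality = NA_integer_,
                   unmatched = 0L, stringsAsFactors = FALSE)
  for (si in seq_along(samples)) {
    rs <- reads[[si]]
    n <- nrow(rs)
    pos <- regexpr(flank$left, rs$sequence, fixed = TRUE)
    start <- ifelse(pos > 0L, pos + nchar(flank$left), NA_integer_)
    windows <- ifelse(is.na(start), NA_character_,
                      substr(rs$sequence, start, start + 3L * k - 1L))
    uw <- unique(windows[!is.na(windows)])
    pep_of <- translate_windows(uw, k)
    pep <- pep_of[match(windows, uw)]
    hit <- match(pep, lib$peptides)
    matched <- !is.na(hit)
    if (any(matched)) {
      tab <- tabulate(hit[matched], nbins = length(lib$peptides))
      counts[, si] <- tab
    }
    qc$unmatched[si] <- n - sum(matched)
    qc$passed[si] <- n
    if (!is.null(qc_filter) && !is.null(qc_filter[[samples[si]]])) {
      qf <- qc_filter[[samples[si]]]
      qc$total[si] <- qf$total
      qc$failed_quality[si] <- qf$failed_quality
    } else {
      qc$total[si] <- n
      qc$failed_quality[si] <- 0L
    }
  }
  screen_count_table(counts, qc = qc)
}

#' Normalize a count table to frequencies
#'
#' Per sample: `norm_freq = count / sample_total * scalar`. The per-sample
#' sums of `norm_freq` therefore equal the scalar exactly.
#'
#' @param table A [screen_count_table].
#' @param scalar Scalar factor (default `1e6`, i.e. counts per million).
#' @return The table with `norm_freq` and `scalar` populated.
#' @export
normalize_counts <- function(table, scalar = 1e6) {
  stopifnot(inherits(table, "screen_count_table"))
  totals <- colSums(table$counts)
  zero <- totals == 0
  if (any(zero)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(table$counts)[zero], collapse = ", "),
         call. = FALSE)
  }
  table$norm_freq <- sweep(table$counts, 2, totals, "/") * scalar
  table$scalar <- scalar
  table
}

#' Run the full FASTQ-to-counts readout
#'
#' Convenience wrapper: quality filter, barcode counting, normalization,
#' with complete per-sample QC.
#'
#' @param fastq Named list of [fastq_records] (or FASTQ paths), one per
#'   sample.
#' @inheritParams filter_reads
#' @inheritParams extract_and_count
#' @inheritParams normalize_counts
#' @return A normalized [screen_count_table].
#' @export
process_screen_fastq <- function(fastq, lib, flank = default_flank_spec(),
                                 min_mean_phred = 30, scalar = 1e6) {
  filtered <- lapply(fastq, filter_reads, min_mean_phred = min_mean_phred)
  tab <- extract_and_count(lapply(filtered, `[[`, "reads"), lib,
                           flank = flank,
                           qc_filter = lapply(filtered, `[[`, "qc"))
  normalize_counts(tab, scalar = scalar)
}

#' Write a count table (raw and normalized) as TSV
#'
#' @param table A [screen_count_table].
#' @param path Base path; raw counts go to `path`, normalized frequencies
#'   (when present) to `<path minus extension>_norm.tsv`.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "screen_count_table"))
  df <- data.frame(peptide = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(table$norm_freq)) {
    npath <- sub("\\.tsv$", "", path)
    df2 <- data.frame(peptide = rownames(table$norm_freq), table$norm_freq,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df2, paste0(npath, "_norm.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Read a raw count table from TSV
#'
#' @param path TSV written by [write_count_table] (peptide column plus one
#'   column per sample).
#' @return A [screen_count_table] (un-normalized).
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$peptide
  screen_count_table(m)
}
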