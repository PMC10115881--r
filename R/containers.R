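# Core S3 containers shared across modules.

#' Screen count table
#'
#' Per-sample peptide counts from a pooled screen, with optional normalized
#' frequencies (counts scaled to the per-sample total times a scalar factor)
#' and per-sample QC tallies.
#'
#' @param counts Integer matrix, peptides (rows, named) x samples (columns,
#'   named).
#' @param norm_freq Numeric matrix of the same shape, or `NULL` before
#'   normalization.
#' @param scalar The scalar factor applied during normalization (`NULL`
#'   before normalization).
#' @param qc Data frame with one row per sample and columns `sample`,
#'   `total`, `passed`, `failed_quality`, `unmatched`, or `NULL`.
#' @param meta Optional list of generator metadata (e.g. planted peptides).
#'
#' @return An object of class `screen_count_table`.
#' @export
screen_count_table <- function(counts, norm_freq = NULL, scalar = NULL,
                               qc = NULL, meta = list()) {
  if (!is.matrix(counts) || is.null(rownames(counts)) ||
      is.null(colnames(counts))) {
    stop("counts must be a matrix with peptide rownames and sample colnames",
         call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(counts = counts, norm_freq = norm_freq, scalar = scalar,
                 qc = qc, meta = meta),
            class = "screen_count_table")
}

#' @export
print.screen_count_table <- function(x, ...) {
  cat("screen_count_table:", nrow(x$counts), "peptides x",
      ncol(x$counts), "samples (", paste(colnames(x$counts), collapse = ", "),
      ")\n")
  cat("  depth:", paste(colSums(x$counts), collapse = ", "), "\n")
  if (!is.null(x$norm_freq)) {
    cat("  normalized (scalar =", format(x$scalar, big.mark = ","), ")\n")
  }
  invisible(x)
}

#' @export
dim.screen_count_table <- function(x) dim(x$counts)

#' In-memory FASTQ records
#'
#' A light container for reads: one row per read with its identifier,
#' nucleotide sequence and Sanger (Phred+33) quality string.
#'
#' @param id,sequence,quality Character vectors of equal length.
#' @return A data frame of class `fastq_records`.
#' @export
fastq_records <- function(id, sequence, quality) {
  if (length(sequence) != length(quality) || length(id) != length(sequence)) {
    stop("id, sequence and quality must have equal length", call. = FALSE)
  }
  bad <- which(nchar(sequence) != nchar(quality))
  if (length(bad) > 0L) {
    stop("malformed FASTQ record '", id[bad[1]],
         "': sequence and quality lengths differ", call. = FALSE)
  }
  structure(data.frame(id = id, sequence = sequence, quality = quality,
                       stringsAsFactors = FALSE),
            class = c("fastq_records", "data.frame"))
}

#' Write FASTQ records to a file
#'
#' @param reads A [fastq_records] object.
#' @param path Output path (plain text, Sanger Phred+33).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "fastq_records"))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$sequence, reads$id)),
    Biostrings::PhredQuality(reads$quality))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into records
#'
#' @param path FASTQ path (plain or gzip, Sanger Phred+33).
#' @return A [fastq_records] object.
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  fastq_records(id = if (is.null(names(x))) as.character(seq_along(x)) else
                  names(x),
                sequence = as.character(x),
                quality = as.character(Biostrings::quality(x)))
}

#' Concentration-polarization binding curve
#'
#' @param conc_uM Receptor (saturation) or competitor (competition)
#'   concentrations in micromolar.
#' @param mp Polarization readings in millipolarization units.
#' @param replicate Integer replicate index per point.
#' @param role `"saturation"` or `"competition"`.
#' @param probe_conc_nM Constant labeled-probe concentration (nM).
#' @param receptor_conc_uM Constant receptor concentration (µM; competition
#'   curves only).
#' @return A data frame of class `binding_curve` with attributes `role`,
#'   `probe_conc_nM` and `receptor_conc_uM`.
#' @export
binding_curve <- function(conc_uM, mp, replicate = 1L,
                          role = c("saturation", "competition"),
                          probe_conc_nM = 50, receptor_conc_uM = NA_real_) {
  role <- match.arg(role)
  if (any(conc_uM < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(!is.finite(mp))) stop("polarization values must be finite",
                                call. = FALSE)
  df <- data.frame(conc_uM = conc_uM, mp = mp,
                   replicate = rep_len(as.integer(replicate), length(conc_uM)))
  structure(df, class = c("binding_curve", "data.frame"),
            role = role, probe_conc_nM = probe_conc_nM,
            receptor_conc_uM = receptor_conc_uM)
}

#' Read a binding curve from CSV
#'
#' Expects columns `conc_uM`, `mp` and optionally `replicate`.
#'
#' @param path CSV path.
#' @inheritParams binding_curve
#' @return A [binding_curve].
#' @export
read_binding_curve <- function(path, role = "saturation", probe_conc_nM = 50,
                               receptor_conc_uM = NA_real_) {
  df <- utils::read.csv(path)
  if (!all(c("conc_uM", "mp") %in% names(df))) {
    stop("CSV must contain columns conc_uM and mp", call. = FALSE)
  }
  binding_curve(df$conc_uM, df$mp,
                replicate = if ("replicate" %in% names(df)) df$replicate else 1L,
                role = role, probe_conc_nM = probe_conc_nM,
                receptor_conc_uM = receptor_conc_uM)
}
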