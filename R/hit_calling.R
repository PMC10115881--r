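# Enrichment scoring of T0 vs selected samples, hit calling, and consensus
# across parallel screens.

# Pull a single sample's normalized frequencies + raw counts out of a
# screen_count_table (normalizing on the fly if needed).
sample_freqs <- function(table, sample = NULL, scalar = 1e6) {
  stopifnot(inherits(table, "screen_count_table"))
  if (is.null(table$norm_freq)) table <- normalize_counts(table, scalar)
  if (is.null(sample)) sample <- colnames(table$counts)[1]
  if (!sample %in% colnames(table$counts)) {
    stop("sample '", sample, "' not in table", call. = FALSE)
  }
  list(freq = table$norm_freq[, sample], counts = table$counts[, sample],
       scalar = table$scalar, total = sum(table$counts[, sample]))
}

#' Score peptide enrichment between T0 and selected samples
#'
#' For each peptide the score is `log2((f_sel + a_sel) / (f_T0 + a_T0))`
#' where `f` are normalized frequencies and the pseudocount `a` defaults,
#' per sample, to half a read in frequency units (`0.5 * scalar / total`),
#' keeping scores finite for peptides absent from one sample. Records are
#' ranked by selected-sample raw reads, descending, ties broken
#' lexicographically by peptide.
#'
#' @param t0,sel [screen_count_table] objects holding the pre-selection and
#'   selected samples. A single two-sample table may be passed as `t0` with
#'   `sel` missing, in which case its `"T0"`/first and `"selected"`/second
#'   columns are used.
#' @param pseudocount Frequency pseudocount; `NULL` (default) uses
#'   `0.5 * scalar / sample_total` per sample.
#' @param t0_sample,sel_sample Sample names to use within each table.
#' @return Data frame of class `enrichment_table` with columns `peptide`,
#'   `f_t0`, `f_sel`, `score`, `reads_sel`, `rank`, `is_hit` (NA until
#'   [call_hits]).
#' @export
score_enrichment <- function(t0, sel = NULL, pseudocount = NULL,
                             t0_sample = NULL, sel_sample = NULL) {
  if (is.null(sel)) {
    stopifnot(inherits(t0, "screen_count_table"), ncol(t0$counts) >= 2)
    cn <- colnames(t0$counts)
    if (is.null(t0_sample))
      t0_sample <- if ("T0" %in% cn) "T0" else cn[1]
    if (is.null(sel_sample))
      sel_sample <- if ("selected" %in% cn) "selected" else cn[2]
    sel <- t0
  }
  a <- sample_freqs(t0, t0_sample)
  b <- sample_freqs(sel, sel_sample)
  if (!identical(names(a$freq), names(b$freq))) {
    stop("T0 and selected tables cover different peptide universes",
         call. = FALSE)
  }
  alpha_t0 <- if (is.null(pseudocount)) 0.5 * a$scalar / a$total else
    pseudocount
  alpha_sel <- if (is.null(pseudocount)) 0.5 * b$scalar / b$total else
    pseudocount
  score <- log2((b$freq + alpha_sel) / (a$freq + alpha_t0))
  ord <- order(-b$counts, names(b$freq))
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  structure(data.frame(peptide = names(a$freq), f_t0 = unname(a$freq),
                       f_sel = unname(b$freq), score = unname(score),
                       reads_sel = unname(b$counts), rank = rank,
                       is_hit = NA, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("enrichment_table", "data.frame"))
}

#' Call hits from an enrichment table
#'
#' A peptide is a hit iff `score >= score_min` and `reads_sel >= reads_min`.
#'
#' @param records An `enrichment_table` from [score_enrichment].
#' @param score_min Minimum log2 enrichment score (default 3, i.e. 8-fold).
#' @param reads_min Minimum selected-sample raw reads (default 100).
#' @return The hit subset, ordered by `reads_sel` descending (ties broken by
#'   peptide), with `is_hit = TRUE`; the full scored table with `is_hit`
#'   populated is attached as attribute `"records"`.
#' @export
call_hits <- function(records, score_min = 3, reads_min = 100) {
  stopifnot(inherits(records, "enrichment_table"))
  records$is_hit <- records$score >= score_min & records$reads_sel >= reads_min
  hits <- records[records$is_hit, , drop = FALSE]
  hits <- hits[order(-hits$reads_sel, hits$peptide), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "records") <- records
  hits
}

#' Intersect hit sets across parallel screens
#'
#' @param per_screen_hits Non-empty (optionally named) list of hit tables
#'   from [call_hits].
#' @return Data frame with one row per peptide present in every screen's hit
#'   set, its per-screen ranks (`rank_<screen>` columns) and
#'   `rank1_everywhere` flagging a peptide ranked first in all screens.
#'   Ordered by total rank.
#' @export
intersect_screens <- function(per_screen_hits) {
  stopifnot(is.list(per_screen_hits), length(per_screen_hits) >= 1)
  nm <- names(per_screen_hits)
  if (is.null(nm)) nm <- paste0("screen", seq_along(per_screen_hits))
  common <- Reduce(intersect, lapply(per_screen_hits, `[[`, "peptide"))
  if (length(common) == 0L) {
    out <- data.frame(peptide = character(0), stringsAsFactors = FALSE)
    for (n in nm) out[[paste0("rank_", n)]] <- integer(0)
    out$rank1_everywhere <- logical(0)
    return(out)
  }
  ranks <- vapply(per_screen_hits, function(h)
    match(common, h$peptide[order(-h$reads_sel, h$peptide)]),
    integer(length(common)))
  ranks <- matrix(ranks, nrow = length(common),
                  dimnames = list(NULL, paste0("rank_", nm)))
  out <- data.frame(peptide = common, ranks, stringsAsFactors = FALSE)
  out$rank1_everywhere <- if (length(common)) rowSums(ranks == 1L) ==
    ncol(ranks) else logical(0)
  out[order(rowSums(ranks)), , drop = FALSE]
}

#' Write an enrichment table as TSV
#'
#' @param records An `enrichment_table` (or [call_hits] output).
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
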