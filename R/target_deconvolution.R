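# Map hit peptides onto PPI interface segments with bounded mismatches, rank
# candidate complexes by identity and disease-GO sharing, and propose
# extended peptide variants from the source chain.

# Hamming distance of `peptide` against every length-k window of `segment`;
# returns integer vector (one per window), or integer(0) if the segment is
# shorter than the peptide.
window_distances <- function(peptide, segment) {
  k <- nchar(peptide)
  n <- nchar(segment) - k + 1L
  if (n < 1L) return(integer(0))
  pep <- strsplit(peptide, "", fixed = TRUE)[[1]]
  seg <- strsplit(segment, "", fixed = TRUE)[[1]]
  # seg[i + j - 1] vs pep[j] for window i; vectorized over windows
  d <- integer(n)
  for (j in seq_len(k)) {
    d <- d + (seg[j:(j + n - 1L)] != pep[j])
  }
  d
}

#' Scan a peptide against all interface segments of a fixture
#'
#' Every length-k window of every interface segment whose Hamming distance
#' to the peptide is at most `max_mismatch` is reported. Per
#' (peptide, segment) the minimum-distance window is marked `best` (leftmost
#' on ties). Offsets are 1-based positions on the full chain. Each match also
#' carries the complex's shared disease-GO count (see [count_pd_go]).
#'
#' @param peptide Amino-acid string (non-empty).
#' @param fixture An `interface_fixture`.
#' @param max_mismatch Maximum Hamming distance (default 3).
#' @return Data frame with columns `peptide`, `complex_id`, `partner`,
#'   `offset`, `window`, `mismatches`, `identity`, `pd_go_count`, `best`.
#'   Zero rows when nothing matches.
#' @export
scan_peptide <- function(peptide, fixture, max_mismatch = 3) {
  if (!is.character(peptide) || length(peptide) != 1L || nchar(peptide) == 0L)
    stop("peptide must be a non-empty string", call. = FALSE)
  stopifnot(inherits(fixture, "interface_fixture"))
  k <- nchar(peptide)
  rows <- list()
  for (cx in fixture$complexes) {
    pdgo <- count_pd_go(cx, fixture$annotations, fixture$pd_terms)
    for (p in cx$partners) {
      segs <- cx$segments[[p]]
      if (is.null(segs) || nrow(segs) == 0L) next
      for (si in seq_len(nrow(segs))) {
        d <- window_distances(peptide, segs$sequence[si])
        ok <- which(d <= max_mismatch)
        if (length(ok) == 0L) next
        best_idx <- ok[which.min(d[ok])]  # leftmost minimum among kept
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = peptide, complex_id = cx$complex_id, partner = p,
          offset = segs$start[si] + ok - 1L,
          window = substring(segs$sequence[si], ok, ok + k - 1L),
          mismatches = d[ok], identity = (k - d[ok]) / k,
          pd_go_count = pdgo, best = ok == best_idx,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(peptide = character(0), complex_id = character(0),
                      partner = character(0), offset = integer(0),
                      window = character(0), mismatches = integer(0),
                      identity = numeric(0), pd_go_count = integer(0),
                      best = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count disease GO terms shared by both partners of a complex
#'
#' Returns the size of the three-way intersection of the disease term set
#' with both partners' annotation sets. A partner without annotations
#' contributes an empty set (with a message), giving 0.
#'
#' @param complex One element of `fixture$complexes`.
#' @param annotations Named list, protein id -> GO term character vector.
#' @param pd_terms Disease-enriched GO term set.
#' @return Non-negative integer.
#' @export
count_pd_go <- function(complex, annotations, pd_terms) {
  anns <- lapply(complex$partners, function(p) {
    a <- annotations[[p]]
    if (is.null(a)) {
      message("partner ", p, " has no GO annotations; treating as empty")
      character(0)
    } else a
  })
  length(Reduce(intersect, c(list(pd_terms), anns)))
}

#' Rank interface matches
#'
#' Sort order: mismatches ascending, shared disease-GO count descending,
#' complex id ascending (then partner and offset for full determinism);
#' 1-based ranks are assigned. The order is independent of the input row
#' permutation.
#'
#' @param matches A [scan_peptide] result (typically its `best` rows).
#' @return The same data frame, sorted, with a `rank` column.
#' @export
rank_matches <- function(matches) {
  stopifnot(is.data.frame(matches),
            all(c("mismatches", "pd_go_count", "complex_id") %in%
                  names(matches)))
  ord <- order(matches$mismatches, -matches$pd_go_count, matches$complex_id,
               matches$partner, matches$offset)
  out <- matches[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Propose extended peptide variants around a match window
#'
#' For each requested length `L >= k`, returns every substring of the match's
#' source chain of length `L` that fully contains the matched window, in
#' N-to-C order. Lengths exceeding the chain are skipped with a warning.
#'
#' @param match One row of a [scan_peptide] result (the best window).
#' @param lengths Integer vector of candidate lengths (residues).
#' @param fixture The `interface_fixture` the match came from.
#' @return Data frame with columns `length`, `start`, `sequence`.
#' @export
propose_extensions <- function(match, lengths, fixture) {
  stopifnot(is.data.frame(match), nrow(match) == 1L,
            inherits(fixture, "interface_fixture"))
  k <- nchar(match$window)
  if (any(lengths < k)) {
    stop("requested lengths must be >= the match window length (", k, ")",
         call. = FALSE)
  }
  idx <- which(vapply(fixture$complexes, function(cx)
    cx$complex_id == match$complex_id, logical(1)))
  if (length(idx) != 1L) stop("complex '", match$complex_id,
                              "' not found in fixture", call. = FALSE)
  chain <- fixture$complexes[[idx]]$chain_sequences[[match$partner]]
  n <- nchar(chain)
  w0 <- match$offset            # window occupies w0 .. w0 + k - 1 on chain
  out <- list()
  for (L in sort(unique(as.integer(lengths)))) {
    if (L > n) {
      warning("length ", L, " exceeds chain length ", n, "; skipped",
              call. = FALSE)
      next
    }
    starts <- max(1L, w0 + k - L):min(w0, n - L + 1L)
    starts <- starts[starts >= 1L & starts + L - 1L <= n &
                       starts <= w0 & starts + L >= w0 + k]
    if (length(starts) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      length = L, start = starts,
      sequence = substring(chain, starts, starts + L - 1L),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(length = integer(0), start = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Deconvolve a hit peptide against an interface fixture
#'
#' Convenience wrapper: scan, keep best windows per segment, rank.
#'
#' @inheritParams scan_peptide
#' @return A ranked match table (see [rank_matches]).
#' @export
deconvolve_peptide <- function(peptide, fixture, max_mismatch = 3) {
  m <- scan_peptide(peptide, fixture, max_mismatch)
  if (nrow(m) == 0L) return(rank_matches(m[, , drop = FALSE]))
  rank_matches(m[m$best, , drop = FALSE])
}
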