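# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately avoid the package's own vectorized code paths.

# Character-by-character Hamming distance.
oracle_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(av)) if (av[i] != bv[i]) n <- n + 1L
  n
}

# Exhaustive all-windows scan over a fixture: every window of every segment,
# plain loops, no marking of best windows.
oracle_scan <- function(peptide, fixture, max_mismatch) {
  k <- nchar(peptide)
  rows <- list()
  for (cx in fixture$complexes) {
    for (p in cx$partners) {
      segs <- cx$segments[[p]]
      for (si in seq_len(nrow(segs))) {
        seg <- segs$sequence[si]
        if (nchar(seg) < k) next
        for (w in 1:(nchar(seg) - k + 1)) {
          win <- substr(seg, w, w + k - 1)
          d <- oracle_hamming(peptide, win)
          if (d <= max_mismatch) {
            rows[[length(rows) + 1]] <- data.frame(
              complex_id = cx$complex_id, partner = p,
              offset = segs$start[si] + w - 1L, window = win,
              mismatches = d, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(complex_id = character(0), partner = character(0),
                      offset = integer(0), window = character(0),
                      mismatches = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$complex_id, out$partner, out$offset), , drop = FALSE]
}

# Bound-probe fraction of the competitive equilibrium by plain bisection on
# the free-receptor mass balance.
oracle_bound_fraction <- function(c_tot, ki, kd_probe, l_tot_nM, r_tot) {
  l <- l_tot_nM / 1000
  g <- function(r) r + l * r / (kd_probe + r) + c_tot * r / (ki + r) - r_tot
  lo <- 0
  hi <- r_tot
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  r <- (lo + hi) / 2
  r / (kd_probe + r)
}

# A tiny amino-acid-only peptide library (no proteome) for readout tests.
toy_library <- function(peptides) {
  structure(list(peptides = sort(peptides),
                 sources = setNames(as.list(sort(peptides)), sort(peptides)),
                 k = nchar(peptides[1])),
            class = "peptide_library")
}

# One-sample count table from a named count vector.
toy_count_table <- function(counts, sample = "S1") {
  m <- matrix(as.integer(counts), ncol = 1,
              dimnames = list(names(counts), sample))
  screen_count_table(m)
}

# Two-sample table (T0, selected) from two named count vectors over the same
# peptides.
toy_pair_table <- function(t0, sel) {
  stopifnot(identical(names(t0), names(sel)))
  m <- cbind(T0 = as.integer(t0), selected = as.integer(sel))
  rownames(m) <- names(t0)
  screen_count_table(m)
}

# Quality string of constant Phred q and length n.
qual_string <- function(q, n) strrep(intToUtf8(q + 33), n)

# Minimal single-complex fixture built by hand around a chain sequence.
hand_fixture <- function(chain, seg_start, seg_len,
                         partners = c("CHMP2B_like", "VPS4B_like"),
                         ann1 = character(0), ann2 = character(0),
                         pd_terms = character(0), complex_id = "2JQK") {
  chain2 <- strrep("G", nchar(chain))
  segs <- list(
    data.frame(start = seg_start,
               sequence = substr(chain, seg_start, seg_start + seg_len - 1L),
               stringsAsFactors = FALSE),
    data.frame(start = 1L, sequence = substr(chain2, 1, 8),
               stringsAsFactors = FALSE))
  names(segs) <- partners
  chains <- list(chain, chain2)
  names(chains) <- partners
  structure(list(
    complexes = list(list(complex_id = complex_id, partners = partners,
                          chain_sequences = chains, segments = segs)),
    annotations = setNames(list(ann1, ann2), partners),
    pd_terms = pd_terms),
    class = "interface_fixture")
}
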