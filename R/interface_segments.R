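# Derive interface segments from two-chain structure coordinates: a residue
# is interfacial iff any of its heavy atoms lies within a distance cutoff of
# any heavy atom of the other chain.

# Coerce coordinate input into a data.frame with columns chain, resno, x, y,
# z and optionally aa (one-letter residue code). Accepts a plain data.frame
# or a bio3d pdb object.
as_atom_table <- function(coords) {
  if (inherits(coords, "pdb")) {
    if (!requireNamespace("bio3d", quietly = TRUE)) {
      stop("reading bio3d pdb objects requires the bio3d package",
           call. = FALSE)
    }
    a <- coords$atom
    a <- a[a$elesy != "H" & a$type %in% c("ATOM", "HETATM"), , drop = FALSE]
    df <- data.frame(chain = a$chain, resno = a$resno,
                     x = a$x, y = a$y, z = a$z,
                     aa = unname(bio3d::aa321(a$resid)),
                     stringsAsFactors = FALSE)
    return(df)
  }
  stopifnot(is.data.frame(coords),
            all(c("chain", "resno", "x", "y", "z") %in% names(coords)))
  if ("element" %in% names(coords)) {
    coords <- coords[coords$element != "H", , drop = FALSE]
  }
  coords
}

# Squared cross-distances between two coordinate matrices.
cross_dist2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
}

# Collapse a sorted integer vector of interfacial residue numbers into
# maximal runs, bridging single-residue gaps, and keep runs spanning at
# least min_run residues.
residue_runs <- function(resnos, min_run) {
  if (length(resnos) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  resnos <- sort(unique(resnos))
  gaps <- diff(resnos)
  brk <- which(gaps > 2L)  # gap of <=1 missing residue is bridged
  starts <- resnos[c(1L, brk + 1L)]
  ends <- resnos[c(brk, length(resnos))]
  keep <- (ends - starts + 1L) >= min_run
  data.frame(start = starts[keep], end = ends[keep])
}

#' Extract interface segments from two-chain coordinates
#'
#' A residue is interfacial iff any of its heavy atoms lies within `cutoff`
#' angstroms of any heavy atom of the other chain. Maximal runs of
#' interfacial residues (single-residue gaps bridged) of span at least
#' `min_run` become segments, reported in 1-based chain coordinates. When
#' the input carries one-letter residue codes (`aa` column, or a bio3d pdb
#' object), segment sequences are reported too.
#'
#' @param coords A data frame with columns `chain`, `resno`, `x`, `y`, `z`
#'   and optionally `aa` and `element` (H atoms are dropped), or a
#'   `bio3d::read.pdb` object. Exactly two chains required.
#' @param cutoff Heavy-atom distance cutoff in angstroms (default 5).
#' @param min_run Minimum segment span in residues (default 5).
#' @return Named list (one element per chain) of data frames with columns
#'   `start`, `end` and `sequence` (`NA` when residue identities are
#'   unavailable).
#' @export
extract_interface_segments <- function(coords, cutoff = 5, min_run = 5) {
  atoms <- as_atom_table(coords)
  chains <- sort(unique(atoms$chain))
  if (length(chains) != 2L) {
    stop("exactly two chains required, got ", length(chains), call. = FALSE)
  }
  A <- atoms[atoms$chain == chains[1], , drop = FALSE]
  B <- atoms[atoms$chain == chains[2], , drop = FALSE]
  d2 <- cross_dist2(as.matrix(A[, c("x", "y", "z")]),
                    as.matrix(B[, c("x", "y", "z")]))
  close <- d2 <= cutoff^2
  ifaceA <- unique(A$resno[rowSums(close) > 0])
  ifaceB <- unique(B$resno[colSums(close) > 0])
  out <- list()
  for (ch in chains) {
    part <- if (ch == chains[1]) A else B
    iface <- if (ch == chains[1]) ifaceA else ifaceB
    runs <- residue_runs(iface, min_run)
    if (nrow(runs) > 0L && "aa" %in% names(part)) {
      res_aa <- tapply(part$aa, part$resno, `[`, 1)
      runs$sequence <- vapply(seq_len(nrow(runs)), function(i) {
        rs <- runs$start[i]:runs$end[i]
        paste(ifelse(is.na(res_aa[as.character(rs)]), "X",
                     res_aa[as.character(rs)]), collapse = "")
      }, character(1))
    } else {
      runs$sequence <- rep(NA_character_, nrow(runs))
    }
    out[[ch]] <- runs
  }
  out
}
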