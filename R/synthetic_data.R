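# Seeded generators for every input the pipeline consumes: proteomes,
# pooled-screen count tables, barcode FASTQ, FP binding curves and
# PPI-interface fixtures.

#' Configuration for the synthetic pooled screen
#'
#' The generative model: baseline library frequencies f are drawn from a
#' symmetric Dirichlet(alpha); the pre-selection (T0) sample is
#' multinomial(depth, f); selection reweights each peptide by a
#' multiplicative survival weight e (enrichment_factor for planted peptides,
#' 1 otherwise) and the selected sample is multinomial(depth, f*e / sum(f*e)).
#'
#' @param library_size Number of distinct peptides in the library.
#' @param planted_hits Number of peptides given the enrichment weight.
#' @param enrichment_factor Multiplicative survival weight of planted
#'   peptides (dimensionless; 1 is neutral).
#' @param depth Total reads per sample.
#' @param dirichlet_alpha Symmetric Dirichlet concentration for baseline
#'   frequencies.
#' @param seed Integer seed; all draws are reproducible given it.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(library_size = 5000, planted_hits = 10,
                              enrichment_factor = 50, depth = 1e6,
                              dirichlet_alpha = 1, seed = 11) {
  if (!is_count(library_size) || library_size < 1)
    stop("library_size must be a positive integer", call. = FALSE)
  if (!is_count(planted_hits) || planted_hits > library_size)
    stop("planted_hits must be an integer <= library_size", call. = FALSE)
  if (enrichment_factor < 0)
    stop("enrichment_factor must be >= 0", call. = FALSE)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  if (dirichlet_alpha <= 0) stop("dirichlet_alpha must be > 0", call. = FALSE)
  structure(list(library_size = as.integer(library_size),
                 planted_hits = as.integer(planted_hits),
                 enrichment_factor = enrichment_factor,
                 depth = depth, dirichlet_alpha = dirichlet_alpha,
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

#' Configuration for synthetic FP curves
#'
#' Defaults mirror the assay design: probe constant at 50 nM, receptor
#' serially diluted 1:1 from 30 uM over 12 points, 5 replicates; additive
#' Gaussian noise with s.d. 2 mp emulates typical plate-reader scatter.
#'
#' @param kd Generative dissociation constant (µM).
#' @param bmax Maximal specific polarization signal (mp).
#' @param background Polarization in the absence of receptor (mp).
#' @param hill Generative Hill coefficient (1 = single-site hyperbola).
#' @param noise_sd Additive Gaussian noise s.d. (mp).
#' @param replicates Number of replicate series.
#' @param series Receptor concentrations (µM), strictly decreasing when
#'   produced by 1:1 dilution.
#' @param probe_conc_nM Constant labeled-probe concentration (nM).
#' @param seed Integer seed.
#' @return An `fp_sim_config` list.
#' @export
fp_sim_config <- function(kd, bmax = 150, background = 50, hill = 1,
                          noise_sd = 2, replicates = 5,
                          series = 30 * 0.5^(0:11), probe_conc_nM = 50,
                          seed = 1) {
  if (kd <= 0) stop("kd must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(series <= 0)) stop("series concentrations must be > 0",
                             call. = FALSE)
  if (probe_conc_nM <= 0) stop("probe_conc_nM must be > 0", call. = FALSE)
  if (!is_count(replicates) || replicates < 1)
    stop("replicates must be a positive integer", call. = FALSE)
  structure(list(kd = kd, bmax = bmax, background = background, hill = hill,
                 noise_sd = noise_sd, replicates = as.integer(replicates),
                 series = series, probe_conc_nM = probe_conc_nM,
                 seed = as.integer(seed)),
            class = "fp_sim_config")
}

#' Generate a random proteome
#'
#' Uniform-residue random protein sequences with unique identifiers; a
#' stand-in for a real proteome when exercising the library-construction and
#' counting steps.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length_range Integer vector `c(min, max)` of sequence lengths
#'   (>= 1).
#' @param seed Integer seed.
#' @return An [Biostrings::AAStringSet] named `prot000001`, ...
#' @export
gen_proteome <- function(n_proteins, length_range = c(50, 500), seed = 1) {
  if (!is_count(n_proteins) || n_proteins < 1)
    stop("n_proteins must be a positive integer", call. = FALSE)
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1] > length_range[2])
    stop("invalid length_range", call. = FALSE)
  withr::with_seed(seed, {
    lens <- length_range[1] - 1L +
      sample.int(length_range[2] - length_range[1] + 1L, n_proteins,
                 replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), character(1))
  })
  names(seqs) <- sprintf("prot%06d", seq_len(n_proteins))
  Biostrings::AAStringSet(seqs)
}

#' Simulate pre- and post-selection screen counts
#'
#' @param cfg A [screen_sim_config].
#' @param library A [peptide_library] or character vector of peptides; its
#'   size must equal `cfg$library_size`.
#' @param baseline_freq Optional fixed baseline frequency vector (summing to
#'   1) to use instead of a fresh Dirichlet draw, e.g. to hold the library
#'   composition constant across seeds.
#' @return A [screen_count_table] with samples `T0` and `selected`; the
#'   planted peptides and their survival weights are recorded in `$meta`.
#' @export
gen_screen_counts <- function(cfg, library, baseline_freq = NULL) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  peptides <- if (inherits(library, "peptide_library")) library$peptides
              else as.character(library)
  if (length(peptides) == 0L) stop("library is empty", call. = FALSE)
  if (length(peptides) != cfg$library_size) {
    stop("library size (", length(peptides), ") != cfg$library_size (",
         cfg$library_size, ")", call. = FALSE)
  }
  n <- length(peptides)
  if (!is.null(baseline_freq) && (length(baseline_freq) != n ||
                                  abs(sum(baseline_freq) - 1) > 1e-8)) {
    stop("baseline_freq must have one probability per peptide, summing to 1",
         call. = FALSE)
  }
  withr::with_seed(cfg$seed, {
    f <- if (is.null(baseline_freq)) {
      g <- rgamma(n, shape = cfg$dirichlet_alpha)
      g / sum(g)
    } else baseline_freq
    planted <- sample(peptides, cfg$planted_hits)
    e <- rep(1, n)
    e[match(planted, peptides)] <- cfg$enrichment_factor
    t0 <- rmultinom(1, size = cfg$depth, prob = f)[, 1]
    fsel <- f * e
    sel <- rmultinom(1, size = cfg$depth, prob = fsel / sum(fsel))[, 1]
  })
  counts <- cbind(T0 = t0, selected = sel)
  rownames(counts) <- peptides
  screen_count_table(counts,
                     meta = list(planted = sort(planted),
                                 enrichment_factor = cfg$enrichment_factor,
                                 baseline_freq = setNames(f, peptides)))
}

# Enforce a per-read mean-quality bound by shifting whole reads down/up.
shift_read_means <- function(Q, idx, bound, above) {
  if (length(idx) == 0L) return(Q)
  m <- rowMeans(Q[idx, , drop = FALSE])
  if (above) { # reads must end up with mean > bound
    low <- which(m <= bound)
    if (length(low) > 0L)
      Q[idx[low], ] <- Q[idx[low], , drop = FALSE] +
        ceiling(bound + 1 - m[low])
  } else {     # reads must end up with mean <= bound
    high <- which(m > bound)
    if (length(high) > 0L)
      Q[idx[high], ] <- Q[idx[high], , drop = FALSE] -
        ceiling(m[high] - bound)
  }
  Q
}

#' Generate barcode-as-peptide FASTQ reads from a count table
#'
#' Emits one read per counted molecule per sample: the peptide's fixed-codon
#' coding sequence flanked by the adapter context, with per-base Sanger
#' qualities. A `fail_fraction` of reads receives qualities with per-read
#' mean at most 30 so they are removed by the downstream mean-Phred filter;
#' the rest have per-read mean strictly above 30.
#'
#' @param table A [screen_count_table].
#' @param codon_map Named residue-to-codon vector; every library residue must
#'   be mapped.
#' @param quality List with `mean_pass`, `mean_fail`, `sd` (Phred units).
#' @param fail_fraction Proportion of reads given low quality, in `[0, 1]`.
#' @param flank Adapter context, see [default_flank_spec()].
#' @param seed Integer seed.
#' @return Named list (one element per sample) of [fastq_records].
#' @export
gen_fastq <- function(table, codon_map = default_codon_map(),
                      quality = list(mean_pass = 37, mean_fail = 25, sd = 2),
                      fail_fraction = 0, flank = default_flank_spec(),
                      seed = 1) {
  stopifnot(inherits(table, "screen_count_table"))
  if (fail_fraction < 0 || fail_fraction > 1)
    stop("fail_fraction must be in [0, 1]", call. = FALSE)
  peptides <- rownames(table$counts)
  coding <- reverse_translate(peptides, codon_map)
  read_len <- nchar(flank$left) + nchar(coding[1]) + nchar(flank$right)
  out <- vector("list", ncol(table$counts))
  names(out) <- colnames(table$counts)
  withr::with_seed(seed, {
    for (s in colnames(table$counts)) {
      cnt <- table$counts[, s]
      idx <- rep.int(seq_along(peptides), cnt)
      idx <- sample(idx)               # shuffle read order
      n <- length(idx)
      seqs <- paste0(flank$left, coding[idx], flank$right)
      Q <- matrix(round(rnorm(n * read_len, sd = quality$sd)),
                  nrow = n, ncol = read_len)
      fail <- runif(n) < fail_fraction
      Q <- Q + ifelse(fail, quality$mean_fail, quality$mean_pass)
      Q <- shift_read_means(Q, which(fail), 30, above = FALSE)
      Q <- shift_read_means(Q, which(!fail), 30, above = TRUE)
      Q[Q < 2L] <- 2L
      Q[Q > 41L] <- 41L
      quals <- substring(rawToChar(as.raw(t(Q) + 33L)),
                         seq(1L, n * read_len, by = read_len),
                         seq_len(n) * read_len)
      out[[s]] <- fastq_records(id = sprintf("%s_read%07d", s, seq_len(n)),
                                sequence = seqs, quality = quals)
    }
  })
  out
}

#' Simulate a saturation FP binding curve
#'
#' Polarization is the single-site (optionally Hill) model evaluated on the
#' dilution series plus additive Gaussian noise.
#'
#' @param cfg An [fp_sim_config].
#' @return A [binding_curve] with `role = "saturation"`.
#' @export
gen_fp_curve <- function(cfg) {
  stopifnot(inherits(cfg, "fp_sim_config"))
  x <- rep(cfg$series, times = cfg$replicates)
  repl <- rep(seq_len(cfg$replicates), each = length(cfg$series))
  mu <- saturation_model(x, kd = cfg$kd, bmax = cfg$bmax,
                         background = cfg$background, h = cfg$hill)
  y <- withr::with_seed(cfg$seed, mu + rnorm(length(x), sd = cfg$noise_sd))
  binding_curve(x, y, replicate = repl, role = "saturation",
                probe_conc_nM = cfg$probe_conc_nM)
}

#' Simulate a competitive-displacement FP curve
#'
#' Competitor concentrations follow the assay's 1:1 dilution series; the
#' signal is the exact competitive-equilibrium model plus Gaussian noise.
#'
#' @param ki Generative competitor dissociation constant (µM).
#' @param kd_probe Probe-receptor dissociation constant (µM).
#' @param l_tot Probe concentration (nM; default 50).
#' @param r_tot Receptor concentration (µM; default 1).
#' @param bmax,background Signal parameters (mp).
#' @param noise_sd Gaussian noise s.d. (mp).
#' @param replicates Number of replicate series.
#' @param series Competitor concentrations (µM); a zero point is appended.
#' @param seed Integer seed.
#' @return A [binding_curve] with `role = "competition"`.
#' @export
gen_fp_competition <- function(ki, kd_probe, l_tot = 50, r_tot = 1,
                               bmax = 150, background = 50, noise_sd = 2,
                               replicates = 3, series = 30 * 0.5^(0:11),
                               seed = 1) {
  x <- rep(c(series, 0), times = replicates)
  repl <- rep(seq_len(replicates), each = length(series) + 1L)
  mu <- competition_signal(x, ki = ki, kd_probe = kd_probe, l_tot = l_tot,
                           r_tot = r_tot, bmax = bmax,
                           background = background)
  y <- withr::with_seed(seed, mu + rnorm(length(x), sd = noise_sd))
  binding_curve(x, y, replicate = repl, role = "competition",
                probe_conc_nM = l_tot, receptor_conc_uM = r_tot)
}

# Default synthetic GO universe: PD-flavored synthetic term ids.
default_go_universe <- function(n = 40) sprintf("GO:%07d", seq_len(n))

#' Generate a synthetic PPI-interface fixture
#'
#' Each complex has two protein partners with full chain sequences, one or
#' more interface segments per partner (substrings with 1-based start
#' coordinates), and per-protein GO annotations drawn from `go_universe`.
#' When `planted` is given, exactly one complex carries the planted segment
#' verbatim as an interface segment, and its two partners share a few
#' disease (PD) terms so the planted complex is prioritizable downstream.
#'
#' @param n_complexes Number of complexes (>= 0).
#' @param planted Optional `list(peptide =, segment =)`; the segment must be
#'   at least as long as the peptide.
#' @param go_universe Character vector of GO term ids.
#' @param pd_terms Disease-enriched GO subset (defaults to the first 8 terms
#'   of the universe).
#' @param chain_length Length of generated chains (residues).
#' @param seed Integer seed.
#' @return An object of class `interface_fixture`.
#' @export
gen_interface_fixture <- function(n_complexes, planted = NULL,
                                  go_universe = default_go_universe(),
                                  pd_terms = head(go_universe, 8),
                                  chain_length = 60, seed = 1) {
  if (!is_count(n_complexes)) stop("n_complexes must be a count",
                                   call. = FALSE)
  if (!is.null(planted)) {
    stopifnot(is.list(planted), !is.null(planted$peptide),
              !is.null(planted$segment))
    if (nchar(planted$segment) < nchar(planted$peptide))
      stop("planted segment must be at least as long as the peptide",
           call. = FALSE)
  }
  withr::with_seed(seed, {
    complexes <- vector("list", n_complexes)
    annotations <- list()
    planted_into <- if (n_complexes > 0 && !is.null(planted))
      sample(n_complexes, 1) else 0L
    for (i in seq_len(n_complexes)) {
      cid <- paste0(sample(1:9, 1),
                    paste(sample(c(LETTERS, 0:9), 3, replace = TRUE),
                          collapse = ""))
      partners <- sprintf("P%05d", sample(1e5, 2))
      chains <- setNames(vapply(1:2, function(j)
        paste(sample(AA20, chain_length, replace = TRUE), collapse = ""),
        character(1)), partners)
      segs <- list()
      for (p in partners) {
        start <- sample(seq_len(chain_length - 14L), 1)
        len <- sample(8:15, 1)
        segs[[p]] <- data.frame(
          start = start,
          sequence = substr(chains[[p]], start, start + len - 1L),
          stringsAsFactors = FALSE)
      }
      if (i == planted_into) {
        seg <- planted$segment
        pos <- sample(seq_len(chain_length - nchar(seg) + 1L), 1)
        chains[[partners[1]]] <- paste0(
          substr(chains[[partners[1]]], 1, pos - 1L), seg,
          substr(chains[[partners[1]]], pos + nchar(seg),
                 chain_length))
        segs[[partners[1]]] <- data.frame(start = pos, sequence = seg,
                                          stringsAsFactors = FALSE)
        shared <- sample(pd_terms, min(3, length(pd_terms)))
        annotations[[partners[1]]] <- shared
        annotations[[partners[2]]] <- shared
      } else {
        for (p in partners) {
          annotations[[p]] <- sort(sample(go_universe,
                                          sample(2:6, 1)))
        }
      }
      complexes[[i]] <- list(complex_id = cid, partners = partners,
                             chain_sequences = as.list(chains),
                             segments = segs)
    }
  })
  # guard the "exactly one" planted invariant against chance duplicates
  if (!is.null(planted) && n_complexes > 0) {
    for (i in seq_len(n_complexes)) {
      if (i == planted_into) next
      for (p in complexes[[i]]$partners) {
        if (grepl(planted$segment, complexes[[i]]$chain_sequences[[p]],
                  fixed = TRUE)) {
          stop("planted segment arose by chance in another complex; ",
               "use a different seed", call. = FALSE)
        }
      }
    }
  }
  structure(list(complexes = complexes, annotations = annotations,
                 pd_terms = pd_terms),
            class = "interface_fixture")
}

#' Write / read an interface fixture as JSON
#'
#' @param fixture An `interface_fixture`.
#' @param path JSON path.
#' @return `path` invisibly (write); the fixture (read).
#' @export
write_interface_fixture <- function(fixture, path) {
  stopifnot(inherits(fixture, "interface_fixture"))
  jsonlite::write_json(unclass(fixture), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_interface_fixture
#' @export
read_interface_fixture <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  complexes <- lapply(x$complexes, function(cx) {
    list(complex_id = cx$complex_id,
         partners = unlist(cx$partners),
         chain_sequences = lapply(cx$chain_sequences, unlist),
         segments = lapply(cx$segments, function(s)
           data.frame(start = vapply(s, function(r) as.integer(r$start),
                                     integer(1)),
                      sequence = vapply(s, function(r)
                        as.character(r$sequence), character(1)),
                      stringsAsFactors = FALSE)))
  })
  structure(list(complexes = complexes,
                 annotations = lapply(x$annotations, function(a)
                   unlist(a, use.names = FALSE)),
                 pd_terms = unlist(x$pd_terms, use.names = FALSE)),
            class = "interface_fixture")
}
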