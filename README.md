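# pepscreen

Analysis pipeline for **proteome-wide pooled peptide-inhibitor screens** in
which each short peptide's coding sequence doubles as its own sequencing
barcode, together with downstream **structural target deconvolution** and
**fluorescence-polarization (FP) binding analysis**. It is written for
groups running survival- or FACS-based selections of C-terminal peptide
libraries (e.g. against α-synuclein toxicity) who need a reproducible,
scriptable path from raw reads to ranked candidate target complexes and
binding constants.

## What it computes

1. **Library construction** — the C-terminal k-mer (default heptamer) of
   every protein in a proteome, deduplicated with merged
   peptide → source-protein maps (`build_cterm_library`).
2. **Screen readout** — FASTQ reads are kept iff their *mean* per-base
   Phred quality is strictly greater than 30, the peptide-coding window is
   translated and matched exactly against the library, and counts are
   normalized per sample to `count / total × S` with scalar `S = 10⁶`
   (`filter_reads`, `extract_and_count`, `normalize_counts`).
3. **Hit calling** — per-peptide enrichment between the pre-selection (T0)
   and selected populations,

   `score = log₂((f_sel + α) / (f_T0 + α))`,   α = ½·S / sample total,

   with hits defined by `score ≥ 3` and `selected reads ≥ 100`, ranked by
   selected-read abundance, and intersectable across parallel screens
   (`score_enrichment`, `call_hits`, `intersect_screens`).
4. **Target deconvolution** — mismatch-tolerant scanning (Hamming distance
   ≤ 3 by default) of hit peptides across the interface segments of a
   protein–protein-interaction fixture; candidate complexes ranked by
   mismatches, then by the number of disease-associated GO terms shared by
   *both* partners; extended peptide variants proposed from the source
   chain (`scan_peptide`, `count_pd_go`, `rank_matches`,
   `propose_extensions`). Interface segments can be derived from two-chain
   coordinates with a 5 Å heavy-atom cutoff (`extract_interface_segments`).
5. **Binding models** — single-site FP saturation
   `Y = Bmax·X/(Kd + X) + Background` (optionally with Hill exponent `h`
   for the *h ≈ 1* single-site check) and the exact two-ligand one-site
   competitive equilibrium, solved via the free-receptor mass-balance root,
   for Ki/IC50 from displacement series (`fit_saturation`,
   `competition_signal`, `fit_competition`).
6. **Synthetic data** — seeded generators for every input above
   (`gen_proteome`, `gen_screen_counts`, `gen_fastq`, `gen_fp_curve`,
   `gen_fp_competition`, `gen_interface_fixture`), so the full pipeline is
   testable without any wet-lab data.

## Worked example

```r
library(pepscreen)

prot <- gen_proteome(2000, c(20, 40), seed = 101)
lib  <- build_cterm_library(prot, k = 7)
cfg  <- screen_sim_config(library_size = length(lib$peptides),
                          planted_hits = 10, enrichment_factor = 50,
                          depth = 1e6, seed = 11)
tab  <- gen_screen_counts(cfg, lib)
fq   <- gen_fastq(tab, fail_fraction = 0.05, seed = 12)

counts <- process_screen_fastq(fq, lib)
counts$qc
#>     sample   total passed failed_quality unmatched
#> 1       T0 1000000 950163          49837         0
#> 2 selected 1000000 950171          49829         0

hits <- call_hits(score_enrichment(counts), score_min = 3, reads_min = 100)
head(hits[, c("peptide", "f_t0", "f_sel", "score", "reads_sel")], 5)
#>   peptide      f_t0     f_sel    score reads_sel
#> 1 PWDWMTN 1623.9319 69072.830 5.410099     65631
#> 2 VHWQPTA 1018.7726 41590.408 5.350620     39518
#> 3 GYASTLH  236.8015  8384.807 5.142916      7967
#> 4 RQNKEMA  183.1265  8289.034 5.496244      7876
#> 5 PVQEPKG  151.5529  6848.241 5.492950      6507
setequal(hits$peptide, tab$meta$planted)
#> [1] TRUE
```

Each row is one called hit: `f_t0`/`f_sel` are reads-per-million before and
after selection, `score` the log₂ enrichment, and `reads_sel` the raw
selected-sample abundance that sets the rank. All ten peptides planted at
50-fold enrichment — and nothing else — are recovered.

Fitting a simulated FP saturation series (probe 50 nM, twelve 1:1 dilutions
from 30 µM, 5 replicates, 2 mp noise, generative Kd = 1.8 µM):

```r
fit <- fit_saturation(gen_fp_curve(fp_sim_config(kd = 1.8, seed = 1)),
                      fit_hill = TRUE)
fit
#> Saturation FP fit (60 points):converged
#>   kd               1.76  +/- 0.0343
#>   bmax            149.1  +/- 0.684
#>   background      50.16  +/- 0.402
#>   Hill variant: h = 0.975 +/- 0.020  (F = 1.6, p = 0.212)
```

The Hill exponent sits within 0.1 of 1 (F test non-significant), the
expected signature of single-site binding.

## Command line

A thin dispatcher over the same functions ships at
`inst/cli/pepscreen.R` (`system.file("cli", "pepscreen.R",
package = "pepscreen")`), with subcommands `simulate`, `build-library`,
`count`, `call-hits`, `deconvolve`, `fit-fp` and `fit-competition`.

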