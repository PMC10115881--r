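---
title: "pepscreen: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pepscreen: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreen)
```

pepscreen implements the computational side of a pooled peptide-inhibitor
screen: a lentiviral library of C-terminal heptamers is delivered at low
multiplicity of infection, cells are subjected to a selection (survival
under proteotoxic stress, or FACS on an oligomerization reporter), and the
peptides of the surviving population are read out by sequencing — the
peptide's own coding sequence is the barcode. Downstream, hit peptides are
mapped onto protein–protein-interaction (PPI) interfaces to nominate the
target complex, extended along the source chain, and characterized by
fluorescence polarization (FP). This vignette documents the models, the
defaults and their units, the numerical choices, and what the synthetic
data do and do not establish.

## The generative screen model

The synthetic screen (`gen_screen_counts`) is the simplest exchangeable
model consistent with a pooled library at low MOI:

* baseline frequencies $f \sim \mathrm{Dirichlet}(\alpha\mathbf{1})$ with
  $\alpha = 1$ by default;
* the pre-selection sample is $\mathrm{Multinomial}(D, f)$ at depth
  $D = 10^6$ reads;
* selection multiplies each peptide's frequency by a survival weight
  $e_i$ ($e_i = 50$ for the planted "protective" peptides, 1 otherwise)
  and the selected sample is
  $\mathrm{Multinomial}\!\left(D, \; f e / \textstyle\sum_j f_j e_j\right)$.

The default design point — a 5,000-peptide library, 10 planted peptides at
50-fold enrichment, depth $10^6$ — is the reference configuration used
throughout the tests and the acceptance script. Column sums of the count
table equal $D$ exactly, and, holding $f$ fixed, the Monte-Carlo mean of a
planted peptide's selected frequency converges on the closed form
$f_i e_i / \sum_j f_j e_j$ (checked over 200 seeded replicates).

Neither the real screen's sequencing depth per sample nor its survivor
fraction is published; both are therefore declared defaults of the
generator, not inferred quantities. The generator deliberately omits PCR
amplification bias, substitution-type sequencing error and cell-growth
dynamics during selection, so passing tests say nothing about those
effects in real data.

## Read architecture and readout

`gen_fastq` emits one read per counted molecule: a fixed left adapter, the
peptide's coding sequence under a fixed one-codon-per-residue table, and a
fixed right adapter. Because the screen treats the amino-acid sequence as
the barcode, codon degeneracy carries no information and a deterministic
reverse translation keeps reads short and exactly invertible. The real
assay's read layout (adapter positions, offsets) is not published, so the
flank specification is an explicit configuration
(`default_flank_spec()`) rather than a discovered constant.

Quality filtering keeps a read iff its arithmetic mean per-base Phred
score is **strictly greater than 30**. Both choices — strictness at the
boundary and averaging integer Phred values rather than error
probabilities — are declared, testable conventions. Counting is exact:
the coding window located after the left flank is translated with the
standard genetic code and matched verbatim against the library; reads with
a missing flank, a stop codon, or no library match are tallied as
unmatched, never rescued. Normalization is counts per sample total times a
scalar $S = 10^6$ (reads-per-million); the per-sample normalized
frequencies sum to $S$ by construction.

## Hit calling

Survivor sequencing is itself the selection in the wet assay, so no
published statistic exists to re-implement. The package's declared
stand-in is a pseudocounted log-ratio,

$$\mathrm{score}_i \;=\; \log_2\!\frac{f^{sel}_i + \alpha_{sel}}
                                      {f^{T0}_i + \alpha_{T0}},
\qquad \alpha = \tfrac{1}{2}\,S/\text{sample total},$$

i.e. half a read in frequency units, which keeps scores finite and
antisymmetric under sample swap. A peptide is a hit iff its score is at
least 3 (8-fold) **and** its selected-sample raw count is at least 100;
hits are ranked by selected reads (ties broken lexicographically for
determinism), matching the "most abundant hit" convention used to pick
the lead peptide. `intersect_screens` reports peptides present in every
parallel screen's hit set and flags one that is rank 1 everywhere.

Two design notes. First, the abundance *rank* is meaningful within the
called hit set, not across the whole library: under a Dirichlet(1)
baseline, a genuinely enriched but rare peptide can carry fewer raw reads
than the most abundant neutral peptides, so recovery of planted peptides
is assessed by score ordering (top-10 scores are the 10 planted peptides
in 99 of 100 seeded replicates at the default design point), while raw
abundance orders the final hit list. Second, no replicate-aware count
model or FDR control is attempted — with 50-fold planted effects and a
null distribution tightly concentrated near score 0 (mean hits < 0.5 over
50 null screens), thresholding is sufficient at this design point; screens
with subtle enrichment would need a proper count model.

## Target deconvolution

`scan_peptide` slides the hit peptide along every interface segment of a
fixture of structure complexes and reports every window at Hamming
distance at most 3 (the declared mismatch ceiling); per segment, the
minimum-distance window is marked best, leftmost on ties. Sequence
identity is reported as $(k - \text{mismatches})/k$; ranking uses the
integer mismatch count directly (the ordering is equivalent and exact).
Candidate complexes are ordered by mismatches ascending, then by the
number of disease-associated GO terms shared — interpreted as the
intersection of the disease term set with **both** partners' annotations;
the looser union reading was considered and rejected because a term
carried by only one partner says nothing about the interface — then by
complex id, partner and offset so that the ranking is a total order,
independent of input permutation.

`propose_extensions` enumerates, for each requested length $L \ge k$,
every substring of the source chain of length $L$ fully containing the
best-match window, N-to-C — the computational counterpart of extending a
minimal motif hit toward the full native segment (e.g. a 7-mer MIM-like
hit extended to 10- and 12-mers along an ESCRT-III C-terminus).

Where the curated fixture must be built from coordinates,
`extract_interface_segments` declares a residue interfacial iff any heavy
atom lies within 5 Å of the partner chain, bridges single-residue gaps,
and keeps runs spanning at least 5 residues. The cutoff and minimum run
length replace the visual discard of crystal-packing contacts with two
explicit parameters; there is no human-in-the-loop step. Reported
coordinates are 1-based inclusive.

The synthetic fixture (`gen_interface_fixture`) plants a known segment in
exactly one complex and gives that complex's partners shared disease
terms; it emulates recoverability, not the size or redundancy of the real
PDB interface universe.

## FP binding models

Saturation: $Y = B_{max} X^h/(K_d^h + X^h) + \mathrm{Background}$, with
$h = 1$ the default single-site hyperbola, $X$ in µM and $Y$ in
millipolarization units (mp). The free-ligand approximation ($X$ = total
receptor) is appropriate because the labeled probe is held at 50 nM, far
below the µM-range $K_d$ values of interest. The default simulated design
mirrors the assay: probe 50 nM, receptor serially diluted 1:1 from 30 µM
over 12 points, 5 replicates, additive Gaussian noise of 2 mp (typical
plate-reader scatter; the real spread is not published). Fits are
nonlinear least squares (`minpack.lm::nlsLM`) over all replicate points,
initialized at $\mathrm{Background} = \min Y$,
$B_{max} = \max Y - \min Y$, $K_d$ at the half-range crossing and
$h = 1$ — robust for monotone curves. The Hill check reports $h$ with its
standard error plus an extra-sum-of-squares F statistic against the
$h = 1$ model. Non-convergence returns a flagged result, not an error.
Background may be fixed to the zero-receptor reading or fitted; fitted is
the default since the original analysis does not say.

Competition: for competitor total $C$, probe total $L$, receptor total
$R$, the free receptor concentration $R_f$ solves the exact mass balance

$$R = R_f\left(1 + \frac{L}{K_d^{probe} + R_f}
                 + \frac{C}{K_i + R_f}\right),$$

which is strictly increasing in $R_f$, so the root on $[0, R]$ is unique;
it is located by `uniroot` and polished with Newton steps to conserve all
three totals to $10^{-10}$ relative tolerance. The signal is
$\mathrm{Background} + B_{max}\, R_f/(K_d^{probe}+R_f)$ (the bound-probe
fraction). `fit_competition` fits $K_i$ on a log scale (with $B_{max}$
and Background unless fixed), and derives the IC50 numerically as the
midpoint of the fitted zero-competitor signal and the background plateau.
In the classical regime ($L, R \ll K_d^{probe}$) the fitted $K_i$ agrees
with the Cheng–Prusoff form $IC_{50}/(1 + L/K_d^{probe})$ to within 5%.
When the fitted $K_i$ exceeds the top assayed concentration or its
standard error exceeds the estimate, the result is flagged unidentifiable
and reported as a lower bound ("> 30 µM" style), the honest summary for
weak binders whose displacement never develops inside the series.
Internally all concentrations are µM (probe 50 nM = 0.05 µM).

## Problem sizes and determinism

Every generator takes an integer seed and is bit-reproducible given it
(RNG state is isolated with `withr::with_seed`). The test suite runs the
screen end-to-end at the full default design point (two samples of $10^6$
reads each, about one minute) and keeps every other simulation at small
n: 100-replicate recovery sweeps at the default design, 50-seed null
screens, 200-replicate Monte-Carlo means, and randomized oracle
comparisons (brute-force window scans, bisection equilibria) on
fixtures of a few complexes. The acceptance script reruns only the
saturation fits and the count-table design point, and finishes in
seconds.

## Known limitations

* Exact barcode matching: a single sequencing error loses the read. At
  mean Phred 37 this wastes little depth, but error-tolerant rescue is
  deliberately out of scope.
* The enrichment score has no variance model; it is calibrated for strong
  (tens-fold) effects.
* The interface fixture abstracts the PDB: redundancy, crystal-packing
  artifacts and obligate-complex annotation noise are not emulated.
* The competitive model assumes one site and no ternary complex;
  cooperative or allosteric displacement would need a different model.
* The ligand-depletion (quadratic) saturation model is intentionally not
  implemented; at probe concentrations approaching $K_d$ the reported
  $K_d$ would be biased upward.
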