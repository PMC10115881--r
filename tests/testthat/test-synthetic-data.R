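# Generators: determinism, conservation laws, and agreement with the
# generative model they claim to implement.

test_that("gen_proteome respects boundaries, seeds, and residue composition", {
  one <- gen_proteome(1, c(7, 7), seed = 1)
  expect_length(one, 1)
  expect_equal(Biostrings::width(one), 7)

  a <- gen_proteome(100, c(50, 500), seed = 7)
  b <- gen_proteome(100, c(50, 500), seed = 7)
  expect_identical(as.character(a), as.character(b))

  # residue composition ~ uniform over the 20 letters (chi-square GOF)
  tab <- table(strsplit(paste(as.character(a), collapse = ""), "")[[1]])
  expect_setequal(names(tab), c("A", "C", "D", "E", "F", "G", "H", "I", "K",
                                "L", "M", "N", "P", "Q", "R", "S", "T", "V",
                                "W", "Y"))
  gof <- suppressWarnings(stats::chisq.test(as.vector(tab)))
  expect_gt(gof$p.value, 1e-4)

  expect_error(gen_proteome(1, c(10, 5)), "length_range")
  expect_error(gen_proteome(0, c(5, 10)), "n_proteins")
})

test_that("gen_screen_counts conserves depth and follows the planted model", {
  peps <- sprintf("PEP%04d", 1:500)
  cfg <- screen_sim_config(library_size = 500, planted_hits = 10,
                           enrichment_factor = 50, depth = 1e5, seed = 11)
  tab <- gen_screen_counts(cfg, peps)
  expect_identical(unname(colSums(tab$counts)), c(1e5, 1e5))
  expect_identical(tab$counts,
                   gen_screen_counts(cfg, peps)$counts) # seed-deterministic

  # every planted peptide's selected frequency exceeds its T0 frequency
  ntab <- normalize_counts(tab)
  planted <- tab$meta$planted
  expect_length(planted, 10)
  expect_true(all(ntab$norm_freq[planted, "selected"] >
                    ntab$norm_freq[planted, "T0"]))

  expect_error(gen_screen_counts(cfg, character(0)), "empty")
  expect_error(gen_screen_counts(cfg, peps[1:10]), "library_size")
})

test_that("null screens differ from T0 only by resampling noise", {
  peps <- sprintf("PEP%03d", 1:200)
  cfg <- screen_sim_config(library_size = 200, planted_hits = 0,
                           enrichment_factor = 1, depth = 1e5, seed = 3)
  ntab <- normalize_counts(gen_screen_counts(cfg, peps))
  # frequency differences centred at zero, bounded by multinomial noise
  d <- ntab$norm_freq[, "selected"] - ntab$norm_freq[, "T0"]
  expect_lt(abs(mean(d)), 10)
  expect_lt(max(abs(d)) / ntab$scalar, 0.01)
})

test_that("selected-frequency expectation matches the closed form", {
  # Hold the baseline composition fixed, draw 200 seeded replicates through
  # the generator, and compare the Monte-Carlo mean of the planted peptides'
  # selected frequencies with f_i * e / sum(f * e).
  peps <- sprintf("P%02d", 1:50)
  f <- withr::with_seed(42, { g <- rgamma(50, 1); g / sum(g) })
  e_factor <- 20
  depth <- 2e4

  reps <- vapply(1:200, function(s) {
    cfg <- screen_sim_config(library_size = 50, planted_hits = 5,
                             enrichment_factor = e_factor, depth = depth,
                             seed = s)
    gen_screen_counts(cfg, peps, baseline_freq = f)$counts[, "selected"]
  }, numeric(50)) / depth
  mc_mean <- rowMeans(reps)

  # planted identity varies by seed, so compare against the seed-averaged
  # closed form: for each seed the expectation is f*e/sum(f*e) with that
  # seed's planted set
  expected <- rowMeans(vapply(1:200, function(s) {
    cfg <- screen_sim_config(library_size = 50, planted_hits = 5,
                             enrichment_factor = e_factor, depth = depth,
                             seed = s)
    planted <- gen_screen_counts(cfg, peps, baseline_freq = f)$meta$planted
    e <- rep(1, 50)
    e[match(planted, peps)] <- e_factor
    f * e / sum(f * e)
  }, numeric(50)))
  expect_equal(unname(mc_mean), unname(expected), tolerance = 0.05)
})

test_that("gen_fastq conserves molecule counts and encodes valid records", {
  tab <- toy_count_table(c(AAAAAAA = 2, CCCCCCC = 3))
  fq <- gen_fastq(tab, seed = 5)
  expect_named(fq, "S1")
  expect_identical(nrow(fq$S1), 5L)
  expect_true(all(nchar(fq$S1$sequence) == nchar(fq$S1$quality)))

  # fail_fraction = 0: every read passes the downstream mean-Phred>30 filter
  keep <- filter_reads(fq$S1, 30)
  expect_identical(keep$qc$failed_quality, 0L)

  # fail reads carry mean quality <= 30
  fq2 <- gen_fastq(toy_count_table(c(AAAAAAA = 200)), fail_fraction = 1,
                   seed = 6)
  expect_identical(filter_reads(fq2$S1, 30)$qc$passed, 0L)

  expect_identical(gen_fastq(tab, seed = 5)$S1, fq$S1)
  expect_error(gen_fastq(toy_count_table(c(AAAAXAA = 1))), "codon")
})

test_that("gen_fp_curve reproduces the model exactly at zero noise", {
  kd <- 1.8
  cfg <- fp_sim_config(kd = kd, noise_sd = 0, replicates = 1,
                       series = c(30, 10, kd, 0.5, 0.1), seed = 1)
  curve <- gen_fp_curve(cfg)
  expect_equal(curve$mp,
               saturation_model(curve$conc_uM, kd, 150, 50, 1),
               tolerance = 1e-12)
  # half-saturation point exact
  expect_equal(curve$mp[curve$conc_uM == kd], 50 + 150 / 2)
  # X = 0 gives background through the model itself
  expect_equal(saturation_model(0, kd, 150, 50), 50)
})

test_that("gen_fp_curve noise has the configured spread", {
  cfg <- fp_sim_config(kd = 1.8, noise_sd = 2, replicates = 50, seed = 8)
  curve <- gen_fp_curve(cfg)
  mu <- saturation_model(curve$conc_uM, 1.8, 150, 50)
  expect_equal(stats::sd(curve$mp - mu), 2, tolerance = 0.15)
})

test_that("gen_interface_fixture plants exactly one recoverable segment", {
  fx <- gen_interface_fixture(
    6, planted = list(peptide = "IPIQLKA", segment = "DEEIERQLKALG"),
    seed = 5)
  hits <- scan_peptide("IPIQLKA", fx, max_mismatch = 3)
  expect_gte(nrow(hits), 1)
  carriers <- vapply(fx$complexes, function(cx)
    any(vapply(cx$partners, function(p)
      grepl("DEEIERQLKALG", cx$chain_sequences[[p]], fixed = TRUE),
      logical(1))), logical(1))
  expect_identical(sum(carriers), 1L)

  empty <- gen_interface_fixture(0, seed = 1)
  expect_length(empty$complexes, 0)
  expect_identical(nrow(scan_peptide("IPIQLKA", empty)), 0L)

  expect_identical(write_interface_fixture(fx, f1 <- tempfile()),
                   f1)
  fx2 <- gen_interface_fixture(
    6, planted = list(peptide = "IPIQLKA", segment = "DEEIERQLKALG"),
    seed = 5)
  expect_equal(unclass(fx), unclass(fx2))
})

test_that("interface fixtures survive a JSON round trip", {
  fx <- gen_interface_fixture(4, seed = 9)
  path <- tempfile(fileext = ".json")
  write_interface_fixture(fx, path)
  fx2 <- read_interface_fixture(path)
  expect_equal(unclass(fx), unclass(fx2))
})
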