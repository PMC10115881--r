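# Saturation and competitive FP binding models and their fits.

test_that("the saturation model obeys its limiting values", {
  expect_equal(saturation_model(0, 1.8, 150, 50), 50)
  expect_equal(saturation_model(1.8, 1.8, 150, 50), 50 + 75)
  expect_lt(abs(saturation_model(1.8e6, 1.8, 150, 50) - 200), 1e-4 * 150)
  # strictly increasing in X
  x <- sort(withr::with_seed(4, runif(50, 0, 100)))
  y <- saturation_model(x, 2, 100, 10)
  expect_true(all(diff(y) > 0))
  expect_error(saturation_model(1, kd = 0, 100, 10), "kd")
  expect_error(saturation_model(-1, kd = 1, 100, 10), ">= 0")
})

test_that("noiseless saturation data identify all parameters", {
  cfg <- fp_sim_config(kd = 1.8, bmax = 150, background = 50, noise_sd = 0,
                       seed = 1)
  fit <- fit_saturation(gen_fp_curve(cfg), fit_hill = FALSE)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["kd"]), 1.8, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["bmax"]), 150, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["background"]), 50, tolerance = 1e-3)
})

test_that("noisy saturation fits recover Kd within uncertainty", {
  cfg <- fp_sim_config(kd = 1.8, noise_sd = 2, replicates = 5, seed = 2)
  fit <- fit_saturation(gen_fp_curve(cfg), fit_hill = TRUE)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["kd"]] - 1.8), 3 * fit$se[["kd"]])
  # Hill variant on h = 1 data returns h close to 1
  expect_lt(abs(fit$hill$estimates[["h"]] - 1), 0.1)

  # grid-search oracle cross-check on the same data: the nls optimum must
  # beat or match every coarse-grid candidate's RSS
  curve <- gen_fp_curve(cfg)
  grid <- expand.grid(kd = seq(1, 3, by = 0.1),
                      bmax = seq(140, 160, by = 2),
                      background = seq(45, 55, by = 1))
  rss <- vapply(seq_len(nrow(grid)), function(i)
    sum((curve$mp - saturation_model(curve$conc_uM, grid$kd[i],
                                     grid$bmax[i], grid$background[i]))^2),
    numeric(1))
  expect_lte(fit$rss, min(rss) + 1e-8)
})

test_that("fixed-parameter fit modes honor the constraint", {
  cfg <- fp_sim_config(kd = 1.8, noise_sd = 1, seed = 5)
  curve <- gen_fp_curve(cfg)
  fb <- fit_saturation(curve, fit_hill = FALSE, fix_background = 50)
  expect_identical(unname(fb$estimates["background"]), 50)
  expect_false("background" %in% names(fb$se))
  expect_equal(unname(fb$estimates["kd"]), 1.8, tolerance = 0.1)
})

test_that("insufficient designs are rejected", {
  short <- binding_curve(c(1, 2, 3), c(10, 20, 30))
  expect_error(fit_saturation(short), ">= 4")
  four <- binding_curve(c(1, 2, 3, 4), c(10, 20, 25, 28))
  expect_error(fit_saturation(four, fit_hill = TRUE), ">= 5")
})

test_that("competition signal has the right limits and monotonicity", {
  # no competitor: equals the saturation prediction in the free ~ total
  # regime (probe 50 nM well below both Kd and receptor)
  y0 <- competition_signal(0, ki = 0.64, kd_probe = 1.8, l_tot = 50,
                           r_tot = 1, bmax = 150, background = 50)
  ysat <- saturation_model(1, 1.8, 150, 50)
  expect_equal(y0, ysat, tolerance = 0.01)
  # full displacement approaches background
  yinf <- competition_signal(1e7, 0.64, 1.8, 50, 1, 150, 50)
  expect_lt(yinf - 50, 0.01)
  # strictly decreasing in competitor concentration
  cc <- c(0, 10^seq(-3, 2, length.out = 30))
  y <- competition_signal(cc, 0.64, 1.8, 50, 1, 150, 50)
  expect_true(all(diff(y) < 0))
})

test_that("the equilibrium solver matches a bisection oracle and conserves mass", {
  draws <- withr::with_seed(77, data.frame(
    c_tot = 10^runif(25, -3, 2), ki = 10^runif(25, -2, 2),
    kd_probe = 10^runif(25, -2, 1.5), l_tot = runif(25, 10, 500),
    r_tot = 10^runif(25, -1, 1)))
  for (i in seq_len(nrow(draws))) {
    d <- draws[i, ]
    y <- competition_signal(d$c_tot, d$ki, d$kd_probe, d$l_tot, d$r_tot,
                            bmax = 1, background = 0)
    want <- oracle_bound_fraction(d$c_tot, d$ki, d$kd_probe, d$l_tot,
                                  d$r_tot)
    expect_equal(y, want, tolerance = 1e-8)

    sp <- pepscreen:::competition_species(d$c_tot, d$ki, d$kd_probe,
                                          d$l_tot, d$r_tot)
    expect_equal(sp$R + sp$RL + sp$RC, d$r_tot, tolerance = 1e-10)
    expect_equal(sp$L + sp$RL, d$l_tot / 1000, tolerance = 1e-10)
    expect_equal(sp$C + sp$RC, d$c_tot, tolerance = 1e-10)
  }
})

test_that("competition fits recover Ki and derive a consistent IC50", {
  noiseless <- gen_fp_competition(ki = 0.64, kd_probe = 1.8, noise_sd = 0,
                                  seed = 3)
  f0 <- fit_competition(noiseless, kd_probe = 1.8)
  expect_true(f0$converged)
  expect_true(f0$identifiable)
  expect_equal(f0$ki, 0.64, tolerance = 1e-3)

  noisy <- gen_fp_competition(ki = 0.64, kd_probe = 1.8, noise_sd = 2,
                              seed = 3)
  fn <- fit_competition(noisy, kd_probe = 1.8)
  expect_lt(abs(fn$ki - 0.64), 3 * fn$ki_se)

  # IC50 sits at the fitted curve's half-displacement point
  ymid <- competition_signal(f0$ic50, f0$ki, 1.8, 50, 1, f0$bmax,
                             f0$background)
  y0 <- competition_signal(0, f0$ki, 1.8, 50, 1, f0$bmax, f0$background)
  expect_equal(ymid, (y0 + f0$background) / 2, tolerance = 1e-6)
  expect_gte(f0$ic50, f0$ki)
})

test_that("weak binders beyond the series are flagged as lower bounds", {
  weak <- gen_fp_competition(ki = 1000, kd_probe = 1.8, noise_sd = 2,
                             seed = 4)
  fw <- fit_competition(weak, kd_probe = 1.8)
  expect_false(fw$identifiable)
  expect_identical(fw$ki_lower_bound, 30)
})

test_that("Ki approaches IC50/(1 + L/Kd) in the Cheng-Prusoff regime", {
  # probe and receptor far below the probe Kd
  curve <- gen_fp_competition(ki = 0.5, kd_probe = 10, l_tot = 5,
                              r_tot = 0.01, noise_sd = 0,
                              series = 30 * 0.5^(0:14), seed = 6)
  fit <- fit_competition(curve, kd_probe = 10)
  cp_ki <- fit$ic50 / (1 + (5 / 1000) / 10)
  expect_equal(fit$ki, cp_ki, tolerance = 0.05)
})
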