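# Fluorescence-polarization binding models: single-site saturation (with
# optional Hill coefficient) and exact two-ligand one-site competitive
# equilibria, plus their nonlinear least-squares fits.

#' Single-site saturation binding model
#'
#' `Y = Bmax * X^h / (Kd^h + X^h) + Background`, with `h = 1` the standard
#' hyperbola. X is taken as the free receptor concentration (free ~= total
#' when the labeled probe is well below Kd).
#'
#' @param x Receptor concentrations (µM, >= 0).
#' @param kd Dissociation constant (µM, > 0).
#' @param bmax Maximal specific signal (mp).
#' @param background Signal at zero receptor (mp).
#' @param h Hill coefficient (default 1).
#' @return Predicted polarization (mp).
#' @export
saturation_model <- function(x, kd, bmax, background, h = 1) {
  if (any(kd <= 0)) stop("kd must be > 0", call. = FALSE)
  if (any(x < 0)) stop("x must be >= 0", call. = FALSE)
  xh <- x^h
  bmax * xh / (kd^h + xh) + background
}

# Shared guts of the two fitters: run nlsLM, harvest estimates/SEs/RSS and a
# convergence flag instead of throwing.
run_nls <- function(formula, data, start, lower = NULL, upper = NULL) {
  fit <- tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = start,
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(ok = FALSE, message = conditionMessage(fit),
                estimates = setNames(rep(NA_real_, length(start)),
                                     names(start)),
                se = setNames(rep(NA_real_, length(start)), names(start)),
                rss = NA_real_, df = NA_integer_, fit = NULL))
  }
  sm <- summary(fit)
  est <- coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  list(ok = TRUE, message = "converged", estimates = est,
       se = setNames(se[names(est)], names(est)),
       rss = sum(residuals(fit)^2), df = df.residual(fit), fit = fit)
}

#' Fit the saturation binding model
#'
#' Nonlinear least squares over all replicate points. With
#' `fit_hill = TRUE`, both the fixed-`h = 1` and the free-Hill variants are
#' fitted; `h` with its standard error and an extra-sum-of-squares F test
#' are reported for the "h close to 1" single-site check.
#'
#' @param curve A [binding_curve] with `role = "saturation"` and at least 4
#'   distinct concentrations (5 for the Hill variant).
#' @param fit_hill Also fit the Hill variant? (default `TRUE`).
#' @param fix_background,fix_bmax Optional fixed values; `NULL` (default)
#'   fits them.
#' @return Object of class `saturation_fit`: estimates (`kd`, `bmax`,
#'   `background`, and for the Hill variant `h`), standard errors, residual
#'   sum of squares, convergence flag; when `fit_hill`, elements `hill`
#'   (its own fit summary) and `hill_test` (F statistic, df, p-value).
#' @export
fit_saturation <- function(curve, fit_hill = TRUE, fix_background = NULL,
                           fix_bmax = NULL) {
  stopifnot(inherits(curve, "binding_curve"))
  nx <- length(unique(curve$conc_uM))
  if (nx < 4) stop("need >= 4 distinct concentrations", call. = FALSE)
  if (fit_hill && nx < 5) stop("need >= 5 distinct concentrations for the ",
                               "Hill variant", call. = FALSE)
  d <- data.frame(x = curve$conc_uM, y = curve$mp)
  bg0 <- if (is.null(fix_background)) min(d$y) else fix_background
  bm0 <- if (is.null(fix_bmax)) max(d$y) - min(d$y) else fix_bmax
  kd0 <- stats::approx(d$y, d$x, xout = bg0 + bm0 / 2, ties = mean,
                       rule = 2)$y
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(d$x[d$x > 0])

  terms <- c(kd = "kd",
             bmax = if (is.null(fix_bmax)) "bmax" else
               format(fix_bmax, digits = 15),
             background = if (is.null(fix_background)) "background" else
               format(fix_background, digits = 15))
  f1 <- stats::as.formula(paste0(
    "y ~ ", terms["bmax"], " * x / (kd + x) + ", terms["background"]))
  start1 <- c(list(kd = kd0),
              if (is.null(fix_bmax)) list(bmax = bm0),
              if (is.null(fix_background)) list(background = bg0))
  base <- run_nls(f1, d, start1,
                  lower = c(kd = 1e-9, bmax = 1e-9,
                            background = -Inf)[names(start1)],
                  upper = rep(Inf, length(start1)))

  res <- list(estimates = c(base$estimates,
                            if (!is.null(fix_bmax)) c(bmax = fix_bmax),
                            if (!is.null(fix_background))
                              c(background = fix_background)),
              se = base$se, rss = base$rss, df = base$df,
              converged = base$ok, message = base$message,
              n = nrow(d))
  if (fit_hill) {
    f2 <- stats::as.formula(paste0(
      "y ~ ", terms["bmax"], " * x^h / (kd^h + x^h) + ",
      terms["background"]))
    start2 <- c(start1, list(h = 1))
    hillfit <- run_nls(f2, d, start2,
                       lower = c(kd = 1e-9, bmax = 1e-9,
                                 background = -Inf,
                                 h = 1e-3)[names(start2)],
                       upper = rep(Inf, length(start2)))
    res$hill <- list(estimates = hillfit$estimates, se = hillfit$se,
                     rss = hillfit$rss, df = hillfit$df,
                     converged = hillfit$ok)
    if (base$ok && hillfit$ok && hillfit$df > 0) {
      fstat <- max(0, (base$rss - hillfit$rss)) / 1 /
        (hillfit$rss / hillfit$df)
      res$hill_test <- list(F = fstat, df1 = 1, df2 = hillfit$df,
                            p = stats::pf(fstat, 1, hillfit$df,
                                          lower.tail = FALSE))
    }
  }
  structure(res, class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("Saturation FP fit (", x$n, " points):",
      if (x$converged) "converged" else paste("NOT converged:", x$message),
      "\n", sep = "")
  est <- x$estimates
  for (p in names(est)) {
    cat(sprintf("  %-10s %10.4g", p, est[[p]]))
    if (!is.null(x$se) && p %in% names(x$se) && is.finite(x$se[[p]]))
      cat(sprintf("  +/- %.3g", x$se[[p]]))
    cat("\n")
  }
  if (!is.null(x$hill) && x$hill$converged) {
    cat(sprintf("  Hill variant: h = %.3f +/- %.3f",
                x$hill$estimates[["h"]], x$hill$se[["h"]]))
    if (!is.null(x$hill_test))
      cat(sprintf("  (F = %.3g, p = %.3g)", x$hill_test$F, x$hill_test$p))
    cat("\n")
  }
  invisible(x)
}

# Free-receptor concentration solving the two-ligand one-site mass balance:
#   R_tot = R + L_tot R/(KdL + R) + C_tot R/(Ki + R).
# Monotone in R, so the root on [0, R_tot] is unique; uniroot then Newton
# polish for near machine-precision conservation.
solve_free_receptor <- function(r_tot, l_tot, c_tot, kd_probe, ki) {
  g <- function(r) r * (1 + l_tot / (kd_probe + r) + c_tot / (ki + r)) -
    r_tot
  if (r_tot == 0) return(0)
  r <- uniroot(g, lower = 0, upper = r_tot,
               tol = .Machine$double.eps^0.75 * max(1, r_tot))$root
  for (i in 1:4) {
    gp <- 1 + l_tot * kd_probe / (kd_probe + r)^2 +
      c_tot * ki / (ki + r)^2
    r_new <- r - g(r) / gp
    if (is.finite(r_new) && r_new > 0) r <- r_new
  }
  r
}

#' Exact competitive-displacement FP signal
#'
#' Solves the two-ligand (labeled probe + unlabeled competitor), one-site
#' competitive equilibrium exactly via the free-receptor root of the mass
#' balances, then returns
#' `Y = Background + Bmax * (bound probe fraction)` where the bound probe
#' fraction is `R_free / (Kd_probe + R_free)`.
#'
#' @param c_tot Competitor concentrations (µM, >= 0; vectorized).
#' @param ki Competitor dissociation constant (µM, > 0).
#' @param kd_probe Probe dissociation constant (µM, > 0).
#' @param l_tot Total probe concentration (nM, > 0).
#' @param r_tot Total receptor concentration (µM, > 0).
#' @param bmax,background Signal parameters (mp).
#' @return Predicted polarization (mp), one value per competitor
#'   concentration.
#' @export
competition_signal <- function(c_tot, ki, kd_probe, l_tot = 50, r_tot = 1,
                               bmax = 150, background = 50) {
  if (ki <= 0 || kd_probe <= 0 || l_tot <= 0 || r_tot <= 0)
    stop("ki, kd_probe, l_tot and r_tot must all be > 0", call. = FALSE)
  if (any(c_tot < 0)) stop("competitor concentrations must be >= 0",
                           call. = FALSE)
  l_uM <- l_tot / 1000
  rfree <- vapply(c_tot, function(cc)
    solve_free_receptor(r_tot, l_uM, cc, kd_probe, ki), numeric(1))
  background + bmax * rfree / (kd_probe + rfree)
}

# Bound/free species table for the competitive equilibrium (used by the
# conservation checks).
competition_species <- function(c_tot, ki, kd_probe, l_tot = 50, r_tot = 1) {
  l_uM <- l_tot / 1000
  r <- solve_free_receptor(r_tot, l_uM, c_tot, kd_probe, ki)
  rl <- l_uM * r / (kd_probe + r)
  rc <- c_tot * r / (ki + r)
  list(R = r, RL = rl, RC = rc, L = l_uM - rl, C = c_tot - rc)
}

#' Fit a competitive-displacement curve
#'
#' Least-squares fit of the competitor dissociation constant Ki (and, unless
#' fixed, Bmax and Background) to a displacement series; Ki is fitted on a
#' log scale for stability. The IC50 is located numerically as the
#' competitor concentration at the midpoint of the fitted zero-competitor
#' signal and the background plateau. When the fitted Ki exceeds the top
#' assayed concentration, or its standard error exceeds the estimate itself,
#' the constant is reported as a lower bound (`identifiable = FALSE`), the
#' "> top concentration" style of report used for weak binders.
#'
#' @param curve A [binding_curve] with `role = "competition"`; its
#'   `probe_conc_nM` and `receptor_conc_uM` attributes supply the fixed
#'   totals.
#' @param kd_probe Probe-receptor dissociation constant (µM), from the
#'   saturation fit.
#' @param fix_bmax,fix_background Optional fixed signal parameters.
#' @return Object of class `competition_fit`: `ki` (µM), `ic50` (µM),
#'   standard errors, `identifiable`, `ki_lower_bound`, convergence flag,
#'   and the fixed inputs.
#' @export
fit_competition <- function(curve, kd_probe, fix_bmax = NULL,
                            fix_background = NULL) {
  stopifnot(inherits(curve, "binding_curve"))
  if (!identical(attr(curve, "role"), "competition"))
    stop("curve role must be 'competition'", call. = FALSE)
  l_tot <- attr(curve, "probe_conc_nM")
  r_tot <- attr(curve, "receptor_conc_uM")
  if (!is.finite(r_tot)) stop("receptor_conc_uM attribute required",
                              call. = FALSE)
  d <- data.frame(x = curve$conc_uM, y = curve$mp)
  bg0 <- if (is.null(fix_background)) min(d$y) else fix_background
  bm0 <- if (is.null(fix_bmax)) max(d$y) - min(d$y) else fix_bmax
  mid <- bg0 + bm0 / 2
  xpos <- d$x[d$x > 0]
  ki0 <- stats::approx(d$y, d$x, xout = mid, ties = mean, rule = 2)$y
  if (!is.finite(ki0) || ki0 <= 0) ki0 <- stats::median(xpos)

  pred <- function(x, log_ki, bmax, background) {
    competition_signal(x, ki = exp(log_ki), kd_probe = kd_probe,
                       l_tot = l_tot, r_tot = r_tot, bmax = bmax,
                       background = background)
  }
  fml <- if (is.null(fix_bmax) && is.null(fix_background)) {
    y ~ pred(x, log_ki, bmax, background)
  } else if (is.null(fix_bmax)) {
    y ~ pred(x, log_ki, bmax, fix_background)
  } else if (is.null(fix_background)) {
    y ~ pred(x, log_ki, fix_bmax, background)
  } else {
    y ~ pred(x, log_ki, fix_bmax, fix_background)
  }
  start <- c(list(log_ki = log(ki0)),
             if (is.null(fix_bmax)) list(bmax = bm0),
             if (is.null(fix_background)) list(background = bg0))
  ft <- run_nls(fml, d, start)
  ki_hat <- unname(exp(ft$estimates[["log_ki"]]))
  ki_se <- if (ft$ok) unname(ki_hat * ft$se[["log_ki"]]) else NA_real_
  bmax_hat <- if (is.null(fix_bmax)) unname(ft$estimates[["bmax"]]) else
    fix_bmax
  bg_hat <- if (is.null(fix_background))
    unname(ft$estimates[["background"]]) else fix_background

  top <- max(d$x)
  identifiable <- isTRUE(ft$ok) && is.finite(ki_hat) && ki_hat <= top &&
    is.finite(ki_se) && ki_se < ki_hat
  ic50 <- NA_real_
  if (isTRUE(ft$ok) && is.finite(ki_hat)) {
    y0 <- competition_signal(0, ki_hat, kd_probe, l_tot, r_tot, bmax_hat,
                             bg_hat)
    target <- (y0 + bg_hat) / 2
    gfun <- function(cc) competition_signal(cc, ki_hat, kd_probe, l_tot,
                                            r_tot, bmax_hat, bg_hat) - target
    upper <- max(top, ki_hat) * 1e4
    ic50 <- tryCatch(uniroot(gfun, lower = 1e-12, upper = upper,
                             tol = 1e-10)$root,
                     error = function(e) NA_real_)
  }
  structure(list(ki = ki_hat, ki_se = ki_se, ic50 = ic50,
                 bmax = bmax_hat, background = bg_hat,
                 identifiable = identifiable,
                 ki_lower_bound = if (identifiable) NA_real_ else top,
                 converged = ft$ok, message = ft$message, rss = ft$rss,
                 kd_probe = kd_probe, l_tot_nM = l_tot, r_tot_uM = r_tot,
                 n = nrow(d)),
            class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  cat("Competition FP fit (", x$n, " points):",
      if (x$converged) "converged" else paste("NOT converged:", x$message),
      "\n", sep = "")
  if (x$identifiable) {
    cat(sprintf("  Ki   = %.4g uM +/- %.3g\n  IC50 = %.4g uM\n",
                x$ki, x$ki_se, x$ic50))
  } else {
    cat(sprintf("  Ki > %.3g uM (unidentifiable above top concentration)\n",
                x$ki_lower_bound))
  }
  invisible(x)
}

#' Write a fit result as a JSON report
#'
#' @param fit A `saturation_fit` or `competition_fit`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  x$fit <- NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
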