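test_that("log-normal band has the declared mode, width and support", {
  b <- lognormal_band(2.5, 350, 60, 1.4)
  expect_equal(eval_lognormal_band(b, 350), 2.5)
  # FWHM: half-maximum points straddle the peak with ratio = asymmetry
  f <- function(l) eval_lognormal_band(b, l) - 1.25
  lo <- stats::uniroot(f, c(300, 350))$root
  hi <- stats::uniroot(f, c(350, 500))$root
  expect_equal(hi - lo, 60, tolerance = 1e-6)
  expect_equal((hi - 350) / (350 - lo), 1.4, tolerance = 1e-6)
  # zero at and beyond the support edge
  edge <- 350 - 60 * 1.4 / (1.4^2 - 1)
  expect_identical(eval_lognormal_band(b, edge - 1), 0)
  expect_identical(eval_lognormal_band(b, 100), 0)
})

test_that("band area matches an independent quadrature of the closed form", {
  b <- lognormal_band(1, 340, 60, 1.4)
  # independent: fine trapezoidal rule on the closed form
  grid <- seq(150, 1200, by = 0.01)
  y <- eval_lognormal_band(b, grid)
  trap <- sum((y[-1] + y[-length(y)]) / 2) * 0.01
  expect_equal(rsdomain:::lognormal_band_area(b), trap, tolerance = 1e-6)
})

test_that("two-band deconvolution recovers known bands", {
  wl <- 280:400
  tyr <- lognormal_band(40, 303, 34, 1.45)
  trp <- lognormal_band(100, 350, 60, 1.48)
  spec <- emission_spectrum(wl, eval_lognormal_band(tyr, wl) +
                              eval_lognormal_band(trp, wl))
  d <- deconvolute_spectrum(spec)
  expect_true(d$converged)
  expect_lt(abs(d$tyr_band$amplitude - 40) / 40, 0.005)
  expect_lt(abs(d$trp_band$amplitude - 100) / 100, 0.005)
  expect_lt(d$residual_rms, 1e-3)
  # permuted initial guesses give the identical result
  d2 <- deconvolute_spectrum(spec, init = list(tyr = trp, trp = tyr))
  expect_equal(d2$tyr_band, d$tyr_band, tolerance = 1e-6)
  # single-band (Trp-only) input: Tyr amplitude collapses
  spec1 <- emission_spectrum(wl, eval_lognormal_band(trp, wl))
  d1 <- deconvolute_spectrum(spec1)
  expect_lt(d1$tyr_band$amplitude, 0.01 * d1$trp_band$amplitude)
})

test_that("FirbY-W ratio is the Tyr/Trp intensity ratio", {
  t1 <- lognormal_band(2, 303, 34, 1.45)
  t2 <- lognormal_band(4, 350, 60, 1.48)
  expect_equal(compute_firby_ratio(t1, t2), 0.5)
  expect_equal(compute_firby_ratio(t2, t2), 1.0)
  expect_gt(compute_firby_ratio(t1, t2, mode = "area"), 0)
  expect_error(compute_firby_ratio(t1, lognormal_band(0, 350, 60, 1.5)),
               "undefined")
})

test_that("two-state model has exact midpoint, limits and monotonicity", {
  # midpoint identity: x = dG/m gives (N + D) / 2
  expect_equal(eval_unfolding_ratio(1.91, 1.91, 1.0, 0.5, 1.5), 1.0)
  # folded baseline at x = 0 with large dG
  expect_equal(eval_unfolding_ratio(0, 50, 1.0, 0.5, 1.5), 0.5,
               tolerance = 1e-10)
  # denatured limit
  expect_equal(eval_unfolding_ratio(500, 1.91, 1.0, 0.5, 1.5), 1.5,
               tolerance = 1e-10)
  # frozen independent evaluation of the closed form at x = 0, T = 295 K:
  # exponent = -1.91 / (1.987e-3 * 295) = -3.25855, ratio = 0.537024
  expect_equal(eval_unfolding_ratio(0, 1.91, 1.0, 0.5, 1.5, 295), 0.537024,
               tolerance = 1e-5)
  # monotone increasing in urea when D > N and m > 0
  x <- seq(0, 8, by = 0.25)
  y <- eval_unfolding_ratio(x, 1.91, 1.0, 0.5, 1.5)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 0.5 & y <= 1.5))
})

test_that("unfolding fit recovers generating parameters from ratio curves", {
  x <- seq(0, 7, length.out = 15)
  for (dg in c(1.91, -0.44)) {
    y <- eval_unfolding_ratio(x, dg, 1.0, 0.5, 1.5)
    fit <- fit_unfolding(unfolding_series(x, y))
    expect_true(fit$identifiable)
    expect_lt(abs(fit$dg - dg), ifelse(dg > 0, 1e-3, 0.02))
    expect_lt(abs(fit$m_value - 1.0), 0.02)
    # fitted midpoint equals the half-transition point of the fitted curve
    cm <- fit$midpoint_M
    half <- (fit$n_base + fit$d_base) / 2
    expect_equal(eval_unfolding_ratio(cm, fit$dg, fit$m_value, fit$n_base,
                                      fit$d_base), half, tolerance = 1e-6)
  }
  # constant series has no transition
  flat <- fit_unfolding(unfolding_series(x, rep(1, 15)))
  expect_false(flat$identifiable)
})

test_that("spectra generator and full deconvolution pipeline round-trip", {
  gen <- gen_config(seed = 5, noise_sd = 0)
  x <- seq(0, 7, by = 0.5)
  sp <- generate_spectra_series(1.91, 1.0, 0.5, 1.5, x, gen = gen)
  expect_length(sp, length(x))
  # generated peak-intensity ratio follows the two-state model: midpoint
  ratios <- vapply(sp, function(s) {
    d <- deconvolute_spectrum(s)
    compute_firby_ratio(d$tyr_band, d$trp_band)
  }, numeric(1))
  expect_equal(ratios, eval_unfolding_ratio(x, 1.91, 1.0, 0.5, 1.5),
               tolerance = 1e-3)
  fit <- fit_unfolding(unfolding_series(x, ratios))
  expect_lt(abs(fit$dg - 1.91) / 1.91, 0.01)
  expect_lt(abs(fit$m_value - 1.0), 0.01)
  # determinism with noise
  g <- gen_config(seed = 9, noise_sd = 1)
  expect_identical(generate_spectra_series(1.91, 1, 0.5, 1.5, x, gen = g),
                   generate_spectra_series(1.91, 1, 0.5, 1.5, x, gen = g))
  expect_error(generate_spectra_series(1.91, 1, 0.5, 1.5, c(0, 9), gen = gen),
               "urea")
  expect_error(
    generate_spectra_series(1.91, 1, 0.5, 1.5, x,
                            band_params = list(trp = list(amplitude = 0)),
                            gen = gen),
    "amplitude"
  )
})
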