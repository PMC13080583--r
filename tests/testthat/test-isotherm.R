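# Independent oracle for the bound fraction: numerical root of
# KD = (PT - b)(LT - b)/b for the bound concentration b.
theta_root_oracle <- function(pt, lt, kd) {
  if (pt == 0) return(0)
  b <- stats::uniroot(function(b) (pt - b) * (lt - b) / b - kd,
                      lower = 1e-12, upper = min(pt, lt) * (1 - 1e-12),
                      tol = 1e-14)$root
  b / lt
}

test_that("isotherm evaluation matches the quadratic-root oracle and limits", {
  # frozen from theta_root_oracle(200, 10, 200): theta = 0.49375098,
  # FP = 50 + theta * 200 = 148.750196
  expect_equal(eval_isotherm(200, 10, 200, 50, 250), 148.750196,
               tolerance = 1e-6)
  for (pt in c(5, 50, 500, 5000)) {
    expect_equal(eval_isotherm(pt, 10, 200, 0, 1),
                 theta_root_oracle(pt, 10, 200), tolerance = 1e-9)
  }
  # no titrant -> baseline; saturation -> fmax
  expect_identical(eval_isotherm(0, 10, 200, 50, 250), 50)
  expect_lt(abs(eval_isotherm(1e9 * 200, 10, 200, 50, 250) - 250), 1e-6 * 200)
  # lt = 0 analytic limit and the lt -> 0 hyperbolic reduction
  expect_equal(eval_isotherm(200, 0, 200, 0, 1), 0.5)
  lt <- 1e-6 * 200
  pts <- c(10, 100, 1000)
  expect_equal(eval_isotherm(pts, lt, 200, 0, 1), pts / (pts + 200),
               tolerance = 1e-6)
  expect_error(eval_isotherm(-1, 10, 200, 50, 250), "non-negative")
})

test_that("bound fraction is within [0,1] and monotone in titrant and Kd", {
  pts <- 10^seq(-2, 5, length.out = 40)
  kds <- c(0.5, 20, 800, 1e5)
  for (kd in kds) {
    th <- (eval_isotherm(pts, 10, kd, 0, 1))
    expect_true(all(th >= 0 & th <= 1))
    expect_true(all(diff(th) > 0))  # increasing in PT
  }
  for (pt in c(1, 100, 10000)) {
    th_kd <- vapply(kds, function(kd) eval_isotherm(pt, 10, kd, 0, 1),
                    numeric(1))
    expect_true(all(diff(th_kd) < 0))  # decreasing in KD
  }
})

test_that("noiseless round-trip recovers the generating Kd", {
  gen <- gen_config(seed = 7, noise_sd = 0)
  for (kd in c(9, 200, 780)) {
    cur <- generate_titration(kd, 10, 50, 250, 8000, 14, gen)
    fit <- fit_isotherm(cur)
    expect_true(fit$converged)
    expect_true(fit$determinable)
    expect_lt(abs(fit$kd - kd) / kd, 1e-3)
  }
})

test_that("replicate fitting reports spread across replicates", {
  gen <- gen_config(seed = 11, noise_sd = 5, n_replicates = 3)
  cur <- generate_titration(200, 10, 50, 250, 8000, 14, gen)
  fit <- fit_isotherm(cur)
  expect_identical(fit$n_replicates, 3L)
  expect_identical(fit$kd_sd_kind, "replicate")
  expect_length(fit$replicate_kd, 3L)
  expect_gte(fit$kd_sd, 0)
  expect_lt(abs(fit$kd - 200) / 200, 0.25)
})

test_that("estimator is approximately unbiased at the triplicate design", {
  # noise 5 mP, probe 10 nM, top 8000 nM, 2-fold dilutions, triplicates
  for (kd in c(9, 200, 780)) {
    est <- vapply(1:70, function(s) {
      cur <- generate_titration(kd, 10, 50, 250, 8000, 14,
                                gen_config(seed = s, noise_sd = 5,
                                           n_replicates = 3))
      fit_isotherm(cur)$kd
    }, numeric(1))
    expect_lt(abs(stats::median(est) - kd) / kd, 0.05)
  }
})

test_that("non-determinable affinities are classified as such", {
  # fitted Kd above the top titrant concentration
  fake <- list(kd = 5 * 8000, fmin = 50, fmax = 250, converged = TRUE,
               residual_rms = 2)
  expect_false(classify_determinability(fake, 8000))
  expect_identical(attr(classify_determinability(fake, 8000), "rule"),
                   "kd_above_top")
  # clean strong binder is determinable
  ok <- list(kd = 200, fmin = 50, fmax = 250, converged = TRUE,
             residual_rms = 2)
  expect_true(classify_determinability(ok, 8000))
  # constant-FP curve: no signal
  flat <- titration_curve(8000 / 2^(0:13), rep(100, 14), 10)
  ffit <- fit_isotherm(flat)
  expect_false(ffit$determinable)
  # very weak binder under the standard design: rule fires almost always
  hits <- vapply(1:100, function(s) {
    cur <- generate_titration(1e6, 10, 50, 250, 8000, 14,
                              gen_config(seed = s, noise_sd = 5))
    !fit_isotherm(cur)$determinable
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("titration generator honours its contracts", {
  gen <- gen_config(seed = 3, noise_sd = 0)
  cur <- generate_titration(200, 10, 50, 250, 8000, 14, gen)
  expect_identical(nrow(cur), 14L)
  expect_equal(cur$titrant_nM[1], 8000)
  expect_equal(cur$titrant_nM[14], 8000 / 2^13)
  # saturating/baseline limits
  expect_gt(max(cur$FP_mP), 240)
  expect_lt(min(cur$FP_mP), 60)
  # determinism under identical seed, also with noise
  g5 <- gen_config(seed = 42, noise_sd = 5)
  expect_identical(generate_titration(200, 10, 50, 250, 8000, 14, g5),
                   generate_titration(200, 10, 50, 250, 8000, 14, g5))
  expect_error(generate_titration(-1, 10, 50, 250, 8000, 14, gen), "kd")
  expect_error(generate_titration(200, 0, 50, 250, 8000, 14, gen), "probe")
  expect_error(generate_titration(200, 10, 50, 250, 8000, 4, gen),
               "n_points")
})
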