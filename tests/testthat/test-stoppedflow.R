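# Stopped-flow fitting: exact round trips on the models' own output,
# closed-form oracles, and Monte-Carlo recovery.

test_that("trace averaging: identity, cancellation and noise reduction", {
  t <- seq(0, 1, by = 0.01)
  y <- 2 * exp(-3 * t) + 1
  tr <- sf_trace(t, y, ligand_conc = 10)
  av <- average_traces(list(tr, tr))
  expect_equal(av$y, y)

  ## y and -y average to zero
  av0 <- average_traces(list(sf_trace(t, y), sf_trace(t, -y)))
  expect_equal(av0$y, rep(0, length(t)), tolerance = 1e-12)

  ## 10 noisy replicates: residual s.d. shrinks ~ sqrt(10)
  reps <- withr::with_seed(31, lapply(1:10, function(i)
    sf_trace(t, y + rnorm(length(t), 0, 0.05))))
  avn <- average_traces(reps)
  expect_equal(sd(avn$y - y) * sqrt(10), 0.05, tolerance = 0.35)

  ## mismatched ligand concentrations refuse to average
  expect_error(average_traces(list(tr, sf_trace(t, y, ligand_conc = 20))),
               "concentrations differ")

  ## differing grids are interpolated onto the densest one
  tr_coarse <- sf_trace(seq(0, 1, by = 0.05),
                        2 * exp(-3 * seq(0, 1, by = 0.05)) + 1,
                        ligand_conc = 10)
  avi <- average_traces(list(tr, tr_coarse))
  expect_equal(avi$y, 2 * exp(-3 * avi$t) + 1, tolerance = 1e-3)
})

test_that("single-exponential fit: exact recovery and degenerate input", {
  t <- seq(0, 1.5, by = 0.005)
  fit <- fit_single_exponential(sf_trace(t, 2 * exp(-5 * t) + 1))
  expect_equal(fit$A, 2, tolerance = 1e-6)
  expect_equal(fit$k_obs, 5, tolerance = 1e-6)
  expect_equal(fit$C, 1, tolerance = 1e-6)

  ## rising transient (negative amplitude), as in mant-ATP binding
  fit2 <- fit_single_exponential(sf_trace(t, 3 - 2 * exp(-8 * t)))
  expect_equal(fit2$k_obs, 8, tolerance = 1e-6)
  expect_equal(fit2$A, -2, tolerance = 1e-6)

  ## generated binding-only transient at the front-head rates: kobs = 145
  tr <- simulate_stopped_flow_transient(
    scheme_params(5.3, 92, 0, ligand_conc = 10),
    list(baseline = 0.2, amplitude = 1, binding_only = TRUE),
    seq(0, 0.04, by = 1e-4))
  expect_lt(rel_err(fit_single_exponential(tr)$k_obs, 145), 1e-3)

  expect_error(fit_single_exponential(sf_trace(t, rep(2, length(t)))),
               "degenerate")
  ## short trace coverage warning
  expect_warning(fit_single_exponential(
    sf_trace(seq(0, 0.1, by = 0.001), 5 * exp(-2 * seq(0, 0.1, by = 0.001)) +
               1 + withr::with_seed(1, rnorm(101, 0, 1e-4)))),
    "relaxation")
})

test_that("burst fit: pure line, exact model, and Monte-Carlo k2 recovery", {
  t <- seq(0, 1, by = 0.002)
  ## pure line: A = 0, rate unidentifiable
  lf <- fit_burst(sf_trace(t, 3 * t + 1))
  expect_equal(lf$A, 0)
  expect_true(is.na(lf$k_obs))
  expect_equal(lf$k_ss, 3, tolerance = 1e-9)
  expect_equal(lf$C, 1, tolerance = 1e-9)

  ## noiseless burst recovered to 6 digits
  bf <- fit_burst(sf_trace(t, 5 * exp(-50 * t) - 0.1 * t + 2))
  expect_equal(bf$A, 5, tolerance = 1e-6)
  expect_equal(bf$k_obs, 50, tolerance = 1e-6)
  expect_equal(bf$k_ss, -0.1, tolerance = 1e-6)
  expect_equal(bf$C, 2, tolerance = 1e-6)

  ## turbidity decay at k2 = 7 with 1% noise: mean recovery error < 3%
  ## over 100 seeds
  tt <- seq(0, 0.8, by = 0.002)
  clean <- 1 * exp(-7 * tt) - 0.02 * tt + 0.5
  errs <- withr::with_seed(32, vapply(1:100, function(i) {
    tr <- sf_trace(tt, clean + rnorm(length(tt), 0, 0.01),
                   kind = "turbidity")
    rel_err(fit_burst(tr)$k_obs, 7)
  }, numeric(1)))
  expect_lt(mean(errs), 0.03)
})

test_that("kobs line fit: exact points, flat series, and WLS oracle", {
  ## exact points on kobs = 5.3 c + 92 give the generating line back
  concs <- c(2, 5, 10, 20, 50)
  kf <- fit_kobs_linear(data.frame(conc = concs, kobs = 5.3 * concs + 92))
  expect_equal(kf$k_plus1, 5.3, tolerance = 1e-9)
  expect_equal(kf$k_minus1, 92, tolerance = 1e-9)

  ## flat series: slope 0, intercept 10
  kf0 <- fit_kobs_linear(data.frame(conc = concs, kobs = rep(10, 5)))
  expect_equal(kf0$k_plus1, 0, tolerance = 1e-12)
  expect_equal(kf0$k_minus1, 10, tolerance = 1e-12)

  ## weighted fit matches the closed-form normal-equations oracle to 1e-10
  df <- withr::with_seed(33, data.frame(
    conc = concs, kobs = 5.3 * concs + 92 + rnorm(5, 0, 3),
    se = runif(5, 0.5, 2)))
  kfw <- fit_kobs_linear(df)
  w <- 1 / df$se^2
  X <- cbind(1, df$conc)
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * df$kobs))
  expect_equal(kfw$k_minus1, beta[1], tolerance = 1e-10)
  expect_equal(kfw$k_plus1, beta[2], tolerance = 1e-10)

  expect_error(fit_kobs_linear(data.frame(conc = c(1, 2), kobs = c(1, 2))),
               ">= 3")
})

test_that("simulate -> fit-exp -> kobs-line pipeline recovers k+1 and k-1", {
  concs <- c(2, 5, 10, 20, 50)
  run <- function(noise_sd, seed = NULL) {
    per_conc <- lapply(concs, function(S) {
      kobs_true <- 5.3 * S + 92
      tr <- simulate_stopped_flow_transient(
        scheme_params(5.3, 92, 0, ligand_conc = S),
        list(baseline = 0, amplitude = 1, binding_only = TRUE),
        seq(0, 6 / kobs_true, length.out = 500),
        noise_sd = noise_sd, seed = if (is.null(seed)) NULL else seed + S)
      f <- fit_single_exponential(tr)
      data.frame(conc = S, kobs = f$k_obs, se = f$se[["k_obs"]])
    })
    fit_kobs_linear(do.call(rbind, per_conc))
  }
  ## noiseless: within 2%
  kf <- run(0)
  expect_lt(rel_err(kf$k_plus1, 5.3), 0.02)
  expect_lt(rel_err(kf$k_minus1, 92), 0.02)
  ## 1% Gaussian noise: within 3 fit SEs
  kfn <- run(0.01, seed = 340)
  expect_lt(abs(kfn$k_plus1 - 5.3), 3 * kfn$se[["k_plus1"]] + 1e-9)
  expect_lt(abs(kfn$k_minus1 - 92), 3 * kfn$se[["k_minus1"]] + 1e-9)

  ## kobs ordering for the full three-state scheme: non-decreasing in [S]
  ko <- vapply(concs, function(S) {
    tr <- simulate_stopped_flow_transient(
      scheme_params(5.3, 92, 50, ligand_conc = S),
      list(baseline = 0, amplitude = 1, binding_only = FALSE),
      seq(0, 0.06, by = 1e-4))
    fit_single_exponential(tr)$k_obs
  }, numeric(1))
  expect_true(all(diff(ko) > 0))
})
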