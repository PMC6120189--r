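# Hill-equation fits (activation and inhibition) and the constrained
# bi-exponential deactivation fit with amplitude-weighted time constant.

half_log_grid <- function(lo = -7.5, hi = -4) 10^seq(lo, hi, 0.5)

test_that("noiseless Hill data are recovered exactly, both modes", {
  cases <- list(list(h = 1e-5, n = 1.5, mode = "activation"),
                list(h = 4e-5, n = 1.0, mode = "inhibition"),
                list(h = 2.19e-6, n = 1.2, mode = "activation"),
                list(h = 5e-7, n = 2.5, mode = "inhibition"))
  for (cs in cases) {
    d <- gen_hill_dataset(cs$h, cs$n, half_log_grid(), cs$mode,
                          noise_spec(0))
    fit <- fit_hill(d)
    expect_equal(fit$half_max, cs$h, tolerance = 1e-6)
    expect_equal(fit$slope, cs$n, tolerance = 1e-6)
    expect_lt(fit$rss, 1e-10)
    # the fitted curve passes through 0.5 at the half-max concentration
    expect_equal(predict(fit, cs$h), 0.5, tolerance = 1e-9)
  }
})

test_that("the inhibition curve runs from 1 (no blocker) to 0 (saturating)", {
  d <- gen_hill_dataset(4e-5, 1, half_log_grid(), "inhibition",
                        noise_spec(0))
  fit <- fit_hill(d)
  expect_equal(predict(fit, 4e-5 / 1e6), 1, tolerance = 1e-5)
  expect_equal(predict(fit, 4e-5 * 1e6), 0, tolerance = 1e-5)
})

test_that("Hill fits are scale-equivariant in concentration", {
  d <- gen_hill_dataset(1e-5, 1.7, half_log_grid(), "activation",
                        noise_spec(0))
  fit <- fit_hill(d)
  for (c_scale in c(10, 1e3)) {
    d2 <- crc_data(d$conc * c_scale, d$response, mode = "activation")
    fit2 <- fit_hill(d2)
    expect_equal(fit2$half_max, fit$half_max * c_scale, tolerance = 1e-6)
    expect_equal(fit2$slope, fit$slope, tolerance = 1e-6)
  }
})

test_that("noisy Hill datasets recover the generating EC50 on average", {
  # generating value: the published WT rho1 EC50
  ec50s <- vapply(1:100, function(s) {
    d <- gen_hill_dataset(2.19e-6, 1.2, 10^seq(-8, -4, 0.5), "activation",
                          noise_spec(0.02, seed = s))
    fit_hill(d)$half_max
  }, numeric(1))
  expect_equal(mean(ec50s), 2.19e-6, tolerance = 0.05)
})

test_that("Hill fitting rejects short or mismatched data", {
  d <- gen_hill_dataset(1e-5, 1, 10^seq(-6, -5, 0.5), "activation",
                        noise_spec(0))
  expect_error(fit_hill(d), "at least 4")
  d2 <- gen_hill_dataset(1e-5, 1, half_log_grid(), "inhibition",
                         noise_spec(0))
  expect_error(fit_hill(d2, mode = "activation"), "mode")
})

biexp_segment <- function(a1, tau1, a2, tau2, t = seq(0, 120, 0.05))
  deactivation_segment(t, -(a1 * exp(-t / tau1) + a2 * exp(-t / tau2)))

test_that("noiseless bi-exponential segments are recovered exactly", {
  fit <- fit_biexp(biexp_segment(60, 2, 40, 20))
  expect_equal(fit$A1, 60, tolerance = 1e-6)
  expect_equal(fit$tau1, 2, tolerance = 1e-6)
  expect_equal(fit$tau2, 20, tolerance = 1e-6)
  expect_equal(fit$weighted_tau, 9.2, tolerance = 1e-6)
  expect_equal(fit$A1 + fit$A2, 100)
  expect_lt(fit$rss, 1e-10)
})

test_that("weighted tau is the amplitude-weighted mean and lies between taus", {
  set.seed(61)
  for (i in 1:10) {
    a1 <- runif(1, 5, 95)
    taus <- sort(exp(runif(2, log(0.5), log(50))))
    fit <- fit_biexp(biexp_segment(a1, taus[1], 100 - a1, taus[2],
                                   t = seq(0, 300, 0.1)))
    expect_equal(fit$weighted_tau,
                 (fit$A1 * fit$tau1 + fit$A2 * fit$tau2) / 100)
    expect_gte(fit$weighted_tau, fit$tau1 - 1e-9)
    expect_lte(fit$weighted_tau, fit$tau2 + 1e-9)
    expect_lte(fit$tau1, fit$tau2)
  }
})

test_that("a mono-exponential input collapses to a single component", {
  t <- seq(0, 30, 0.01)
  fit <- fit_biexp(deactivation_segment(t, -100 * exp(-t / 2)))
  expect_equal(fit$weighted_tau, 2, tolerance = 1e-6)
})

test_that("noisy bi-exponential segments recover the weighted tau", {
  t <- seq(0, 120, 0.1)
  clean <- -(60 * exp(-t / 2) + 40 * exp(-t / 20))
  wts <- vapply(1:100, function(s) {
    set.seed(s)
    y <- clean + c(0, rnorm(length(t) - 1, 0, 1))  # t=0 pinned at -100
    y <- y * (-100 / y[1])
    fit_biexp(deactivation_segment(t, y))$weighted_tau
  }, numeric(1))
  expect_equal(median(wts), 9.2, tolerance = 0.05)
})

test_that("bi-exponential fitting validates its input", {
  t <- seq(0, 10, 1)
  expect_error(fit_biexp(deactivation_segment(t, -100 * exp(-t / 2))),
               "at least 20")
  expect_error(deactivation_segment(seq(0, 10, 0.5),
                                    -90 * exp(-seq(0, 10, 0.5))),
               "-100")
})

test_that("fit standard errors are finite and positive on noisy data", {
  d <- gen_hill_dataset(1e-5, 1.5, half_log_grid(), "activation",
                        noise_spec(0.02, seed = 7))
  fit <- fit_hill(d)
  expect_true(all(is.finite(fit$se)) && all(fit$se > 0))
  set.seed(71)
  t <- seq(0, 120, 0.1)
  y <- -(60 * exp(-t / 2) + 40 * exp(-t / 20)) +
    c(0, rnorm(length(t) - 1, 0, 0.5))
  y <- y * (-100 / y[1])
  bf <- fit_biexp(deactivation_segment(t, y))
  expect_true(all(is.finite(bf$se)) && all(bf$se > 0))
})

test_that("bootstrap standard errors are seeded and comparable in scale", {
  d <- gen_hill_dataset(1e-5, 1.5, half_log_grid(), "activation",
                        noise_spec(0.02, seed = 5))
  f1 <- fit_hill(d, boot = 30, boot_seed = 2)
  f2 <- fit_hill(d, boot = 30, boot_seed = 2)
  expect_identical(f1$se, f2$se)
  lin <- fit_hill(d)
  # same point estimate, same order of magnitude for the half-max SE
  expect_equal(f1$half_max, lin$half_max)
  expect_lt(f1$se[["half_max"]] / lin$se[["half_max"]], 5)
  expect_gt(f1$se[["half_max"]] / lin$se[["half_max"]], 0.2)

  set.seed(81)
  t <- seq(0, 120, 0.1)
  y <- -(60 * exp(-t / 2) + 40 * exp(-t / 20)) +
    c(0, rnorm(length(t) - 1, 0, 0.5))
  y <- y * (-100 / y[1])
  b1 <- fit_biexp(deactivation_segment(t, y), boot = 20, boot_seed = 3)
  b2 <- fit_biexp(deactivation_segment(t, y), boot = 20, boot_seed = 3)
  expect_identical(b1$se, b2$se)
  expect_true(all(is.finite(b1$se)) && all(b1$se > 0))
})
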