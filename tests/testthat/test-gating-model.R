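# Scheme construction, generator matrix, stationary distributions,
# mutant perturbation rules and scheme file IO.

test_that("generator rows sum to zero and carry exactly the scheme edges", {
  sc <- wt_like_scheme()
  for (conc in c(0, 1e-7, 1e-3)) {
    Q <- build_generator(sc, conc)
    expect_equal(rowSums(Q), setNames(rep(0, 6), rownames(Q)))
    expect_equal(Q["R", "AR"], sc$k1 * conc)
    # non-edges stay zero at any concentration
    expect_identical(Q["R", "AF"], 0)
    expect_identical(Q["R", "AO"], 0)
    expect_identical(Q["AR", "AO"], 0)
    expect_identical(Q["AFD", "AOD"], 0)
    expect_identical(Q["AOD", "R"], 0)
  }
  expect_error(build_generator(sc, -1e-6), "non-negative")
})

test_that("a binding-only scheme has a single nonzero off-diagonal rate", {
  sc <- gating_scheme(k1 = 1e6, k_minus1 = 0, f1 = 0, f_minus1 = 0,
                      beta = 0, alpha = 0, dAF_on = 0, dAF_off = 0,
                      dAO_on = 0, dAO_off = 0)
  Q <- build_generator(sc, 1e-6)
  off <- Q
  diag(off) <- 0
  expect_equal(sum(off != 0), 1L)
  expect_equal(Q["R", "AR"], 1.0)
  expect_equal(build_generator(sc, 0)["R", "AR"], 0)
})

test_that("scheme constructor enforces non-negative finite rates", {
  expect_error(gating_scheme(0, 1, 1, 1, 1, 1, 1, 1, 1, 1),
               "strictly positive")
  expect_error(gating_scheme(1e6, -1, 1, 1, 1, 1, 1, 1, 1, 1),
               "non-negative")
  expect_error(gating_scheme(1e6, Inf, 1, 1, 1, 1, 1, 1, 1, 1), "finite")
})

test_that("steady state matches the analytic two-state equilibrium", {
  # at zero agonist the resting state is the only reachable state
  expect_equal(steady_state(wt_like_scheme(), 0),
               setNames(c(1, 0, 0, 0, 0, 0),
                        c("R", "AR", "AF", "AO", "AFD", "AOD")))
  # two-state reduction: occupancy k1[A] / (k1[A] + k_minus1)
  ts <- two_state_scheme(k1 = 1e6, k_minus1 = 1)
  ss <- steady_state(ts, 1e-6)
  expect_equal(ss[["AR"]], 0.5, tolerance = 1e-12)
  ss2 <- steady_state(ts, 3e-6)
  expect_equal(ss2[["AR"]], 3 / 4, tolerance = 1e-12)
  # unreachable gated states keep zero occupancy
  expect_equal(unname(ss[3:6]), rep(0, 4))
})

test_that("a long simulation converges to the stationary distribution", {
  set.seed(11)
  for (i in 1:3) {
    sc <- random_wt_like_scheme()
    conc <- 1e-5
    ss <- steady_state(sc, conc)
    pr <- concentration_protocol(data.frame(duration = 2000, conc = conc),
                                 dt = 0.5)
    tr <- simulate_protocol(sc, pr)
    expect_lt(max(abs(tr$occupancy[nrow(tr$occupancy), ] - ss)), 1e-6)
  }
})

test_that("occupancy rows sum to one along arbitrary protocols", {
  set.seed(21)
  for (i in 1:5) {
    sc <- random_scheme()
    pr <- concentration_protocol(
      data.frame(duration = c(2, 10, 30), conc = c(0, 1e-5, 0)), dt = 0.05)
    tr <- simulate_protocol(sc, pr)
    expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-8)
    expect_gte(min(tr$occupancy), 0)
    expect_lte(max(tr$occupancy), 1)
    expect_identical(tr$p_open, unname(tr$occupancy[, "AO"]))
  }
})

test_that("a resting receptor without agonist stays at rest", {
  pr <- concentration_protocol(data.frame(duration = 5, conc = 0), dt = 0.1)
  tr <- simulate_protocol(wt_like_scheme(), pr)
  expect_equal(tr$occupancy[, "R"], rep(1, length(tr$time)))
  expect_equal(max(abs(tr$p_open)), 0)
})

test_that("two-state relaxation follows the analytic mono-exponential", {
  k1 <- 2e6; km1 <- 1.5; conc <- 1e-6
  ts <- two_state_scheme(k1 = k1, k_minus1 = km1)
  rate <- k1 * conc + km1
  ss <- k1 * conc / rate
  pr <- concentration_protocol(data.frame(duration = 4, conc = conc),
                               dt = 0.001)
  tr <- simulate_protocol(ts, pr)
  expect_equal(tr$occupancy[, "AR"], ss * (1 - exp(-rate * tr$time)),
               tolerance = 1e-9)
  # fitted relaxation rate within 0.1% of k1[A] + k_minus1; start the
  # rate at the empirical 1 - 1/e crossing time
  ar <- tr$occupancy[, "AR"]
  a0 <- ar[length(ar)]
  r0 <- 1 / tr$time[which(ar >= a0 * (1 - exp(-1)))[1]]
  fit <- stats::nls(ar ~ a * (1 - exp(-r * t)),
                    data = list(ar = ar, t = tr$time),
                    start = list(a = a0, r = r0),
                    control = stats::nls.control(maxiter = 200, scaleOffset = 1))
  expect_equal(unname(coef(fit)[["r"]]), rate, tolerance = 1e-3)
})

test_that("matrix-exponential propagation agrees with a stiff ODE solve", {
  skip_if_not_installed("deSolve")
  set.seed(31)
  for (i in 1:8) {
    sc <- random_scheme()
    pr <- concentration_protocol(
      data.frame(duration = stats::runif(2, 1, 10),
                 conc = c(10^stats::runif(1, -7, -4), 0)), dt = 0.05)
    tr <- simulate_protocol(sc, pr)
    oracle <- ode_oracle_trace(sc, pr)
    expect_lt(max(abs(tr$occupancy - oracle$occupancy)), 1e-6)
  }
})

test_that("simulation errors are raised for invalid protocols", {
  expect_error(concentration_protocol(data.frame(duration = 1, conc = 0),
                                      dt = 2), "shortest segment")
  expect_error(concentration_protocol(data.frame(duration = -1, conc = 0)),
               "positive")
  expect_error(concentration_protocol(data.frame(duration = 1, conc = -2)),
               "non-negative")
})

test_that("protocol strings parse into segments", {
  pr <- parse_protocol("0@5;0.001@60;0@600", dt = 0.01)
  expect_equal(pr$segments$conc, c(0, 1e-3, 0))
  expect_equal(pr$segments$duration, c(5, 60, 600))
  expect_error(parse_protocol("5;60"), "expected conc@duration")
})

test_that("mutant rules rescale exactly the named rates", {
  wt <- wt_like_scheme()
  expect_equal(scheme_rates(apply_mutation(wt, mutant_rule("id"))),
               scheme_rates(wt))
  rules <- predefined_mutant_rules()
  expect_named(rules, c("WT", "W329A", "W280Q"))
  expect_length(rules$WT$factors, 0L)

  m329 <- apply_mutation(wt, rules$W329A)
  expect_equal(m329$dAF_on, 0)
  expect_equal(m329$dAO_on, 0)
  expect_equal(m329$k_minus1, wt$k_minus1 * 10)
  expect_equal(m329$beta, wt$beta)

  m280 <- apply_mutation(wt, rules$W280Q)
  expect_equal(m280$k_minus1, wt$k_minus1 * 0.1)
  expect_equal(m280$dAO_on, wt$dAO_on * 0.7)
  expect_equal(m280$dAF_on, wt$dAF_on)

  # multiplicative algebra: inverting the k_minus1 factor recovers WT
  undo <- apply_mutation(m329, mutant_rule("undo", c(k_minus1 = 0.1)))
  expect_equal(undo$k_minus1, wt$k_minus1)
  # input scheme unchanged
  expect_equal(wt$k_minus1, 1)

  expect_error(mutant_rule("bad", c(nope = 2)), "unknown rate name")
  expect_error(mutant_rule("bad", c(k1 = -1)), "non-negative")
})

test_that("scheme JSON round-trips and rejects unknown keys", {
  wt <- wt_like_scheme()
  path <- withr::local_tempfile(fileext = ".json")
  write_scheme(wt, path)
  expect_equal(scheme_rates(read_scheme(path)), scheme_rates(wt))
  writeLines('{"k1": 1e6, "bogus": 2}', path)
  expect_error(read_scheme(path), "unknown key")
})
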