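# Published target table, per-genotype model summary statistics, and the
# joint WT calibration machinery.

test_that("the published target table carries the six printed statistics", {
  tg <- default_targets()
  expect_equal(nrow(tg), 6)
  expect_setequal(tg$genotype, c("WT", "W280Q", "W329A"))
  get <- function(g, s) tg$printed_mean[tg$genotype == g & tg$statistic == s]
  expect_equal(get("WT", "ec50"), 2.19e-6)
  expect_equal(get("W280Q", "ec50"), 0.92e-6)
  expect_equal(get("W329A", "ec50"), 25.76e-6)
  expect_equal(get("WT", "weighted_tau"), 26.9)
  expect_equal(get("W280Q", "weighted_tau"), 84.4)
  expect_equal(get("W329A", "weighted_tau"), 0.86)
  expect_equal(tg$tolerance, tg$printed_sem)
  expect_true(all(tg$printed_sem > 0))
})

test_that("mutant summary statistics equal those of the mutated scheme", {
  wt <- wt_like_scheme()
  via_rule <- model_summary_stats(wt, "W329A")
  explicit <- apply_mutation(wt, predefined_mutant_rules()$W329A)
  direct <- model_summary_stats(explicit, "WT")
  expect_equal(via_rule$ec50, direct$ec50, tolerance = 1e-9)
  expect_equal(via_rule$weighted_tau, direct$weighted_tau,
               tolerance = 1e-9)
  expect_error(model_summary_stats(wt, "nope"), "unknown genotype")
})

test_that("eliminating desensitization entry zeroes the measured extent", {
  wt <- wt_like_scheme()
  s <- model_summary_stats(wt, "W329A")
  expect_lt(s$desensitization_pct, 0.5)
  expect_gt(model_summary_stats(wt, "WT")$desensitization_pct, 30)
})

test_that("in the binding limit the W329A EC50 is ~10x the WT EC50", {
  # weak gating, no desensitization: peak response follows equilibrium
  # occupancy, so EC50 ~ k_minus1/k1 and the x10 rule scales it tenfold
  wt <- gating_scheme(k1 = 2e6, k_minus1 = 1, f1 = 0.2, f_minus1 = 200,
                      beta = 0.2, alpha = 200, dAF_on = 0, dAF_off = 1,
                      dAO_on = 0, dAO_off = 1)
  s_wt <- model_summary_stats(wt, "WT", application_duration = 200,
                              concentrations = 10^seq(-9, -3, 0.5))
  s_mut <- model_summary_stats(wt, "W329A", application_duration = 200,
                               concentrations = 10^seq(-9, -3, 0.5))
  expect_equal(s_mut$ec50 / s_wt$ec50, 10, tolerance = 0.1)
})

test_that("calibration is a fixed point at a known solution", {
  wt <- wt_like_scheme()
  stats <- lapply(c(WT = "WT", W280Q = "W280Q", W329A = "W329A"),
                  function(g) model_summary_stats(wt, g))
  tg <- calibration_targets(
    genotype = rep(names(stats), 2),
    statistic = rep(c("ec50", "weighted_tau"), each = 3),
    printed_mean = c(vapply(stats, `[[`, numeric(1), "ec50"),
                     vapply(stats, `[[`, numeric(1), "weighted_tau")),
    printed_sem = c(vapply(stats, `[[`, numeric(1), "ec50") * 0.05,
                    vapply(stats, `[[`, numeric(1), "weighted_tau") * 0.05))
  cal <- calibrate_scheme(tg, n_starts = 1, seed = 1,
                          start = matrix(scheme_rates(wt), 1,
                                         dimnames = list(NULL,
                                                         names(scheme_rates(wt)))))
  expect_true(cal$converged)
  expect_lt(cal$loss, 1e-6)
  expect_true(all(cal$table$within_tolerance))
  # stored model values are reproducible from the fitted scheme
  re <- model_summary_stats(cal$scheme, "W280Q")
  expect_equal(re$ec50,
               cal$table$model_value[cal$table$genotype == "W280Q" &
                                       cal$table$statistic == "ec50"],
               tolerance = 1e-9)
})

test_that("calibration recovers a perturbed known rate set", {
  wt <- wt_like_scheme()
  stats <- lapply(c(WT = "WT", W280Q = "W280Q", W329A = "W329A"),
                  function(g) model_summary_stats(wt, g))
  tg <- calibration_targets(
    genotype = rep(names(stats), 2),
    statistic = rep(c("ec50", "weighted_tau"), each = 3),
    printed_mean = c(vapply(stats, `[[`, numeric(1), "ec50"),
                     vapply(stats, `[[`, numeric(1), "weighted_tau")),
    printed_sem = c(vapply(stats, `[[`, numeric(1), "ec50") * 0.05,
                    vapply(stats, `[[`, numeric(1), "weighted_tau") * 0.05))
  # start from a rate set displaced from the solution
  start <- scheme_rates(wt) * exp(c(0.4, -0.4, 0.3, -0.3, 0.2, -0.2,
                                    0.3, -0.3, 0.2, -0.2))
  cal <- calibrate_scheme(tg, n_starts = 1, seed = 1,
                          start = matrix(start, 1,
                                         dimnames = list(NULL, names(start))),
                          eval_budget = 500)
  expect_true(cal$converged)
  # mutant statistics in the result derive from the single fitted WT
  # scheme plus the fixed rules, never fitted independently
  mut <- apply_mutation(cal$scheme, predefined_mutant_rules()$W329A)
  expect_equal(model_summary_stats(mut, "WT")$weighted_tau,
               cal$table$model_value[cal$table$genotype == "W329A" &
                                       cal$table$statistic ==
                                       "weighted_tau"],
               tolerance = 1e-9)
})

test_that("calibration results are deterministic given the seed", {
  wt <- wt_like_scheme()
  tg <- calibration_targets(
    genotype = c("WT", "WT"), statistic = c("ec50", "weighted_tau"),
    printed_mean = c(2e-6, 30), printed_sem = c(0.5e-6, 5))
  s <- matrix(scheme_rates(wt), 1,
              dimnames = list(NULL, names(scheme_rates(wt))))
  c1 <- calibrate_scheme(tg, n_starts = 1, seed = 7, start = s,
                         eval_budget = 60)
  c2 <- calibrate_scheme(tg, n_starts = 1, seed = 7, start = s,
                         eval_budget = 60)
  expect_identical(scheme_rates(c1$scheme), scheme_rates(c2$scheme))
  expect_identical(c1$loss, c2$loss)
})

test_that("dropping a target never increases the optimal loss", {
  wt <- wt_like_scheme()
  stats <- lapply(c(WT = "WT", W329A = "W329A"),
                  function(g) model_summary_stats(wt, g))
  tg <- calibration_targets(
    genotype = rep(names(stats), 2),
    statistic = rep(c("ec50", "weighted_tau"), each = 2),
    printed_mean = c(vapply(stats, `[[`, numeric(1), "ec50"),
                     vapply(stats, `[[`, numeric(1), "weighted_tau")),
    printed_sem = c(vapply(stats, `[[`, numeric(1), "ec50") * 0.05,
                    vapply(stats, `[[`, numeric(1), "weighted_tau") * 0.05))
  s <- matrix(scheme_rates(wt), 1,
              dimnames = list(NULL, names(scheme_rates(wt))))
  full <- calibrate_scheme(tg, n_starts = 1, seed = 1, start = s,
                           eval_budget = 120)
  subset <- calibrate_scheme(tg[-2, ], n_starts = 1, seed = 1, start = s,
                             eval_budget = 120)
  expect_lte(subset$loss, full$loss + 1e-8)
})
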