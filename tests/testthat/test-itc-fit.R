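test_that("OSS fit recovers generating parameters from noiseless data", {
  sch <- make_schedule()
  truth <- thermo_params(1.2, 1.2e-6, -10.6)
  fit <- fit_oss(oss_isotherm(truth, sch))
  expect_true(fit$converged)
  expect_equal(fit$params[["n"]], 1.2, tolerance = 1e-6)
  expect_equal(fit$params[["kd"]], 1.2e-6, tolerance = 1e-6)
  expect_equal(fit$params[["dh"]], -10.6, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-8)
  # derived thermodynamics attached
  expect_equal(fit$events$dg, delta_g_from_kd(fit$events$kd), tolerance = 1e-9)
  expect_equal(fit$events$neg_t_ds, fit$events$dg - fit$events$dh)
})

test_that("OSS recovery holds across the identifiable c range", {
  sch <- make_schedule()
  set.seed(7)
  for (i in 1:40) {
    n <- runif(1, 0.8, 2.5)
    c_val <- 10^runif(1, log10(5), log10(500))   # Wiseman c = n Ka Mt
    ka <- c_val / (n * sch$cell_conc0)
    dh <- runif(1, -14, -4)
    truth <- thermo_params(n, 1 / ka, dh)
    fit <- fit_oss(oss_isotherm(truth, sch))
    expect_equal(fit$params[["n"]], n, tolerance = 1e-5)
    expect_equal(fit$params[["kd"]], 1 / ka, tolerance = 1e-5)
    expect_equal(fit$params[["dh"]], dh, tolerance = 1e-5)
  }
})

test_that("recovery error grows with noise and is zero at zero noise", {
  sch <- make_schedule()
  truth <- thermo_params(1.2, 1.2e-6, -10.6)
  spec0 <- synthetic_spec(truth, sch, noise_sigma = 0, seed = 11)
  err <- vapply(c(0, 0.5, 4), function(sg) {
    errs <- vapply(1:8, function(r) {
      spec <- synthetic_spec(truth, sch, noise_sigma = sg, seed = 100 + r)
      f <- fit_oss(gen_isotherm(spec))
      abs(f$params[["kd"]] - 1.2e-6) / 1.2e-6
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_lt(err[1], 1e-7)
  expect_lt(err[1], err[2])
  expect_lt(err[2], err[3])
})

test_that("flat isotherms are flagged instead of fitted", {
  sch <- make_schedule()
  iso <- oss_isotherm(thermo_params(1.2, 1.2e-6, 0), sch)
  fit <- fit_oss(iso)
  expect_false(fit$converged)
  expect_true(fit$diagnostics$ill_conditioned)
  expect_true(is.na(fit$params[["kd"]]))
})

test_that("constrained sequential fit recovers all four free parameters", {
  sm <- sequential_model(c(1 / 0.3e-6, 1 / 0.3e-6, 1 / 1.1e-6),
                         c(-10, -10, -5))
  iso <- sequential_isotherm(sm, make_schedule(cell_conc = 10e-6))
  fit <- fit_sequential_constrained(iso)
  expect_true(fit$converged)
  expect_equal(fit$params[["kd1"]], 0.3e-6, tolerance = 1e-4)
  expect_equal(fit$params[["kd3"]], 1.1e-6, tolerance = 1e-4)
  expect_equal(fit$params[["h1"]], -10, tolerance = 1e-4)
  expect_equal(fit$params[["h3"]], -5, tolerance = 1e-4)
  # equalities hold by construction
  expect_identical(fit$params[["k1"]], fit$params[["k2"]])
  expect_identical(fit$params[["h1"]], fit$params[["h2"]])
  # constrained fit of constraint-satisfying data sits at the noise floor
  expect_lt(fit$residual_rms, 1e-7)
})

test_that("sequential fit satisfies the inequalities from any start", {
  sm <- sequential_model(c(1 / 0.3e-6, 1 / 0.3e-6, 1 / 1.1e-6),
                         c(-10, -10, -5))
  iso <- sequential_isotherm(sm, make_schedule(cell_conc = 10e-6))
  # infeasible initializations are projected and still yield feasible output
  bad_inits <- list(
    sequential_model(c(1e5, 1e5, 1e7), c(-3, -3, -12)),  # k3 > k1, h3 < h1
    sequential_model(c(1e8, 1e8, 1e3), c(-20, -20, 5)))
  for (init in bad_inits) {
    f <- fit_sequential_constrained(iso, init = init, n_starts = 2)
    expect_gt(f$params[["k1"]], f$params[["k3"]])
    expect_lt(f$params[["h1"]], f$params[["h3"]])
  }
})

test_that("fitting single-event data with the sequential model flags h3", {
  iso <- oss_isotherm(thermo_params(1, 1e-6, -10),
                      make_schedule(cell_conc = 10e-6))
  fit <- fit_sequential_constrained(iso)
  # the third event is superfluous: k3 well below k1 or its enthalpy step
  # poorly determined (large standard error), flagged ill-conditioned
  expect_true(fit$params[["k3"]] < 0.5 * fit$params[["k1"]] ||
                fit$diagnostics$ill_conditioned ||
                fit$events$dh_se[2] > 10 * abs(fit$events$dh[2] + 1e-9))
})

test_that("derived thermodynamics propagate errors to first order", {
  f <- fit_oss(oss_isotherm(thermo_params(1.2, 0.4e-6, -9.7),
                            make_schedule()))
  ev <- f$events
  expect_equal(ev$dg, -8.73, tolerance = 0.01)
  expect_equal(ev$neg_t_ds, -8.73 - (-9.7), tolerance = 0.02)
  # zero input errors give zero propagated errors
  g <- f
  g$events$kd_se <- 0; g$events$dh_se <- 0
  g <- derive_thermo(g, 298.15)
  expect_equal(g$events$dg_se, 0)
  expect_equal(g$events$ntds_se, 0)
})

test_that("inverse-variance aggregation matches the closed forms", {
  # two-point worked example
  a <- aggregate_inverse_variance(c(1, 2), c(1, 2))
  expect_equal(a$aggregate, 1.2)
  expect_equal(a$aggregate_error, 0.8)
  # single measurement: value unchanged, error sigma^2 (verbatim form)
  s <- aggregate_inverse_variance(3.4, 0.5)
  expect_equal(s$aggregate, 3.4)
  expect_equal(s$aggregate_error, 0.25)
  expect_equal(aggregate_inverse_variance(3.4, 0.5,
                                          conventional = TRUE)$aggregate_error,
               0.5)
  # equal sigmas: arithmetic mean; aggregate within data range always
  y <- c(1.1, 2.3, 0.4)
  expect_equal(aggregate_inverse_variance(y, rep(2, 3))$aggregate, mean(y))
  set.seed(5)
  for (i in 1:50) {
    yy <- rnorm(4); ss <- runif(4, 0.1, 3)
    ag <- aggregate_inverse_variance(yy, ss)$aggregate
    expect_gte(ag, min(yy)); expect_lte(ag, max(yy))
  }
  expect_error(aggregate_inverse_variance(1:2, c(1, 0)), "sigma")
  expect_error(aggregate_inverse_variance(1:3, 1:2), "length")
})
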