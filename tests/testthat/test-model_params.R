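test_that("nominal rate constants give the published effective kinetics", {
  rc <- preset_rate_constants("table1")
  ek <- effective_kinetics(rc)
  expect_equal(ek$lambda_inf, 1080)
  expect_equal(ek$K, 8)
  expect_equal(ek$epsilon, 3000 / 4000)
  # identity lambda_inf/K = epsilon * k_cat / k_c
  expect_equal(ek$lambda_inf / ek$K, ek$epsilon * rc$k_cat / rc$k_c,
               tolerance = 1e-12)
  expect_equal(ek$lambda_inf / ek$K, 135)
})

test_that("lambda_inf is linear in k_cat and K independent of it", {
  rc <- preset_rate_constants("table1")
  ek <- effective_kinetics(rc)
  ek2 <- effective_kinetics(update_rate_constants(rc, k_cat = 2 * rc$k_cat))
  expect_equal(ek2$lambda_inf, 2 * ek$lambda_inf)
  expect_equal(ek2$K, ek$K)
})

test_that("saturation identity and (k_cat, k_rev) homogeneity hold across random parameter sets", {
  set.seed(42)
  for (i in 1:25) {
    rc <- rate_constants(
      n_s = sample(10:10000, 1),
      k_1 = 10^runif(1, -3, 1), k_m1 = 10^runif(1, 0, 4),
      k_cat = 10^runif(1, -2, 2), k_rev = 10^runif(1, -4, 0),
      k_c = 10^runif(1, -3, 0), k_tx = 0.027, k_tl = 0.2,
      k_on = 0.0225, k_off = 0.0075, k_deg = 0.2, delta = 2.5e-4)
    ek <- effective_kinetics(rc)
    expect_gt(ek$epsilon, 0); expect_lt(ek$epsilon, 1)
    expect_equal(ek$lambda_inf / ek$K, ek$epsilon * rc$k_cat / rc$k_c,
                 tolerance = 1e-12)
    # scaling k_cat and k_rev together leaves lambda_inf fixed, scales K down
    f <- 10^runif(1, -1, 1)
    ekf <- effective_kinetics(update_rate_constants(
      rc, k_cat = f * rc$k_cat, k_rev = f * rc$k_rev))
    expect_equal(ekf$lambda_inf, ek$lambda_inf, tolerance = 1e-12)
    expect_equal(ekf$K, ek$K / f, tolerance = 1e-12)
  }
})

test_that("irreversible catalysis is an explicit regime, not an infinity", {
  rc <- update_rate_constants(preset_rate_constants("table1"), k_rev = 0)
  expect_error(effective_kinetics(rc), "irreversible")
  map <- poisson_parameter(rc)
  expect_identical(map$mode, "irreversible")
  expect_equal(map$linear_slope, 135)
  expect_equal(map$lambda(2), 270)
})

test_that("three-stage parameters match direct arithmetic and Vieta identities", {
  rc <- preset_rate_constants("table1")
  tsp <- three_stage_params(rc)
  expect_equal(tsp$gamma, 120)
  expect_equal(tsp$a, 108)
  expect_equal(tsp$b, 1)
  set.seed(7)
  for (i in 1:20) {
    rci <- update_rate_constants(
      rc, k_on = 10^runif(1, -5, -1), k_off = 10^runif(1, -5, -1),
      k_tx = 10^runif(1, -3, -1))
    ts <- three_stage_params(rci)
    expect_gte(ts$alpha_plus, ts$alpha_minus)
    expect_gte(ts$alpha_minus, 0)
    expect_equal(ts$alpha_plus + ts$alpha_minus, ts$a + ts$gamma,
                 tolerance = 1e-9)
    expect_equal(ts$alpha_plus * ts$alpha_minus,
                 ts$a * rci$k_on / rci$delta, tolerance = 1e-9)
    # the roots bracket both a and gamma
    expect_lte(ts$alpha_minus, min(ts$a, ts$gamma) + 1e-9)
    expect_gte(ts$alpha_plus, max(ts$a, ts$gamma) - 1e-9)
  }
})

test_that("a silent promoter collapses the small root to zero", {
  rc <- update_rate_constants(preset_rate_constants("table1"), k_on = 0)
  tsp <- three_stage_params(rc)
  expect_equal(tsp$alpha_minus, 0)
  expect_equal(tsp$alpha_plus, tsp$a + tsp$gamma)
})

test_that("timescale diagnostics order the three scales and flag weak separation", {
  rc <- preset_rate_constants("table1")
  d <- timescale_diagnostics(rc)
  expect_equal(d$binding_scale, 4000)
  expect_equal(d$expression_scale, 0.03)
  expect_true(d$fast_binding_ok)
  expect_true(d$slow_expression_ok)
  expect_gt(d$ratio_fast_catalytic, 10)
  # binding scale only 5x the catalytic one -> flag
  rc2 <- update_rate_constants(rc, k_1 = 5 * rc$k_cat / 2 / rc$n_s,
                               k_m1 = 5 * rc$k_cat / 2, k_rev = 1e-6)
  d2 <- timescale_diagnostics(rc2)
  expect_false(d2$fast_binding_ok)
  # the expression scale is the slowest of the three at nominal parameters
  expect_lt(d$expression_scale, d$catalytic_scale)
  expect_lt(d$catalytic_scale, d$binding_scale)
})

test_that("rate constant validation rejects bad inputs and configs round-trip", {
  expect_error(rate_constants(n_s = 0, k_1 = 1, k_m1 = 1, k_cat = 1,
                              k_rev = 0, k_c = 1, k_tx = 1, k_tl = 1,
                              k_on = 1, k_off = 1, k_deg = 1, delta = 1),
               "n_s")
  expect_error(update_rate_constants(preset_rate_constants("table1"),
                                     k_cat = -1), "k_cat")
  expect_error(update_rate_constants(preset_rate_constants("table1"),
                                     bogus = 1), "unknown")
  rc <- preset_rate_constants("table1")
  path <- withr::local_tempfile(fileext = ".json")
  write_rate_config(rc, path)
  expect_equal(read_rate_config(path), rc)
  # YAML dialect
  pathy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(unclass(rc)), pathy)
  expect_equal(read_rate_config(pathy), rc)
  # the shipped example config is the nominal set
  shipped <- system.file("extdata", "table1_config.json",
                         package = "metanoise")
  expect_equal(read_rate_config(shipped), rc)
})

test_that("figure presets carry the published settings", {
  f1 <- preset_rate_constants("fig1c")
  expect_length(f1, 3)
  for (rc in f1) {
    expect_equal(rc$k_on, 0.01)
    ek <- effective_kinetics(rc)
    expect_equal(c(ek$lambda_inf, ek$K), c(1080, 8))
  }
  expect_equal(vapply(f1, `[[`, 0, "k_off"), c(0.03, 0.01, 1e-4),
               ignore_attr = TRUE)
  f2 <- preset_rate_constants("fig2")
  expect_equal(f2$K, 0.1333)
  expect_equal(f2$lambda_inf, c(300, 3000, 30000))
  f3 <- preset_rate_constants("fig3")
  expect_equal(f3$lambda_inf, 750)
  expect_equal(f3$K, c(10.0400, 2.1630, 0.4660))
  expect_equal(f3$switching$low[["k_on"]], 1.56e-4)
  f4 <- preset_rate_constants("fig4b_enzyme")
  expect_equal(c(f4$k_on, f4$k_off, f4$k_tx, f4$k_tl),
               c(1.56e-4, 3e-4, 0.025, 0.2))
})
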