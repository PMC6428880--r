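# Small parameter sets for oracle comparisons: fast mRNA turnover
# relative to dilution (k_deg/delta >= 4000), protein means 10-25, so the
# closed-form stationary law is in its validity regime and the truncated
# CME is cheap.
small_sets <- list(
  asym_fast = list(k_on = 0.015, k_off = 0.005, k_tx = 0.005, k_tl = 2,
                   k_deg = 2, delta = 2.5e-4),
  asym_slow = list(k_on = 1e-3, k_off = 2e-3, k_tx = 0.004, k_tl = 2,
                   k_deg = 2, delta = 2.5e-4),
  bursty = list(k_on = 5e-3, k_off = 5e-3, k_tx = 0.002, k_tl = 5,
                k_deg = 1, delta = 2.5e-4))

small_rc <- function(overrides) {
  do.call(update_rate_constants,
          c(list(preset_rate_constants("table1")), overrides))
}

test_that("three-stage pmf masses are a valid truncated distribution", {
  pmf <- three_stage_pmf(preset_rate_constants("table1"))
  expect_s3_class(pmf, "discrete_pmf")
  expect_true(all(pmf$probs >= 0))
  expect_equal(sum(pmf$probs) + pmf$tail_mass_bound, 1, tolerance = 1e-9)
  expect_lte(pmf$tail_mass_bound, 1e-8)
  # mean of the three-stage law: p_on * (k_tx/delta) * (k_tl/k_deg)
  expect_equal(pmf_mean(pmf), 0.75 * 108 * 1, tolerance = 1e-6)
})

test_that("always-on promoter reduces to the negative binomial closed form", {
  rc <- small_rc(list(k_off = 0, k_on = 0.015))
  pmf <- three_stage_pmf(rc, truncation_tol = 1e-10)
  a <- rc$k_tx / rc$delta
  b <- rc$k_tl / rc$k_deg
  nb <- dnbinom(0:pmf$support_max, size = a, prob = 1 / (1 + b))
  expect_lt(max(abs(pmf$probs - nb)), 1e-8)
  # the general formula evaluated just off the degenerate point agrees too
  rc_eps <- small_rc(list(k_off = 1e-9, k_on = 0.015))
  pmf_eps <- three_stage_pmf(rc_eps, truncation_tol = 1e-10)
  n <- 0:min(pmf$support_max, pmf_eps$support_max)
  expect_lt(max(abs(pmf_eps$probs[n + 1] - nb[n + 1])), 1e-6)
})

test_that("silent promoter gives a point mass at zero", {
  pmf <- three_stage_pmf(small_rc(list(k_on = 0)))
  expect_equal(pmf$support_max, 0L)
  expect_equal(pmf$probs, 1)
})

test_that("three-stage pmf matches the CME oracle on small parameter sets", {
  for (nm in names(small_sets)) {
    rc <- small_rc(small_sets[[nm]])
    pmf <- three_stage_pmf(rc, truncation_tol = 1e-10)
    cme <- cme_three_stage(rc, cap_mrna = 9,
                           cap_protein = max(120, pmf$support_max))
    expect_lt(tv_distance(pmf, cme$protein), 1e-3)
    expect_equal(pmf_mean(pmf), pmf_mean(cme$protein), tolerance = 1e-3)
  }
})

test_that("fast-switching limit approaches a negative binomial with effective rate a*p_on", {
  rc <- small_rc(list(k_on = 0.3, k_off = 0.1, k_tx = 0.005))
  pmf <- three_stage_pmf(rc)
  a_eff <- (rc$k_tx / rc$delta) * rc$k_on / (rc$k_on + rc$k_off)
  nb <- dnbinom(0:pmf$support_max, size = a_eff, prob = 1 / (1 + 1))
  expect_lt(sum(abs(pmf$probs - nb)) / 2, 5e-3)
})

test_that("slow switching yields a bimodal enzyme distribution", {
  rc <- small_rc(list(k_on = 3e-6, k_off = 1e-6, k_tx = 0.005))
  pmf <- three_stage_pmf(rc)
  expect_identical(classify_modality(pmf)$label, "bimodal")
})

test_that("decreasing the truncation tolerance never shrinks the support", {
  rc <- small_rc(small_sets$asym_fast)
  tols <- 10^seq(-4, -12, by = -2)
  supports <- vapply(tols, function(tol)
    three_stage_pmf(rc, truncation_tol = tol)$support_max, integer(1))
  expect_true(all(diff(supports) >= 0))
})

test_that("empirical pmf normalises, validates, and handles gaps", {
  p <- empirical_pmf(cbind(0, 1))
  expect_equal(p$probs, 1)
  p2 <- empirical_pmf(cbind(c(0, 10), c(1, 1)))
  expect_equal(p2$probs[c(1, 11)], c(0.5, 0.5))
  expect_equal(sum(p2$probs), 1)
  expect_identical(p2$provenance, "empirical")
  expect_error(empirical_pmf(cbind(c(0, 0), c(1, 1))), "duplicate")
  expect_error(empirical_pmf(cbind(0, -1)), "negative")
  expect_error(empirical_pmf(cbind(c(1, 2), c(0, 0))), "positive")
})

test_that("a discretised Gamma reproduces its continuous moments", {
  # integrating the density over [n, n+1) shifts the mean by ~ -1/2
  for (shape in c(2, 8)) for (scale in c(30, 60)) {
    g <- gamma_discretized_pmf(shape, scale, truncation_tol = 1e-10)
    expect_lte(g$tail_mass_bound, 1e-10)
    expect_equal(pmf_mean(g) + 0.5, shape * scale,
                 tolerance = 0.01)
  }
  # empirical_pmf built from the same weights agrees with the generator
  g <- gamma_discretized_pmf(3, 40)
  tab <- cbind(0:g$support_max, g$probs)
  expect_equal(empirical_pmf(tab)$probs, g$probs / sum(g$probs),
               tolerance = 1e-12)
  expect_lt(abs(pmf_mean(empirical_pmf(tab)) - 3 * 40) / (3 * 40), 0.02)
  # shape < 1 puts the mode at zero
  g0 <- gamma_discretized_pmf(0.5, 50)
  expect_equal(which.max(g0$probs), 1L)
})

test_that("pmf tables round-trip bit-identically", {
  pmf <- three_stage_pmf(small_rc(small_sets$asym_fast))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pmf(pmf, path)
  back <- read_pmf(path)
  expect_identical(back$probs, pmf$probs)
  expect_identical(back$tail_mass_bound, pmf$tail_mass_bound)
  expect_identical(back$provenance, pmf$provenance)
})
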