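test_that("quantile and cdf are closed-form inverses for every family", {
  dists <- list(
    dist_loglogistic(2.025207, 1.687245),
    dist_weibull(2.4009431, 0.3465461),
    dist_triangular(0.09, 0.21, 0.55))
  grid <- seq(0.01, 0.99, length.out = 20)
  for (d in dists) {
    expect_equal(dist_cdf(d, dist_quantile(d, grid)), grid,
                 tolerance = 1e-10, label = d$family)
  }
  expect_error(dist_quantile(dists[[1]], 1), class = "hbmtier_domain_error")
  expect_error(dist_quantile(dists[[1]], 0), class = "hbmtier_domain_error")
})

test_that("fitted exposure distribution brackets the Belgian percentile", {
  # p95 of the reconstructed Belgian children 3-PBA distribution
  expect_equal(dist_quantile(belgian_exposure_dist, 0.95), 7.22,
               tolerance = 1e-3)
  # the log-logistic median is the scale parameter exactly
  expect_identical(dist_quantile(belgian_exposure_dist, 0.5), 1.687245)
  # Weibull cdf at its scale point is 1 - 1/e
  expect_equal(dist_cdf(fue_weibull, 0.3465461), 1 - exp(-1))
})

test_that("triangular closed forms agree with their defining density", {
  d <- dist_triangular(0.09, 0.21, 0.55)
  # mode cdf equals (mode-min)/(max-min)
  expect_equal(dist_cdf(d, 0.21), (0.21 - 0.09) / (0.55 - 0.09))
  expect_equal(dist_mean(d), (0.09 + 0.21 + 0.55) / 3)
  expect_equal(dist_cdf(d, 0.05), 0)
  expect_equal(dist_cdf(d, 0.6), 1)
})

test_that("quantile fitting recovers generating parameters exactly", {
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  ll <- dist_loglogistic(2.0, 1.7)
  fit_ll <- fit_to_quantiles(
    tibble::tibble(p = probs, value = dist_quantile(ll, probs)), "loglogistic")
  expect_equal(fit_ll$params$shape, 2.0, tolerance = 1e-6)
  expect_equal(fit_ll$params$scale, 1.7, tolerance = 1e-6)
  wb <- dist_weibull(2.4009431, 0.3465461)
  fit_wb <- fit_to_quantiles(
    tibble::tibble(p = probs, value = dist_quantile(wb, probs)), "weibull")
  expect_equal(fit_wb$params$shape, 2.4009431, tolerance = 1e-6)
  expect_equal(fit_wb$params$scale, 0.3465461, tolerance = 1e-6)
  # two quantiles, two parameters: exact interpolation, zero objective
  fit2 <- fit_to_quantiles(
    tibble::tibble(p = c(0.5, 0.95), value = dist_quantile(ll, c(0.5, 0.95))),
    "loglogistic")
  expect_lt(attr(fit2, "objective_value"), 1e-20)
  # non-monotone input is rejected
  expect_error(fit_to_quantiles(tibble::tibble(p = c(0.5, 0.95),
                                               value = c(3, 2)),
                                "loglogistic"),
               class = "hbmtier_validation_error")
})

test_that("quantile fitting tolerates small perturbations of the input", {
  # regression: 0.5% relative noise moves parameters by less than 1%
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  ll <- dist_loglogistic(2.025207, 1.687245)
  set.seed(7)
  for (i in 1:10) {
    noisy <- sort(dist_quantile(ll, probs) * (1 + runif(5, -0.005, 0.005)))
    fit <- fit_to_quantiles(tibble::tibble(p = probs, value = noisy),
                            "loglogistic")
    expect_equal(fit$params$shape, 2.025207, tolerance = 0.01)
    expect_equal(fit$params$scale, 1.687245, tolerance = 0.01)
  }
})

test_that("screening-value simulation matches its analytic anchors", {
  # degenerate fraction: every sample equals the deterministic value
  mc_pt <- mc_screening_distribution(reg, "children",
                                     fue_dist = dist_point(0.09),
                                     n = 500, seed = 11)
  det <- derive_screening_value(reg, "3-PBA", "children")$raw_gv
  expect_true(all(abs(mc_pt$samples - det) < 1e-12))
  # triangular fraction: empirical median near the value at the triangular
  # median (the screening value is linear in the fraction)
  mc_tri <- mc_screening_distribution(reg, "children", n = 10000, seed = 12)
  tri_med <- dist_quantile(dist_triangular(0.09, 0.21, 0.55), 0.5)
  expect_equal(unname(mc_tri$sample_quantiles["p50"]),
               det / 0.09 * tri_med, tolerance = 0.02)
  # seeded runs are identical
  mc_rep <- mc_screening_distribution(reg, "children", n = 10000, seed = 12)
  expect_identical(mc_tri$samples, mc_rep$samples)
})

test_that("exceedance simulation agrees with the closed-form survival oracle", {
  # degenerate fraction at 0.307: closed-form log-logistic survival ~2.2%
  gv_per_fue <- derive_screening_value(reg, "3-PBA", "children")$raw_gv / 0.09
  cf <- exceedance_closed_form(belgian_exposure_dist, gv_per_fue,
                               dist_point(0.307))
  expect_equal(cf, 0.0224, tolerance = 0.01)
  mc <- mc_exceedance(belgian_exposure_dist, dist_point(0.307), reg,
                      n = 10000, seed = 21)
  expect_lt(abs(mc$exceedance_probability - cf), 3 * mc$mcse + 1e-12)
  # sampled Weibull fraction: agrees with the numerically integrated oracle
  cf_wb <- exceedance_closed_form(belgian_exposure_dist, gv_per_fue,
                                  fue_weibull)
  mc_wb <- mc_exceedance(belgian_exposure_dist, fue_weibull, reg,
                         n = 10000, seed = 22)
  expect_lt(abs(mc_wb$exceedance_probability - cf_wb), 3 * mc_wb$mcse)
  # unreachable guidance value: probability 0
  mc_far <- mc_exceedance(dist_point(1e-6), dist_point(0.9), reg,
                          n = 200, seed = 23)
  expect_identical(mc_far$exceedance_probability, 0)
})

test_that("exceedance is monotone in the guidance-value ingredients", {
  # raising every ADI raises the guidance value and lowers the exceedance
  base <- mc_exceedance(belgian_exposure_dist, dist_point(0.307), reg,
                        n = 5000, seed = 31)
  reg_hi <- reg
  reg_hi$substances$adi_mg_per_kg_bw_day <-
    reg_hi$substances$adi_mg_per_kg_bw_day * 3
  hi_adi <- mc_exceedance(belgian_exposure_dist, dist_point(0.307), reg_hi,
                          n = 5000, seed = 31)
  expect_lt(hi_adi$exceedance_probability, base$exceedance_probability)
  # raising the fraction likewise
  hi_fue <- mc_exceedance(belgian_exposure_dist, dist_point(0.55), reg,
                          n = 5000, seed = 31)
  expect_lt(hi_fue$exceedance_probability, base$exceedance_probability)
})

test_that("mixed-substance attribution lowers the exceedance into the published band", {
  single <- mc_exceedance(belgian_exposure_dist, dist_point(0.307), reg,
                          n = 10000, seed = 41)
  mixed <- mc_exceedance(belgian_exposure_dist, dist_point(0.307), reg,
                         scenario = "mixed_adi", n = 10000, seed = 41)
  expect_lt(mixed$exceedance_probability, single$exceedance_probability)
  expect_lte(mixed$exceedance_probability, 0.011)
  expect_gte(mixed$exceedance_probability, 0.001)
  # seeded reproducibility across repeated invocations
  mixed2 <- mc_exceedance(belgian_exposure_dist, dist_point(0.307), reg,
                          scenario = "mixed_adi", n = 10000, seed = 41)
  expect_identical(mixed$samples, mixed2$samples)
  expect_identical(mixed$exceedance_probability, mixed2$exceedance_probability)
})

test_that("monte carlo results expose tidy summaries and diagnostics", {
  mc <- mc_exceedance(belgian_exposure_dist, fue_weibull, reg,
                      n = 2000, seed = 51)
  g <- glance(mc)
  expect_equal(g$n, 2000)
  expect_equal(g$mcse, sqrt(g$exceedance_probability *
                              (1 - g$exceedance_probability) / 2000))
  td <- tidy(mc)
  expect_true(all(c("p5", "p50", "p95") %in% td$quantile))
  expect_s3_class(autoplot(mc), "ggplot")
})
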