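test_that("noise-free Verhulst data are recovered to 1e-4 relative", {
  p <- growth_params(r = 0.8, K = 1e6, N0 = 1e4)
  curve <- growth_curve(0:21, verhulst_solution(p, 0:21))
  fit <- fit_growth(curve, "verhulst")
  expect_true(fit$converged)
  est <- coef(fit)
  expect_equal(est[["r"]], 0.8, tolerance = 1e-4)
  expect_equal(est[["K"]], 1e6, tolerance = 1e-4)
  expect_equal(est[["N0"]], 1e4, tolerance = 1e-4)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-8)
  expect_length(residuals(fit), 22)
  expect_equal(predict(fit, c(0, 21)), verhulst_solution(p, c(0, 21)),
               tolerance = 1e-4)
})

test_that("constant counts are flagged degenerate, not an error", {
  curve <- growth_curve(0:9, rep(1000, 10))
  fit <- fit_growth(curve, "verhulst")
  expect_true(fit$degenerate)
  expect_true(is.na(fit$adj_r2))
})

test_that("growth rate is recovered within 5% median error under 5% noise", {
  p <- growth_params(r = 0.8, K = 1e6, N0 = 1e4)
  set.seed(5)
  rel_err <- replicate(50, {
    curve <- generate_growth_curve(p, 0:21, noise_cv = 0.05)
    fit <- fit_growth(curve, "verhulst")
    abs(coef(fit)[["r"]] - 0.8) / 0.8
  })
  expect_lt(median(rel_err), 0.05)
})

test_that("adjusted R2 follows its defining formula", {
  expect_equal(adjusted_r2(1, n = 20, k = 3), 1)      # perfect fit
  expect_lte(adjusted_r2(0, n = 20, k = 3), 0)        # mean-only fit
  expect_equal(adjusted_r2(0.99, n = 20, k = 3), 1 - 0.01 * 19 / 16)
  expect_error(adjusted_r2(0.5, n = 4, k = 3), "exceed")
})

test_that("AIC ranking penalizes parameters and finds the generator", {
  # on exact Verhulst data both logistic-family models interpolate
  # (identical RSS floor), so the 3-parameter model must rank first
  p <- growth_params(r = 0.6, K = 1e6, N0 = 2e4)
  exact <- growth_curve(0:21, verhulst_solution(p, 0:21))
  fits <- list(fit_growth(exact, "verhulst"), fit_growth(exact, "richards"))
  rk <- rank_growth_models(fits)
  expect_equal(rk$model[1], "verhulst")

  # Richards generator with strong shape (v = 3): Richards usually wins
  set.seed(6)
  pr <- growth_params(r = 0.5, K = 1e6, N0 = 2e4, v = 3)
  wins <- replicate(20, {
    curve <- generate_growth_curve(pr, 0:21, noise_cv = 0.02,
                                   model = "richards")
    fits <- lapply(c("verhulst", "richards"), fit_growth, curve = curve)
    rank_growth_models(fits)$model[1] == "richards"
  })
  expect_gt(mean(wins), 0.5)

  # Verhulst generator: parsimony keeps Verhulst ahead of Richards
  set.seed(7)
  wins_v <- replicate(20, {
    curve <- generate_growth_curve(p, 0:21, noise_cv = 0.02)
    fits <- lapply(c("verhulst", "richards"), fit_growth, curve = curve)
    rank_growth_models(fits)$model[1] == "verhulst"
  })
  expect_gt(mean(wins_v), 0.5)
})

test_that("profile likelihood matches the full fit and bounds shrink with noise", {
  p <- growth_params(r = 0.7, K = 8e5, N0 = 2e4)
  set.seed(8)
  curve <- generate_growth_curve(p, 0:18, noise_cv = 0.03)
  fit <- fit_growth(curve, "verhulst")
  prof <- profile(fit, "K")
  # the profile maximum equals the unconstrained maximum
  expect_lt(abs(prof$max_logLik - fit$logLik), 1e-6)
  expect_true(prof$identifiable)
  # CI contains the point estimate
  expect_gte(fit$params$K, prof$ci[1])
  expect_lte(fit$params$K, prof$ci[2])

  # with less noise the confidence region tightens
  set.seed(9)
  curve_lo <- generate_growth_curve(p, 0:18, noise_cv = 0.005)
  prof_lo <- profile(fit_growth(curve_lo, "verhulst"), "K")
  width <- function(pr) sum(pr$profile_logLik >= pr$cutoff)
  expect_lte(width(prof_lo), width(prof))
})

test_that("exponential-phase data leave K practically non-identifiable", {
  # counts far below capacity constrain only r: every sufficiently large K
  # fits equally well, so the upper profile CI escapes the searched range
  set.seed(12)
  expo <- growth_curve(0:8, 200 * exp(0.5 * (0:8)) * exp(rnorm(9, 0, 0.02)))
  prof <- profile(fit_growth(expo, "verhulst"), "K")
  expect_false(prof$identifiable)
  expect_identical(prof$ci[2], Inf)
})

test_that("Richards shape v is non-identifiable without a saturation phase", {
  # contact inhibition never manifests in exponential-phase data, so any
  # shape exponent v (with K adjusted) fits the data equally well
  set.seed(12)
  expo <- growth_curve(0:8, 200 * exp(0.5 * (0:8)) * exp(rnorm(9, 0, 0.02)))
  fit <- fit_growth(expo, "richards")
  prof <- profile(fit, "v")
  expect_false(prof$identifiable)
})

test_that("stopping criterion: stable plateau stops, exponential phase does not", {
  p <- growth_params(r = 0.9, K = 5e5, N0 = 2e4)
  # exactly-logistic noise-free curve: all truncated estimates identical
  exact <- growth_curve(0:20, verhulst_solution(p, 0:20))
  expect_true(stopping_criterion(exact))
  # long plateau with mild noise
  set.seed(13)
  plateau <- generate_growth_curve(p, 0:20, noise_cv = 0.03)
  expect_true(stopping_criterion(plateau))
  # still exponential: inferred K drifts under truncation
  expo <- growth_curve(0:14, 100 * exp(0.4 * (0:14)))
  expect_false(stopping_criterion(expo))
})

test_that("r and K estimates are nearly unbiased at the observed noise level", {
  p <- growth_params(r = 0.8, K = 1e6, N0 = 1e4)
  set.seed(14)
  est <- replicate(200, {
    curve <- generate_growth_curve(p, 0:21, noise_cv = 0.05)
    coef(fit_growth(curve, "verhulst"))[c("r", "K")]
  })
  expect_lt(abs(mean(est["r", ]) - 0.8) / 0.8, 0.02)
  expect_lt(abs(mean(est["K", ]) - 1e6) / 1e6, 0.02)
})
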