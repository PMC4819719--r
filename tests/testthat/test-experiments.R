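test_that("attenuation budget orderings across b, diameter and diffusivity", {
  bud <- run_attenuation_budget(b = c(0, 500, 1000, 2000, 4000))
  z <- dplyr::filter(bud, b == 0)
  expect_true(all(z$intra_pct == 0 & z$extra_pct == 0))
  # strictly increasing in b
  mono <- dplyr::summarise(
    dplyr::group_by(bud, distribution, D_f),
    intra = all(diff(intra_pct[order(b)]) > 0),
    extra = all(diff(extra_pct[order(b)]) > 0),
    .groups = "drop"
  )
  expect_true(all(mono$intra & mono$extra))
  # at b = 4000: intra attenuation grows with diameter, shrinks with D_f
  b4 <- dplyr::filter(bud, b == 4000)
  for (d in unique(b4$D_f)) {
    small <- dplyr::filter(b4, D_f == d, distribution == "smallest")$intra_pct
    large <- dplyr::filter(b4, D_f == d, distribution == "largest")$intra_pct
    expect_gt(large, small)
  }
  for (ds in unique(b4$distribution)) {
    sub <- dplyr::filter(b4, distribution == ds)
    expect_true(all(diff(sub$intra_pct[order(sub$D_f)]) < 0))
  }
})

test_that("BIC trend selection identifies flat, linear and noisy-flat series", {
  expect_equal(bic_trend_select(1:9, rep(0.4, 9))$trend, "constant")
  up <- bic_trend_select(1:9, 0.1 + 0.02 * (1:9))
  expect_equal(up$model, "linear")
  expect_equal(up$trend, "increasing")
  dn <- bic_trend_select(1:9, 1 - 0.03 * (1:9))
  expect_equal(dn$trend, "decreasing")
  expect_error(bic_trend_select(1:3, 1:3))
  # flat truth + small noise: constant is selected far more often than
  # either alternative (the three-model race caps the rate near 2/3;
  # pairwise against the linear model alone it is ~0.8)
  sel <- withr::with_seed(1, vapply(1:400, function(i) {
    y <- 0.5 + rnorm(9, 0, 0.01)
    bic_trend_select(1:9, y)$model
  }, character(1)))
  expect_gt(mean(sel == "constant"), 0.6)
  expect_lt(mean(sel == "linear"), 0.25)
  expect_lt(mean(sel == "quadratic"), 0.25)
})

test_that("difference-method SNR matches its closed form and invariances", {
  set.seed(3)
  a <- 10 + rnorm(1e5, 0, 0.5)
  b <- 10 + rnorm(1e5, 0, 0.5)
  expect_equal(snr_difference(a, b), 10 / 0.5, tolerance = 0.02)
  expect_error(snr_difference(a, a), "zero difference")
  expect_equal(snr_difference(3 * a, 3 * b), snr_difference(a, b))
})

test_that("precision factor is sqrt(N); 216 measurements give almost 15", {
  expect_equal(precision_gain(1), 1)
  expect_equal(precision_gain(4), 2)
  expect_equal(precision_gain(216), 14.70, tolerance = 1e-3)
  expect_lt(precision_gain(216), 15)
})

test_that("noiseless density-bias run: free tensor exact, tortuosity trending", {
  rep <- run_density_bias_experiment(
    f_r = c(0.3, 0.5), radii = c(0.25, 1.5), snr = Inf, n_rep = 1,
    fit_cfg = fit_config(multistart = 1), seed = 2
  )
  free <- dplyr::filter(rep$summary, variant == "free_tensor")
  expect_true(all(abs(free$mean_f_r - free$f_r) < 1e-3))
  ftr <- dplyr::filter(rep$trends, variant == "free_tensor")
  expect_true(all(ftr$trend == "constant"))
  # tortuosity: a diffusion-time trend in at least 3 of 4 conditions,
  # with both over- and under-estimation across conditions
  tor <- dplyr::filter(rep$summary, variant == "tortuosity")
  ttr <- dplyr::filter(rep$trends, variant == "tortuosity")
  expect_gte(sum(ttr$trend != "constant"), 3)
  bias <- dplyr::summarise(
    dplyr::group_by(tor, f_r, radius),
    bias = mean(mean_f_r - f_r), .groups = "drop"
  )
  expect_true(any(bias$bias > 0.01) && any(bias$bias < -0.01))
})

test_that("accuracy experiment: high accuracy except the disorder coefficient", {
  rep <- run_accuracy_experiment(n_rep = 12, seed = 3)
  acc <- tibble::deframe(rep$summary)
  expect_gt(acc["f_r"], 80)
  expect_gt(acc["D_par"], 80)
  expect_gt(acc["D_inf"], 80)
  expect_lt(acc["A"], acc["f_r"])
  expect_lt(acc["A"], acc["D_inf"])
})
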