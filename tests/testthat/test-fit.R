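test_that("T1 pre-fit recovers exact and closed-form cases", {
  tm <- c(14.4, 26.4, 46.4, 66.4, 86.4, 106.4, 126.4, 146.4, 161.4)
  d <- tibble::tibble(TM = tm, signal = 1.7 * exp(-tm / 800))
  f <- fit_t1(d)
  expect_equal(unname(coef(f)["T1"]), 800, tolerance = 1e-6)
  expect_equal(unname(coef(f)["S0"]), 1.7, tolerance = 1e-6)
  # two-point half-life identity
  d2 <- tibble::tibble(TM = c(0, 800 * log(2)), signal = c(1, 0.5))
  expect_equal(unname(coef(fit_t1(d2))["T1"]), 800, tolerance = 1e-6)
  expect_error(fit_t1(tibble::tibble(TM = c(5, 5), signal = c(1, 1))))
})

test_that("T1 recovery is robust to Rician noise across seeds", {
  sch <- steam_scheme()
  b0 <- dplyr::filter(sch, is_b0)
  truth <- exp(-b0$TM / 800)
  t1s <- vapply(1:60, function(s) {
    noisy <- dplyr::mutate(b0,
      signal = add_rician_noise(truth, 30, max(truth), seed = s)
    )
    unname(coef(fit_t1(noisy, config = fit_config(multistart = 1)))["T1"])
  }, numeric(1))
  expect_lt(abs(median(t1s) / 800 - 1), 0.05)
})

test_that("density fits recover truth from consistent noiseless data", {
  set.seed(1)
  sch <- steam_scheme()
  # generator with a constant D_perp consistent with both variants:
  # D_perp = D_par (1 - f_r) so tortuosity is exactly satisfied
  tis <- tissue_params(
    f_r = 0.4,
    hindered = hindered_spec("free_tensor", D_hpar = 1.5, D_hperp = 0.9),
    distribution = axon_distribution("delta", radius = 1),
    D_rpar = 1.5, D_f = 1.5
  )
  grp <- dplyr::filter(steam_signal(sch, tis), Delta == 100)
  for (v in c("free_tensor", "tortuosity")) {
    fit <- fit_density(grp, v)
    expect_equal(unname(coef(fit)["f_r"]), 0.4, tolerance = 1e-3)
    expect_equal(unname(coef(fit)["D_par"]), 1.5, tolerance = 1e-2)
    expect_true(fit$converged)
  }
  expect_error(fit_density(steam_signal(sch, tis)), "single Delta")
})

test_that("time-dependent truth biases the tortuosity density fit, not the free tensor", {
  set.seed(2)
  sch <- steam_scheme()
  tis <- make_tissue(f_r = 0.3, D = 1, R = 1.5)
  sig <- steam_signal(sch, tis)
  ests <- purrr::map_dfr(c(48, 100, 195), function(D) {
    grp <- dplyr::filter(sig, Delta == D)
    tibble::tibble(
      Delta = D,
      free = unname(coef(fit_density(grp, "free_tensor",
        radius_prior = tis$distribution
      ))["f_r"]),
      tort = unname(coef(fit_density(grp, "tortuosity",
        radius_prior = tis$distribution
      ))["f_r"])
    )
  })
  # free tensor: no Delta trend, unbiased
  expect_true(all(abs(ests$free - 0.3) < 1e-3))
  # tortuosity: biased, and the bias changes with Delta
  expect_gt(max(abs(ests$tort - 0.3)), 0.02)
  expect_gt(diff(range(ests$tort)), 0.01)
})

test_that("noiseless diameter fit is a round-trip identity", {
  set.seed(3)
  sch <- steam_scheme()
  tis <- make_tissue(f_r = 0.45, D = 1.3, R = 1.2, D_inf = 0.6, A = 1.5)
  sig <- steam_signal(sch, tis, S0 = 1.4)
  fit <- fit_diameter(sig, time_dependent = TRUE, family = "delta")
  est <- coef(fit)
  truth <- c(f_r = 0.45, D_par = 1.3, R = 1.2, D_inf = 0.6, A = 1.5)
  expect_true(all(abs(est[names(truth)] - truth) / truth < 0.005))
  expect_equal(fit$T1_fixed, 800, tolerance = 1e-3)
  # per-Delta-normalised variant drops T1 and still recovers
  fit2 <- fit_diameter(sig,
    time_dependent = TRUE, family = "delta",
    normalize = "per_delta"
  )
  expect_true(all(abs(coef(fit2)[names(truth)] - truth) / truth < 0.005))
  expect_error(
    fit_diameter(dplyr::filter(sig, Delta < 70), family = "delta"),
    ">= 3 Delta"
  )
})

test_that("poisson-distribution diameter fit recovers a poisson generator", {
  set.seed(4)
  sch <- steam_scheme()
  gen <- axon_distribution("poisson", rate = 0.9)
  tis <- tissue_params(
    f_r = 0.5,
    hindered = hindered_spec("time_dependent",
      D_hpar = 1.4, D_inf = 0.55,
      A = 1
    ),
    distribution = gen, D_rpar = 1.4, D_f = 1.4
  )
  sig <- steam_signal(sch, tis)
  fit <- fit_diameter(sig, time_dependent = TRUE, family = "poisson")
  expect_equal(unname(coef(fit)["lambda"]), 0.9, tolerance = 0.02)
  expect_equal(
    unname(coef(fit)["mean_diameter"]),
    2 * mean_radius(gen),
    tolerance = 0.02
  )
})

test_that("fits are bit-identical under a fixed seed and respect bounds", {
  sch <- steam_scheme()
  tis <- make_tissue()
  sig <- steam_signal(sch, tis)
  noisy <- dplyr::mutate(sig,
    signal = add_rician_noise(signal, 30, max(signal), seed = 9)
  )
  f1 <- withr::with_seed(5, fit_diameter(noisy, family = "delta"))
  f2 <- withr::with_seed(5, fit_diameter(noisy, family = "delta"))
  expect_identical(coef(f1), coef(f2))
  box <- axontime:::.par_box(c("f_r", "D_par", "R", "D_inf", "A"))
  est <- coef(f1)[c("f_r", "D_par", "R", "D_inf", "A")]
  expect_true(all(est >= box$lower - 1e-12 & est <= box$upper + 1e-12))
})

test_that("accuracy metric arithmetic and edge cases", {
  expect_equal(
    parameter_accuracy(data.frame(a = c(1, 1)), c(a = 1))$accuracy, 100
  )
  expect_equal(
    parameter_accuracy(data.frame(a = 1.2 * c(1, 1)), c(a = 1))$accuracy, 80
  )
  expect_error(parameter_accuracy(data.frame(a = 1), c(a = 0)), "zero")
})

test_that("tidy and glance expose broom-style summaries", {
  d <- tibble::tibble(TM = seq(10, 170, 20), signal = 2 * exp(-TM / 800))
  f <- fit_t1(d)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_setequal(td$term, c("S0", "T1"))
  gl <- glance(f)
  expect_true(gl$converged)
  expect_equal(gl$variant, "t1")
})
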