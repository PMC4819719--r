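# Walks kept small: a few thousand walkers suffice for the closed-form
# calibration checks at their Monte Carlo tolerances.

test_that("free diffusion calibration: MSD linear with the right slopes", {
  far <- pack_cylinders(5, target_icvf = pi * 25 / 4e6, box = 2000)
  cfg <- mc_config(
    n_walkers = 6000, duration = 50, D_f = 1.5, n_steps = 2000,
    intra_fraction = 0
  )
  w <- random_walk(far, cfg, seed = 1)
  msd_t <- mean((w$y - w$y0)^2 + (w$z - w$z0)^2)
  msd_x <- mean(w$x^2)
  expect_lt(abs(msd_t / (4 * 1.5 * 50) - 1), 0.05)
  expect_lt(abs(msd_x / (2 * 1.5 * 50) - 1), 0.05)
  # b = 1000 free-water signal ~ exp(-b D) (Gaussian phase)
  sch <- dplyr::filter(steam_scheme(), Delta == 48, ny %in% c(0, 1), nz == 0)
  cfg2 <- mc_config(
    n_walkers = 6000, duration = 70, D_f = 1.5, n_steps = 2000,
    intra_fraction = 0
  )
  sig <- mc_signal(far, sch, cfg2, T1 = 800, seed = 2)
  b1000 <- dplyr::filter(sig, b == 1000, ny == 1)
  s0 <- mean(dplyr::filter(sig, is_b0)$signal)
  expect_equal(-log(b1000$signal / s0), 1.5, tolerance = 0.05)
})

test_that("confined walkers saturate at the disk displacement variance", {
  sub <- pack_cylinders(2, target_icvf = pi * 4 / 400, box = 20)
  cfg <- mc_config(
    n_walkers = 4000, duration = 100, D_f = 1.5,
    intra_fraction = 1
  )
  w <- random_walk(sub, cfg, seed = 3)
  # long-time displacement variance of uniform points in a disk: R^2 per
  # plane pair (R^2/2 + R^2/2)
  expect_equal(mean((w$y - w$y0)^2 + (w$z - w$z0)^2), 4, tolerance = 0.05)
})

test_that("impermeability: compartment membership is conserved", {
  sub <- pack_cylinders(substrate_radii(1.52, 3000, seed = 4), 0.55, 25,
    seed = 5
  )
  cfg <- mc_config(
    n_walkers = 3000, duration = 30, D_f = 1.5,
    intra_fraction = 0.6
  )
  w <- random_walk(sub, cfg, seed = 6)
  expect_identical(w$membership_end, w$membership)
  # too-coarse discretization is refused
  cfg_bad <- mc_config(
    n_walkers = 10, duration = 212, D_f = 1.5,
    n_steps = 500
  )
  expect_error(random_walk(sub, cfg_bad, seed = 1), "too coarse")
})

test_that("intra-cylinder MC signal matches the analytic cylinder model", {
  sub <- pack_cylinders(1.5, target_icvf = pi * 1.5^2 / 400, box = 20)
  sch <- dplyr::filter(steam_scheme(), Delta %in% c(48, 120))
  cfg <- mc_config(
    n_walkers = 6000, duration = 137, D_f = 1.5,
    intra_fraction = 1
  )
  sig <- mc_signal(sub, sch, cfg, T1 = 800, seed = 7)
  perp <- dplyr::filter(sig, ny == 1, nz == 0)
  s0 <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(sig, is_b0), Delta),
    s0 = mean(signal), .groups = "drop"
  )
  perp <- dplyr::left_join(perp, s0, by = "Delta")
  vg <- mapply(
    function(b, D) {
      restricted_perp_signal(q_for_b(b, 17, D), D, 17, 1.5, 1.5)
    },
    perp$b, perp$Delta
  )
  expect_equal(perp$signal / perp$s0, vg, tolerance = 0.002)
})

test_that("mc_signal honours T1 decay and scheme-duration preconditions", {
  sub <- pack_cylinders(1.5, target_icvf = pi * 1.5^2 / 400, box = 20)
  sch <- dplyr::filter(steam_scheme(), Delta == 48)
  cfg <- mc_config(n_walkers = 50, duration = 65, D_f = 1.5)
  sig <- mc_signal(sub, sch, cfg, T1 = 800, seed = 8)
  expect_equal(
    dplyr::filter(sig, is_b0)$signal,
    exp(-dplyr::filter(sig, is_b0)$TM / 800)
  )
  expect_error(
    mc_signal(sub, steam_scheme(), cfg, seed = 8),
    "exceeds walk duration"
  )
})

test_that("apparent perpendicular diffusivity reads mono-exponentials exactly", {
  sch <- dplyr::filter(steam_scheme(), Delta %in% c(48, 100))
  # synthetic signals with D = 0.4 along y and 0.6 along z
  d_dir <- ifelse(sch$ny == 1 & sch$nz == 0, 0.4,
    ifelse(sch$nz == 1 & sch$ny == 0, 0.6, 0.5)
  )
  sig <- dplyr::mutate(sch, signal = exp(-(b / 1000) * d_dir))
  adc <- apparent_dperp(sig)
  expect_equal(adc$adc, c(0.5, 0.5), tolerance = 1e-10)
  bad <- dplyr::mutate(sch, signal = -1)
  expect_error(apparent_dperp(bad), "nonpositive")
})
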