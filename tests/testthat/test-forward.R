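test_that("cylinder eigenvalue roots are universal after rescaling", {
  r1 <- bessel_alpha_roots(1, 5)
  expect_length(r1, 5)
  expect_true(all(diff(r1) > 0))
  expect_equal(r1[1], 1.8412, tolerance = 1e-4)
  expect_equal(bessel_alpha_roots(2, 5), r1 / 2)
  expect_error(bessel_alpha_roots(0))
})

test_that("restricted perpendicular signal matches a long-series oracle", {
  for (case in list(
    list(b = 4000, Delta = 48, D_f = 0.7, R = 0.97),
    list(b = 2000, Delta = 100, D_f = 1.5, R = 2),
    list(b = 500, Delta = 195, D_f = 2.4, R = 3)
  )) {
    q <- q_for_b(case$b, 17, case$Delta)
    expect_equal(
      restricted_perp_signal(q, case$Delta, 17, case$D_f, case$R),
      oracle_vg_perp(q, case$Delta, 17, case$D_f, case$R),
      tolerance = 1e-10
    )
  }
})

test_that("restricted perpendicular signal limits and monotonicity", {
  expect_identical(restricted_perp_signal(0, 48, 17, 1.5, 1), 1)
  # attenuation vanishes as R^4 in the small-radius limit
  q <- q_for_b(4000)
  expect_gt(restricted_perp_signal(q, 48, 17, 1.5, 0.01), 0.9999)
  # monotone non-increasing in q and R
  qs <- seq(0, 0.05, length.out = 6)
  s_q <- vapply(qs, restricted_perp_signal, numeric(1),
    Delta = 48, delta = 17, D_f = 1.5, R = 2
  )
  expect_true(all(diff(s_q) <= 0))
  rs <- c(0.5, 1, 2, 3, 4)
  s_r <- vapply(rs, function(r) {
    restricted_perp_signal(q, 48, 17, 1.5, r)
  }, numeric(1))
  expect_true(all(diff(s_r) <= 0))
  # truncation: 20 vs 50 terms indistinguishable at 1e-9 over the regimes of use
  for (R in c(0.5, 2, 5)) {
    expect_lt(
      abs(restricted_perp_signal(q, 48, 17, 0.7, R, m_max = 20) -
        restricted_perp_signal(q, 48, 17, 0.7, R, m_max = 50)),
      1e-9
    )
  }
  # too-short series is flagged
  expect_warning(restricted_perp_signal(q, 48, 17, 0.7, 5, m_max = 3),
    "not converged"
  )
})

test_that("parallel restricted signal is mono-exponential in b", {
  expect_equal(restricted_parallel_signal(0, 48, 17, 1.5), 1)
  expect_equal(restricted_parallel_signal(0.05, 48, 17, 0), 1)
  q1 <- q_for_b(1000)
  q2 <- q_for_b(2000)
  expect_equal(
    log(restricted_parallel_signal(q2, 48, 17, 1.2)) /
      log(restricted_parallel_signal(q1, 48, 17, 1.2)),
    2,
    tolerance = 1e-12
  )
  expect_error(restricted_parallel_signal(0.01, 48, 17, -1))
})

test_that("area weights follow the r^2 law and shift mass upward", {
  d <- axon_distribution("delta", radius = 1)
  expect_equal(area_weights(d), 1)
  two <- axon_distribution("empirical",
    radius_grid = c(1, 2),
    count_weights = c(0.5, 0.5)
  )
  expect_equal(area_weights(two), c(0.2, 0.8))
  pois <- axon_distribution("poisson", rate = 0.8)
  expect_equal(sum(area_weights(pois)), 1, tolerance = 1e-12)
  expect_true(all(area_weights(pois) >= 0))
  expect_gt(mean_radius(pois, "area"), mean_radius(pois, "count"))
  gam <- axon_distribution("gamma", shape = 3, scale = 0.2)
  expect_gt(mean_radius(gam, "area"), mean_radius(gam, "count"))
  expect_error(
    axon_distribution("empirical",
      radius_grid = c(1, 2),
      count_weights = c(0, 0)
    )
  )
})

test_that("hindered perpendicular diffusivity variants", {
  tort <- hindered_spec("tortuosity", D_hpar = 1.5)
  expect_equal(hindered_dperp(tort, f_r = 0.5), 0.75)
  td0 <- hindered_spec("time_dependent", D_hpar = 1.5, D_inf = 0.4, A = 0)
  expect_equal(
    hindered_dperp(td0, Delta = c(48, 100, 195), delta = 17),
    rep(0.4, 3)
  )
  td <- hindered_spec("time_dependent", D_hpar = 1.5, D_inf = 0.5, A = 2)
  expect_equal(
    hindered_dperp(td, Delta = 48, delta = 17),
    0.5 + 2 * (log(48 / 17) + 1.5) / (48 - 17 / 3)
  )
  # strictly decreasing in Delta for A > 0
  dp <- hindered_dperp(td, Delta = c(48, 60, 80, 100, 120, 140, 160, 180, 195), delta = 17)
  expect_true(all(diff(dp) < 0))
  # log approximation warning for small Delta/delta
  expect_warning(hindered_dperp(td, Delta = 20, delta = 17), "Delta/delta")
  expect_no_warning(hindered_dperp(td, Delta = 48, delta = 17))
  # free tensor carries its own value; tortuosity refuses one
  ft <- hindered_spec("free_tensor", D_hpar = 1.5, D_hperp = 0.6)
  expect_equal(hindered_dperp(ft), 0.6)
  expect_error(hindered_spec("tortuosity", D_hpar = 1, D_hperp = 0.5))
})

test_that("hindered signal diagonalises along the fiber frame", {
  sch <- steam_scheme()
  ft <- hindered_spec("free_tensor", D_hpar = 1.5, D_hperp = 0.5)
  s <- hindered_signal(sch, ft, fiber_dir = c(1, 0, 0))
  expect_true(all(s[sch$is_b0] == 1))
  # oblique decomposition against a hand evaluation
  geomq <- q_from_gradient(sch$g, sch$delta)
  cosang <- sch$nx
  manual <- exp(-4 * pi^2 * (sch$Delta - sch$delta / 3) *
    ((geomq * cosang)^2 * 1.5 + (geomq^2 - (geomq * cosang)^2) * 0.5))
  expect_equal(s[!sch$is_b0], manual[!sch$is_b0], tolerance = 1e-12)
  # rotation invariance: rotate scheme directions and fiber together
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  dirs <- t(Rz %*% t(cbind(sch$nx, sch$ny, sch$nz)))
  rot <- dplyr::mutate(sch, nx = dirs[, 1], ny = dirs[, 2], nz = dirs[, 3])
  s_rot <- hindered_signal(rot, ft, fiber_dir = as.numeric(Rz %*% c(1, 0, 0)))
  expect_equal(s_rot, s, tolerance = 1e-12)
})

test_that("restricted signal composes weights and separability holds", {
  sch <- steam_scheme()
  tis <- make_tissue()
  # q parallel to the fiber reduces to the parallel factor
  par_rows <- dplyr::filter(sch, nx == 1, !is_b0)
  s <- restricted_signal(par_rows, tis)
  q <- q_from_gradient(par_rows$g, par_rows$delta)
  expect_equal(
    s,
    restricted_parallel_signal(q, par_rows$Delta, 17, tis$D_rpar),
    tolerance = 1e-12
  )
  # two-radius mixture equals the manual weighted sum of single-radius calls
  two <- axon_distribution("empirical",
    radius_grid = c(0.8, 1.6),
    count_weights = c(0.7, 0.3)
  )
  tis2 <- tissue_params(
    f_r = 0.5, hindered = tis$hindered, distribution = two,
    D_rpar = 1.2, D_f = 1.2
  )
  perp_rows <- dplyr::filter(sch, ny == 1, nz == 0, !is_b0)
  mix <- restricted_signal(perp_rows, tis2)
  w <- area_weights(two)
  qp <- q_from_gradient(perp_rows$g, perp_rows$delta)
  manual <- vapply(seq_len(nrow(perp_rows)), function(i) {
    w[1] * restricted_perp_signal(qp[i], perp_rows$Delta[i], 17, 1.2, 0.8) +
      w[2] * restricted_perp_signal(qp[i], perp_rows$Delta[i], 17, 1.2, 1.6)
  }, numeric(1))
  expect_equal(mix, manual, tolerance = 1e-12)
  # separability: oblique signal equals parallel-only times perpendicular-only
  obl <- dplyr::filter(sch, abs(ny) > 0 & abs(nz) > 0, !is_b0)
  s_obl <- restricted_signal(obl, tis)
  qo <- q_from_gradient(obl$g, obl$delta)
  perp_part <- vapply(seq_len(nrow(obl)), function(i) {
    restricted_perp_signal(qo[i], obl$Delta[i], 17, tis$D_f, 1.5)
  }, numeric(1))
  expect_equal(s_obl, perp_part, tolerance = 1e-12) # q_par = 0 for these rows
})

test_that("STEAM synthesis applies mixing-time T1 decay and pool mixing", {
  sch <- steam_scheme()
  tis <- make_tissue(T1 = 800)
  sig <- steam_signal(sch, tis, S0 = 2)
  expect_true(all(sig$signal > 0))
  expect_true(all(sig$signal <= 2 * exp(-sig$TM / 800) + 1e-12))
  # b0 at TM = T1 log(2) halves S0
  one <- sch[1, ]
  one$TM <- 800 * log(2)
  one$is_b0 <- TRUE
  one$g <- 0
  one$b <- 0
  expect_equal(steam_signal(one, tis, S0 = 1)$signal, 0.5)
  # f_r = 0 perpendicular rows: pure hindered mono-exponential in b
  tis0 <- tissue_params(
    f_r = 0,
    hindered = hindered_spec("free_tensor", D_hpar = 1.2, D_hperp = 0.5),
    distribution = axon_distribution("delta", radius = 1),
    D_rpar = 1.2, D_f = 1.2
  )
  perp <- dplyr::filter(steam_signal(sch, tis0), ny == 1, nz == 0, Delta == 48)
  lg <- log(perp$signal * exp(perp$TM / 800))
  expect_equal(lg, -(perp$b / 1000) * 0.5, tolerance = 1e-9)
  # noiseless signals monotone non-increasing in b per direction/Delta group
  sig_dw <- dplyr::filter(sig, !is_b0)
  ord <- dplyr::group_by(sig_dw, nx, ny, nz, Delta)
  chk <- dplyr::summarise(ord,
    mono = all(diff(signal[order(b)]) <= 1e-12),
    .groups = "drop"
  )
  expect_true(all(chk$mono))
})

test_that("Rician noise has the right moments and determinism", {
  x <- rep(1, 1e4)
  expect_equal(add_rician_noise(x, 1e12, 1), x, tolerance = 1e-9)
  # zero signal: Rayleigh mean sigma sqrt(pi/2)
  z <- add_rician_noise(rep(0, 1e5), 30, 1, seed = 42)
  expect_equal(mean(z), (1 / 30) * sqrt(pi / 2), tolerance = 0.01)
  expect_identical(
    add_rician_noise(x, 30, 1, seed = 7),
    add_rician_noise(x, 30, 1, seed = 7)
  )
})
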