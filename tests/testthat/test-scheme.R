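test_that("the main STEAM protocol carries the nine-diffusion-time timing", {
  sch <- steam_scheme("main")
  expect_equal(sort(unique(sch$Delta)), c(48, 60, 80, 100, 120, 140, 160, 180, 195))
  expect_equal(
    sort(unique(sch$TM)),
    c(14.4, 26.4, 46.4, 66.4, 86.4, 106.4, 126.4, 146.4, 161.4)
  )
  expect_true(all(sch$delta == 17))
  expect_equal(sort(unique(sch$b[!sch$is_b0])), c(500, 1000, 2000, 4000))
  # 5 directions x 4 b + 2 b0 per Delta
  expect_equal(nrow(sch), 9 * (5 * 4 + 2))
  # Delta - TM constant across the scheme
  expect_equal(sch$Delta - sch$TM, rep(33.6, nrow(sch)))
  # single-axis gradient demand peaks just under the 70 mT/m hardware limit
  ax_max <- max(abs(cbind(sch$nx, sch$ny, sch$nz) * sch$g))
  expect_lt(ax_max, 70)
  expect_equal(
    max(sch$g[sch$ny == 0 & sch$nz == 0 & !sch$is_b0]),
    67.6,
    tolerance = 1e-2
  )
})

test_that("the low-Delta protocol starts at 38 ms with reduced b", {
  sch <- steam_scheme("low_delta")
  expect_equal(min(sch$Delta), 38)
  expect_true(all(sch$delta == 12))
  expect_equal(sort(unique(sch$b[!sch$is_b0])), c(250, 500, 1000, 2000))
  expect_error(steam_scheme("bogus"))
})

test_that("b and g interconvert exactly under the rectangular-pulse identity", {
  expect_equal(gradient_from_b(0, 17, 48), 0)
  g <- 70
  expect_equal(gradient_from_b(b_from_gradient(g, 17, 48), 17, 48), g,
    tolerance = 1e-10
  )
  # hand-derived value for the strongest shell
  expect_equal(gradient_from_b(4000, 17, 48), 67.6, tolerance = 1e-2)
  expect_error(gradient_from_b(1000, -1, 48))
  expect_error(gradient_from_b(1000, 17, 10))
  # every generated scheme row is self-consistent to < 0.5%
  sch <- steam_scheme()
  dw <- dplyr::filter(sch, !is_b0)
  expect_true(all(abs(
    b_from_gradient(dw$g, dw$delta, dw$Delta) - dw$b
  ) / dw$b < 0.005))
})

test_that("scheme files round-trip losslessly and reject malformed input", {
  sch <- steam_scheme()
  path <- withr::local_tempfile(fileext = ".scheme")
  write_scheme(sch, path)
  back <- read_scheme(path)
  expect_equal(as.data.frame(back), as.data.frame(sch), tolerance = 1e-12)

  # b-value column variant
  write_scheme(sch, path, b_column = TRUE)
  back_b <- read_scheme(path)
  expect_equal(back_b$g, sch$g, tolerance = 1e-9)

  # zero direction on a diffusion-weighted row
  bad <- sch
  bad$nx[1] <- bad$ny[1] <- bad$nz[1] <- 0
  expect_error(write_scheme(bad, path), "non-unit")

  # mixed pulse durations named by row
  bad2 <- sch
  bad2$delta[5] <- 12
  expect_error(validate_scheme(bad2), "delta")

  # malformed rows rejected with row numbers
  writeLines(c("nx ny nz g_mTm delta_ms Delta_ms TM_ms", "1 0 0 50 17"), path)
  expect_error(read_scheme(path), "7 columns")
  writeLines(
    c("nx ny nz g_mTm delta_ms Delta_ms TM_ms", "1 0 0 oops 17 48 14.4"),
    path
  )
  expect_error(read_scheme(path), "non-numeric")
})
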