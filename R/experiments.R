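# Simulation experiments: density-bias study on analytic signals, diameter
# recovery on Monte Carlo substrates, the intra/extra signal-attenuation
# budget, BIC trend classification, difference-method SNR, and the sqrt(N)
# precision factor.

#' Substrate radii targeting a mean axonal diameter
#'
#' Gamma radii (shape `k = 3` by default) with the scale calibrated so that
#' the truncated distribution (radii floored at `r_min`) has mean radius
#' equal to half the requested mean axonal diameter.
#'
#' @param mean_diameter Target mean axonal diameter, um.
#' @param n Number of draws.
#' @param shape Gamma shape.
#' @param r_min Radius floor, um (0.25 um: the smallest histologically
#'   reported calibre, and the resolution floor of the walker step
#'   contract).
#' @param seed Optional seed.
#' @return Radii, um.
#' @export
substrate_radii <- function(mean_diameter, n, shape = 3, r_min = 0.25,
                            seed = NULL) {
  target <- mean_diameter / 2
  stopifnot(target > r_min / 2)
  trunc_mean <- function(theta) {
    theta * shape *
      stats::pgamma(r_min, shape + 1, scale = theta, lower.tail = FALSE) /
      stats::pgamma(r_min, shape, scale = theta, lower.tail = FALSE)
  }
  sc <- stats::uniroot(
    function(th) trunc_mean(th) - target,
    c(1e-3, 5),
    tol = 1e-10
  )$root
  sample_gamma_radii(shape, sc, n, r_min = r_min, seed = seed)
}

new_report <- function(kind, config, summary, extra = list()) {
  structure(
    c(list(kind = kind, config = config, summary = summary), extra),
    class = "axt_report"
  )
}

#' @export
print.axt_report <- function(x, ...) {
  cat("<axontime experiment report: ", x$kind, ">\n", sep = "")
  print(x$summary, n = 20)
  invisible(x)
}

#' Density-bias experiment on analytic signals
#'
#' Generates noisy signals from the two-pool model with the time-dependent
#' extra-axonal tensor (the generating truth), then estimates the axonal
#' density separately at each diffusion time with the free-tensor and the
#' tortuosity-constrained fits. The free-tensor fit absorbs the time
#' dependence into its per-time `D_perp` (density unbiased, no trend); the
#' tortuosity fit cannot, producing diffusion-time-dependent over- or
#' under-estimation depending on density and diameter.
#'
#' @param f_r,radii,D_0 Condition grids: densities, axonal radii (um), and
#'   the single unrestricted diffusivity (um^2/ms).
#' @param D_inf,A Generating extra-axonal parameters (um^2/ms, um^2).
#' @param T1 Relaxation time, ms.
#' @param snr Rician SNR (referenced to the largest-Delta b0); `Inf` for
#'   noiseless.
#' @param n_rep Noise repetitions per condition.
#' @param scheme Acquisition scheme.
#' @param fit_cfg A [fit_config()].
#' @param seed Master seed.
#' @return An `axt_report` with per (condition, Delta, variant) mean and sd
#'   of the density estimate plus a BIC trend call per condition and
#'   variant.
#' @export
run_density_bias_experiment <- function(f_r = c(0.3, 0.5),
                                        radii = c(0.25, 1.5),
                                        D_0 = 1,
                                        D_inf = 0.5, A = 2, T1 = 800,
                                        snr = 30, n_rep = 500,
                                        scheme = steam_scheme(),
                                        fit_cfg = fit_config(),
                                        seed = 1) {
  conds <- tidyr::expand_grid(f_r = f_r, radius = radii, D_0 = D_0)
  groups <- split(seq_len(nrow(scheme)), scheme$Delta)
  res <- withr::with_seed(seed, purrr::pmap(conds, function(f_r, radius, D_0) {
    tis <- tissue_params(
      f_r = f_r,
      hindered = hindered_spec("time_dependent",
        D_hpar = D_0, D_inf = D_inf, A = A
      ),
      distribution = axon_distribution("delta", radius = radius),
      D_rpar = D_0, D_f = D_0, T1 = T1
    )
    clean <- steam_signal(scheme, tis)
    s_ref <- clean$signal[which(clean$is_b0 &
      clean$Delta == max(clean$Delta))[1]]
    prior <- tis$distribution
    purrr::map_dfr(seq_len(n_rep), function(rep) {
      dat <- clean
      if (is.finite(snr)) {
        dat$signal <- add_rician_noise(clean$signal, snr, s_ref)
      }
      purrr::map_dfr(groups, function(idx) {
        grp <- dat[idx, ]
        purrr::map_dfr(c("free_tensor", "tortuosity"), function(v) {
          fit <- fit_density(grp, v,
            radius_prior = prior,
            config = fit_cfg
          )
          tibble::tibble(
            rep = rep, Delta = grp$Delta[1], variant = v,
            f_r_hat = unname(coef(fit)["f_r"]),
            converged = fit$converged
          )
        })
      })
    }) |>
      dplyr::mutate(f_r = f_r, radius = radius, D_0 = D_0)
  }))
  long <- dplyr::bind_rows(res)
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$f_r, .data$radius, .data$D_0, .data$variant,
      .data$Delta),
    mean_f_r = mean(.data$f_r_hat), sd_f_r = stats::sd(.data$f_r_hat),
    .groups = "drop"
  )
  trends <- dplyr::summarise(
    dplyr::group_by(summary, .data$f_r, .data$radius, .data$D_0,
      .data$variant),
    trend = bic_trend_select(.data$Delta, .data$mean_f_r)$trend,
    .groups = "drop"
  )
  new_report("density_bias",
    list(
      f_r = f_r, radii = radii, D_0 = D_0, D_inf = D_inf, A = A,
      T1 = T1, snr = snr, n_rep = n_rep, seed = seed
    ),
    summary,
    extra = list(trends = trends, estimates = long)
  )
}

#' Full-model accuracy study on analytic signals
#'
#' Generates Rician-noisy signals from the complete time-dependent two-pool
#' model over a grid of tissue configurations and refits the model to each
#' noisy repetition with per-diffusion-time b = 0 normalisation. The axon
#' radius distribution is assumed (fixed at the generating distribution, the
#' CHARMED-style histological-prior convention), leaving `f_r`, `D_par`,
#' `D_inf` and `A` free. Accuracy per parameter is
#' `100 (1 - mean |est - truth| / truth)`.
#'
#' Initial values are perturbed uniformly by up to `perturb` around the
#' generating truth (a local-accuracy protocol).
#'
#' @param f_r,radii,D_0 Configuration grids (fractions, um, um^2/ms).
#' @param D_inf,A,T1 Generating extra-axonal parameters and relaxation time.
#' @param snr Rician SNR (reference: largest-Delta b0 amplitude).
#' @param n_rep Noise repetitions per configuration.
#' @param scheme Acquisition scheme.
#' @param perturb Relative width of the start perturbation.
#' @param seed Master seed.
#' @return An `axt_report`: `summary` holds per-parameter accuracy pooled
#'   over configurations, `per_config` the per-configuration table, and
#'   `estimates` every fit.
#' @export
run_accuracy_experiment <- function(f_r = c(0.3, 0.5), radii = c(0.25, 1.5),
                                    D_0 = c(1, 2), D_inf = 0.5, A = 2,
                                    T1 = 800, snr = 30, n_rep = 500,
                                    scheme = steam_scheme(),
                                    perturb = 0.3, seed = 1) {
  conds <- tidyr::expand_grid(f_r = f_r, radius = radii, D_0 = D_0)
  cfg1 <- fit_config(multistart = 1)
  long <- withr::with_seed(seed, purrr::pmap_dfr(
    conds,
    function(f_r, radius, D_0) {
      tis <- tissue_params(
        f_r = f_r,
        hindered = hindered_spec("time_dependent",
          D_hpar = D_0,
          D_inf = D_inf, A = A
        ),
        distribution = axon_distribution("delta", radius = radius),
        D_rpar = D_0, D_f = D_0, T1 = T1
      )
      clean <- steam_signal(scheme, tis)
      s_ref <- clean$signal[which(clean$is_b0 &
        clean$Delta == max(clean$Delta))[1]]
      truth <- c(f_r = f_r, D_par = D_0, D_inf = D_inf, A = A)
      purrr::map_dfr(seq_len(n_rep), function(rep) {
        dat <- dplyr::mutate(clean,
          signal = add_rician_noise(.data$signal, snr, s_ref)
        )
        start <- truth * stats::runif(length(truth), 1 - perturb, 1 + perturb)
        fit <- fit_diameter(dat,
          time_dependent = TRUE, distribution = tis$distribution,
          normalize = "per_delta", config = cfg1, start = start
        )
        tibble::as_tibble(c(
          as.list(coef(fit)[names(truth)]),
          list(
            rep = rep, cfg_f_r = f_r, cfg_radius = radius,
            cfg_D_0 = D_0, converged = fit$converged
          )
        ))
      })
    }
  ))
  per_config <- dplyr::group_modify(
    dplyr::group_by(long, .data$cfg_f_r, .data$cfg_radius, .data$cfg_D_0),
    function(d, key) {
      truth <- c(
        f_r = key$cfg_f_r, D_par = key$cfg_D_0, D_inf = D_inf, A = A
      )
      parameter_accuracy(d, truth)
    }
  )
  per_config <- dplyr::ungroup(per_config)
  summary <- dplyr::summarise(
    dplyr::group_by(per_config, .data$parameter),
    accuracy = mean(.data$accuracy), .groups = "drop"
  )
  new_report("accuracy",
    list(
      f_r = f_r, radii = radii, D_0 = D_0, D_inf = D_inf, A = A,
      T1 = T1, snr = snr, n_rep = n_rep, perturb = perturb, seed = seed
    ),
    summary,
    extra = list(per_config = per_config, estimates = long)
  )
}

#' Diameter-recovery experiment on Monte Carlo substrates
#'
#' For each condition (mean axonal diameter x walker diffusivity x SNR),
#' packs a disordered gamma-radius substrate, runs `n_rep` random walks from
#' different starting points, synthesises STEAM signals, and fits the axonal
#' diameter with and without the extra-axonal diffusion-time dependence
#' (continuous-Poisson diameter distribution, T1 pre-fit from the b = 0
#' data).
#'
#' @param mean_diameters Substrate mean axonal diameters, um.
#' @param D_f Walker diffusivities, um^2/ms.
#' @param snr Rician SNR values.
#' @param intra_fraction Seeded restricted fraction.
#' @param n_walkers,n_rep Walkers per run and repetitions (different walker
#'   seeds on a common substrate).
#' @param box Substrate box side, um.
#' @param T1 Relaxation time, ms.
#' @param scheme Acquisition scheme.
#' @param fit_cfg A [fit_config()].
#' @param seed Master seed.
#' @return An `axt_report`; summary rows carry mean and sd of the fitted
#'   mean diameter and of (`D_par`, `D_inf`, `f_r`, `A`) per condition and
#'   variant, plus the per-repetition estimates.
#' @export
run_mc_recovery_experiment <- function(mean_diameters = c(1.26, 1.32, 1.52, 1.94),
                                       D_f = c(0.7, 1.5, 2.4),
                                       snr = c(25, 40, 55),
                                       intra_fraction = 0.6,
                                       n_walkers = 1e4, n_rep = 5,
                                       box = 40, T1 = 800,
                                       scheme = steam_scheme(),
                                       fit_cfg = fit_config(),
                                       seed = 1) {
  delta <- scheme$delta[1]
  duration <- max(scheme$Delta) + delta
  conds <- tidyr::expand_grid(mean_diameter = mean_diameters, D_f = D_f)
  long <- purrr::pmap_dfr(conds, function(mean_diameter, D_f) {
    sub_seed <- seed + round(1000 * mean_diameter)
    radii <- substrate_radii(mean_diameter, 5000, seed = sub_seed)
    sub <- pack_cylinders(radii, 0.6, box, seed = sub_seed + 1)
    cfg <- mc_config(
      n_walkers = n_walkers, duration = duration, D_f = D_f,
      intra_fraction = intra_fraction
    )
    purrr::map_dfr(seq_len(n_rep), function(rep) {
      wseed <- sub_seed + 10 * rep
      clean <- mc_signal(sub, scheme, cfg, T1 = T1, seed = wseed)
      s_ref <- clean$signal[which(clean$is_b0 &
        clean$Delta == max(clean$Delta))[1]]
      purrr::map_dfr(snr, function(sn) {
        dat <- clean
        dat$signal <- add_rician_noise(clean$signal, sn, s_ref,
          seed = wseed + 1
        )
        purrr::map_dfr(c(TRUE, FALSE), function(td) {
          fit <- fit_diameter(dat,
            time_dependent = td, family = "poisson",
            config = fit_cfg
          )
          est <- coef(fit)
          tibble::tibble(
            mean_diameter = mean_diameter, D_f = D_f, snr = sn,
            rep = rep, time_dependent = td,
            diameter_hat = unname(est["mean_diameter"]),
            f_r_hat = unname(est["f_r"]),
            D_par_hat = unname(est["D_par"]),
            D_inf_hat = unname(est["D_inf"] %||% NA_real_),
            A_hat = unname(est["A"] %||% NA_real_),
            D_perp_hat = unname(est["D_perp"] %||% NA_real_),
            achieved_icvf = sub$achieved_icvf,
            converged = fit$converged
          )
        })
      })
    })
  })
  summary <- dplyr::summarise(
    dplyr::group_by(long, .data$mean_diameter, .data$D_f, .data$snr,
      .data$time_dependent),
    dplyr::across(
      dplyr::ends_with("_hat"),
      list(mean = ~ mean(.x), sd = ~ stats::sd(.x))
    ),
    .groups = "drop"
  )
  new_report("mc_recovery",
    list(
      mean_diameters = mean_diameters, D_f = D_f, snr = snr,
      intra_fraction = intra_fraction, n_walkers = n_walkers,
      n_rep = n_rep, box = box, T1 = T1, seed = seed
    ),
    summary,
    extra = list(estimates = long)
  )
}

#' Intra/extra signal-attenuation budget
#'
#' Deterministic decomposition of the diffusion attenuation of the
#' normalised two-pool signal at a single diffusion time, perpendicular to
#' the fiber: the intra-axonal share is `100 f_r (1 - S_r,perp(b))` with the
#' restricted signal area-weighted over the diameter distribution; the
#' extra-axonal share is `100 (1 - f_r)(1 - S_h,perp(b))` with the hindered
#' perpendicular diffusivity at its tortuosity baseline `D_f (1 - f_r)`.
#'
#' @param b b-values, s/mm^2.
#' @param Delta,delta Timing, ms.
#' @param f_r Restricted signal fraction.
#' @param distributions Named list of [axon_distribution()] objects; the
#'   defaults are the smallest and largest substrate distributions (gamma,
#'   shape 3, mean axonal diameters 1.26 and 1.94 um).
#' @param D_f Intrinsic diffusivities, um^2/ms.
#' @return A tibble with `distribution`, `D_f`, `b`, `intra_pct`,
#'   `extra_pct`.
#' @examples
#' run_attenuation_budget(b = 4000)
#' @export
run_attenuation_budget <- function(b = c(500, 1000, 2000, 4000),
                                   Delta = 48, delta = 17, f_r = 0.6,
                                   distributions = list(
                                     smallest = axon_distribution("gamma",
                                       shape = 3, scale = 1.26 / 6
                                     ),
                                     largest = axon_distribution("gamma",
                                       shape = 3, scale = 1.94 / 6
                                     )
                                   ),
                                   D_f = c(0.7, 1.5, 2.4)) {
  grid <- tidyr::expand_grid(
    distribution = names(distributions), D_f = D_f, b = b
  )
  purrr::pmap_dfr(grid, function(distribution, D_f, b) {
    dist <- distributions[[distribution]]
    q <- q_from_gradient(gradient_from_b(b, delta, Delta), delta)
    w <- area_weights(dist)
    C <- .vg_sum(Delta, delta, D_f, dist$radius_grid)
    s_r <- sum(w * exp(-8 * pi^2 * q^2 * C[1, ]))
    d_perp <- D_f * (1 - f_r)
    s_h <- exp(-4 * pi^2 * q^2 * (Delta - delta / 3) * d_perp)
    tibble::tibble(
      distribution = distribution, D_f = D_f, b = b,
      intra_pct = 100 * f_r * (1 - s_r),
      extra_pct = 100 * (1 - f_r) * (1 - s_h)
    )
  })
}

#' Classify a parameter-versus-diffusion-time trend by BIC
#'
#' Least-squares fits of a constant, linear and quadratic model with
#' `BIC = n log(RSS/n) + k log(n)` (`k` counting the intercept); the
#' minimum-BIC model labels the trend, with the sign of the net change over
#' the observed range (floored at machine noise) giving the direction.
#'
#' @param x Diffusion times (or any ordinate), length >= 4.
#' @param y Values.
#' @param slope_floor Net changes below this are treated as flat.
#' @return A list with `trend` (`"constant"`, `"increasing"`,
#'   `"decreasing"`), `model`, and the `bic` table.
#' @examples
#' bic_trend_select(1:9, rep(0.5, 9))$trend
#' @export
bic_trend_select <- function(x, y, slope_floor = 1e-10) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  n <- length(y)
  if (max(y) - min(y) < slope_floor) {
    return(list(
      trend = "constant", model = "constant",
      bic = tibble::tibble(
        model = "constant", k = 1, rss = 0, bic = -Inf
      )
    ))
  }
  fits <- list(
    constant = stats::lm(y ~ 1),
    linear = stats::lm(y ~ x),
    quadratic = stats::lm(y ~ x + I(x^2))
  )
  bic <- purrr::imap_dfr(fits, function(f, nm) {
    rss <- sum(stats::residuals(f)^2)
    k <- length(stats::coef(f))
    tibble::tibble(model = nm, k = k, rss = rss,
      bic = n * log(rss / n) + k * log(n))
  })
  best <- bic$model[which.min(bic$bic)]
  trend <- "constant"
  if (best != "constant") {
    fv <- stats::fitted(fits[[best]])[order(x)]
    net <- fv[n] - fv[1]
    trend <- if (abs(net) < slope_floor) {
      "constant"
    } else if (net > 0) "increasing" else "decreasing"
  }
  list(trend = trend, model = best, bic = bic)
}

#' SNR by the difference method
#'
#' Two repeated acquisitions of the same object: the signal is the mean of
#' the average image and the noise standard deviation is `sd(A - B) /
#' sqrt(2)` (subtraction cancels the object, leaving doubled noise
#' variance).
#'
#' @param a,b Numeric vectors/arrays of identical shape (foreground voxels).
#' @return SNR estimate.
#' @export
snr_difference <- function(a, b) {
  stopifnot(length(a) == length(b))
  s <- stats::sd(as.numeric(a) - as.numeric(b))
  if (s == 0) stop("zero difference variance: images are identical", call. = FALSE)
  mean((as.numeric(a) + as.numeric(b)) / 2) / (s / sqrt(2))
}

#' Precision gain from measurement count
#'
#' The Cramer-Rao bound on an estimator variance improves linearly with the
#' number of measurements N, so the standard deviation improves by
#' `sqrt(N)`.
#'
#' @param n Number of measurements.
#' @return `sqrt(n)`.
#' @examples
#' precision_gain(216)
#' @export
precision_gain <- function(n) {
  stopifnot(all(n >= 1))
  sqrt(n)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a
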