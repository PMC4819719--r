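# Bounded nonlinear least-squares fits of the two-pool model: T1 pre-fit,
# per-diffusion-time density fits (free tensor vs tortuosity) and
# all-diffusion-time diameter fits (with vs without extra-axonal time
# dependence). Levenberg-Marquardt with box bounds via minpack.lm, with
# multistart from perturbed initial values.

#' Fit configuration
#'
#' @param multistart Number of starts; the first uses `start` as given, the
#'   rest perturb it multiplicatively by up to `perturb` (uniform), clipped
#'   to the bounds. Perturbations draw from the current RNG stream, so fits
#'   are reproducible under a fixed seed.
#' @param perturb Relative perturbation of the multistart initial values.
#' @param maxiter Levenberg-Marquardt iteration cap.
#' @param ftol Relative reduction tolerance.
#' @return A list of class `axt_fit_config`.
#' @export
fit_config <- function(multistart = 5, perturb = 0.3, maxiter = 200,
                       ftol = 1e-10) {
  structure(
    list(
      multistart = multistart, perturb = perturb,
      maxiter = maxiter, ftol = ftol
    ),
    class = "axt_fit_config"
  )
}

# default parameter box and starts (um^2/ms, um, um^2)
.par_box <- function(names) {
  lower <- c(
    f_r = 0, D_par = 0, D_perp = 0, D_inf = 0, A = 0, R = 0.05,
    lambda = 0.05, T1 = 1, S0 = 0
  )
  upper <- c(
    f_r = 1, D_par = 3.5, D_perp = 3.5, D_inf = 3.5, A = 20, R = 5,
    lambda = 5, T1 = 5000, S0 = Inf
  )
  start <- c(
    f_r = 0.5, D_par = 1.5, D_perp = 0.5, D_inf = 0.3, A = 0.5, R = 1,
    lambda = 1, T1 = 800, S0 = 1
  )
  list(lower = lower[names], upper = upper[names], start = start[names])
}

.fit_lm <- function(resid_fn, start, lower, upper, config,
                    extra_starts = list()) {
  stopifnot(all(lower <= start), all(start <= upper))
  starts <- list(start)
  if (config$multistart > 1) {
    for (k in seq_len(config$multistart - 1)) {
      p <- start * stats::runif(length(start), 1 - config$perturb,
        1 + config$perturb
      )
      starts[[k + 1]] <- pmin(pmax(p, lower), upper)
    }
  }
  for (p in extra_starts) starts <- c(starts, list(pmin(pmax(p, lower), upper)))
  best <- NULL
  for (p0 in starts) {
    fit <- try(
      minpack.lm::nls.lm(
        par = p0, lower = lower, upper = upper, fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = config$maxiter, ftol = config$ftol, ptol = 1e-12
        )
      ),
      silent = TRUE
    )
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    stop("all least-squares starts failed", call. = FALSE)
  }
  est <- best$par
  n <- length(resid_fn(est))
  p <- length(est)
  se <- rep(NA_real_, p)
  if (n > p) {
    s2 <- best$deviance / (n - p)
    cov <- try(solve(best$hessian) * s2, silent = TRUE)
    if (!inherits(cov, "try-error")) {
      d <- diag(cov)
      se[d >= 0] <- sqrt(d[d >= 0])
    }
  }
  names(se) <- names(est)
  converged <- best$info %in% 1:4
  list(
    estimates = est, se = se, residual_norm = sqrt(best$deviance),
    n_iter = best$niter, converged = converged, n_obs = n
  )
}

new_fit <- function(lm_out, variant, extra = list()) {
  structure(
    c(lm_out, list(variant = variant), extra),
    class = "axt_fit"
  )
}

#' Fit T1 from b = 0 signals across mixing times
#'
#' Least-squares fit of `S = S0 exp(-TM/T1)` to the unweighted measurements
#' of a STEAM acquisition; the estimate is typically fixed in the subsequent
#' diameter fit. Needs at least two distinct mixing times. A fit pinned at
#' the T1 upper bound (non-decaying data) is flagged as not converged.
#'
#' @param data A tibble with columns `TM` and `signal`; rows with an
#'   `is_b0` column present are filtered to the b = 0 subset.
#' @param config A [fit_config()].
#' @return An `axt_fit` with estimates `S0` and `T1` (ms).
#' @examples
#' d <- tibble::tibble(TM = seq(10, 170, 20), signal = 2 * exp(-TM / 800))
#' coef(fit_t1(d))
#' @export
fit_t1 <- function(data, config = fit_config()) {
  if ("is_b0" %in% names(data)) data <- dplyr::filter(data, .data$is_b0)
  tm <- data$TM
  s <- data$signal
  if (length(unique(tm)) < 2) {
    stop("need b = 0 signals at >= 2 distinct mixing times", call. = FALSE)
  }
  if (any(s <= 0)) stop("nonpositive b = 0 signals", call. = FALSE)
  # log-linear initial values
  cf <- stats::coef(stats::lm(log(s) ~ tm))
  t1_0 <- if (cf[2] < 0) min(max(-1 / cf[2], 50), 4000) else 2000
  box <- .par_box(c("S0", "T1"))
  start <- c(S0 = unname(exp(cf[1])), T1 = t1_0)
  out <- .fit_lm(
    function(p) s - p["S0"] * exp(-tm / p["T1"]),
    start, box$lower, box$upper, config
  )
  if (out$estimates["T1"] >= box$upper["T1"] - 1e-6) {
    out$converged <- FALSE
    warning("T1 pinned at the upper bound (non-decaying b0 data)",
      call. = FALSE
    )
  }
  new_fit(out, "t1")
}

# forward model used inside the fits; geom from .scheme_geom, dist a
# distribution or NULL (then p carries R or lambda)
.fit_model_signal <- function(p, geom, variant, time_dependent, dist,
                              decay) {
  D <- unname(p["D_par"])
  f_r <- unname(p["f_r"])
  dperp <- if (variant == "tortuosity") {
    D * (1 - f_r)
  } else if (time_dependent) {
    unname(p["D_inf"]) + unname(p["A"]) *
      (log(geom$Delta / geom$delta) + 1.5) / (geom$Delta - geom$delta / 3)
  } else {
    unname(p["D_perp"])
  }
  s_h <- exp(-4 * pi^2 * (geom$Delta - geom$delta / 3) *
    (geom$q_par2 * D + geom$q_perp2 * dperp))
  if (is.null(dist)) {
    dist <- if ("R" %in% names(p)) {
      axon_distribution("delta", radius = unname(p["R"]))
    } else {
      axon_distribution("poisson", rate = unname(p["lambda"]))
    }
  }
  # deep truncation: the optimizer explores low-diffusivity corners where
  # the series decays slowly
  s_r <- .restricted_signal_geom(geom, dist, D_rpar = D, D_f = D, m_max = 50)
  sig <- decay * ((1 - f_r) * s_h + f_r * s_r)
  sig[geom$is_b0] <- decay[geom$is_b0]
  sig
}

#' Per-diffusion-time axonal density fit
#'
#' Fits the two-pool model to the measurements of a single diffusion time,
#' normalised to that group's b = 0 mean (which removes S0 and the
#' mixing-time T1 decay). The restricted compartment uses a fixed, assumed
#' diameter distribution (CHARMED-style histological prior); a single
#' diffusivity parameter `D_par` describes all unrestricted diffusivities.
#' Free parameters: `f_r`, `D_par`, and — for the `free_tensor` variant —
#' `D_perp`; the `tortuosity` variant derives
#' `D_perp = D_par (1 - f_r)`.
#'
#' @param data Scheme tibble with a `signal` column, single `Delta` group.
#' @param variant `"free_tensor"` or `"tortuosity"`.
#' @param fiber_dir Known fiber direction (never fitted).
#' @param radius_prior Fixed [axon_distribution()] of the restricted pool.
#' @param config A [fit_config()].
#' @param start Optional named starting values overriding the defaults.
#' @return An `axt_fit`.
#' @export
fit_density <- function(data, variant = c("free_tensor", "tortuosity"),
                        fiber_dir = c(1, 0, 0),
                        radius_prior = axon_distribution("delta", radius = 1),
                        config = fit_config(), start = NULL) {
  variant <- match.arg(variant)
  stopifnot("signal" %in% names(data))
  if (length(unique(data$Delta)) != 1) {
    stop("fit_density works on a single Delta group", call. = FALSE)
  }
  s0 <- mean(data$signal[data$is_b0])
  if (!is.finite(s0) || s0 <= 0) {
    stop("no usable b = 0 signal in the group", call. = FALSE)
  }
  dw <- data[!data$is_b0, ]
  y <- dw$signal / s0
  geom <- .scheme_geom(dw, fiber_dir)
  par_names <- if (variant == "free_tensor") {
    c("f_r", "D_par", "D_perp")
  } else {
    c("f_r", "D_par")
  }
  box <- .par_box(par_names)
  p0 <- box$start
  if (!is.null(start)) p0[names(start)] <- pmin(pmax(start, box$lower[names(start)]), box$upper[names(start)])
  decay <- rep(1, nrow(dw))
  out <- .fit_lm(
    function(p) {
      y - .fit_model_signal(p, geom, variant,
        time_dependent = FALSE,
        dist = radius_prior, decay = decay
      )
    },
    p0, box$lower, box$upper, config
  )
  new_fit(out, paste0("density_", variant),
    extra = list(Delta = data$Delta[1])
  )
}

#' All-diffusion-time axonal diameter fit
#'
#' Fits the two-pool model jointly over all diffusion times. The diameter
#' distribution is a continuous Poisson over radius (single parameter
#' `lambda` controlling mean and width) or a single radius (`delta` family).
#' With `time_dependent = TRUE` the extra-axonal perpendicular diffusivity
#' follows `D_inf + A (log(Delta/delta) + 3/2) / (Delta - delta/3)`; with
#' `FALSE` it is the constant `D_perp` of the earlier diameter-mapping
#' frameworks. A single diffusivity `D_par` describes all unrestricted
#' diffusivities; the fiber direction is supplied, never fitted.
#'
#' Normalisation: `normalize = "none"` models raw amplitudes with `S0` and
#' `T1` fixed from a b = 0 pre-fit ([fit_t1()]) unless supplied;
#' `"per_delta"` divides each diffusion-time group by its b = 0 mean, which
#' removes T1/S0 from the problem entirely.
#'
#' The reported mean axonal diameter is twice the count-weighted mean radius
#' of the fitted distribution.
#'
#' @param data Scheme tibble with a `signal` column (>= 3 Delta groups).
#' @param time_dependent Include the extra-axonal diffusion-time dependence.
#' @param family `"poisson"` or `"delta"` diameter distribution.
#' @param distribution Optional fixed [axon_distribution()]; when supplied
#'   the distribution is not fitted (no size parameter) and the free
#'   parameters reduce to `f_r`, `D_par` and the extra-axonal terms — the
#'   assumed-distribution protocol used when the acquisition carries little
#'   diameter information.
#' @param fiber_dir Known fiber direction.
#' @param normalize `"none"` or `"per_delta"`.
#' @param T1_fixed,S0_fixed Optional pre-fit values (ms, amplitude).
#' @param config A [fit_config()].
#' @param start Optional named starting values overriding the defaults.
#' @return An `axt_fit`; estimates include `mean_diameter` (um, derived) and
#'   a `lambda_pinned` flag marks a boundary-pinned distribution parameter.
#' @export
fit_diameter <- function(data, time_dependent = TRUE,
                         family = c("poisson", "delta"),
                         distribution = NULL,
                         fiber_dir = c(1, 0, 0),
                         normalize = c("none", "per_delta"),
                         T1_fixed = NULL, S0_fixed = NULL,
                         config = fit_config(), start = NULL) {
  family <- match.arg(family)
  normalize <- match.arg(normalize)
  stopifnot("signal" %in% names(data))
  if (length(unique(data$Delta)) < 3) {
    stop("diameter fit needs >= 3 Delta groups", call. = FALSE)
  }
  if (normalize == "per_delta") {
    data <- dplyr::mutate(
      dplyr::group_by(data, .data$Delta),
      signal = .data$signal / mean(.data$signal[.data$is_b0])
    )
    data <- dplyr::ungroup(data)
    dw <- data[!data$is_b0, ]
    decay <- rep(1, nrow(dw))
  } else {
    if (is.null(T1_fixed) || is.null(S0_fixed)) {
      pre <- fit_t1(data, config = config)
      if (is.null(T1_fixed)) T1_fixed <- unname(stats::coef(pre)["T1"])
      if (is.null(S0_fixed)) S0_fixed <- unname(stats::coef(pre)["S0"])
    }
    dw <- data[!data$is_b0, ]
    decay <- S0_fixed * exp(-dw$TM / T1_fixed)
  }
  y <- dw$signal
  geom <- .scheme_geom(dw, fiber_dir)
  size_par <- if (family == "poisson") "lambda" else "R"
  par_names <- c(
    "f_r", "D_par", if (is.null(distribution)) size_par,
    if (time_dependent) c("D_inf", "A") else "D_perp"
  )
  box <- .par_box(par_names)
  p0 <- box$start
  if (!is.null(start)) p0[names(start)] <- pmin(pmax(start, box$lower[names(start)]), box$upper[names(start)])
  # the size parameter is the non-convex direction of this problem; a
  # deterministic coarse grid of starts over it makes the multistart
  # reliable where perturbed starts alone are not
  extra <- list()
  if (is.null(distribution)) {
    perp_par <- if (time_dependent) "D_inf" else "D_perp"
    for (sz in c(0.3, 0.75, 1.5, 2.5, 4)) {
      for (dp in c(0.2, 0.7)) {
        p_sz <- p0
        p_sz[size_par] <- sz
        p_sz[perp_par] <- dp
        extra <- c(extra, list(p_sz))
      }
    }
  }
  out <- .fit_lm(
    function(p) {
      y - .fit_model_signal(p, geom, "free", time_dependent,
        dist = distribution, decay = decay
      )
    },
    p0, box$lower, box$upper, config,
    extra_starts = extra
  )
  est <- out$estimates
  if (is.null(distribution)) {
    dist <- if (family == "poisson") {
      axon_distribution("poisson", rate = unname(est["lambda"]))
    } else {
      axon_distribution("delta", radius = unname(est["R"]))
    }
    pinned <- est[size_par] <= box$lower[size_par] + 1e-8 ||
      est[size_par] >= box$upper[size_par] - 1e-8
    out$estimates <- c(est, mean_diameter = 2 * mean_radius(dist))
  } else {
    pinned <- FALSE
  }
  new_fit(out,
    paste0(
      "diameter_",
      if (time_dependent) "time_dependent" else "time_independent"
    ),
    extra = list(
      family = family, lambda_pinned = pinned,
      T1_fixed = T1_fixed, S0_fixed = S0_fixed
    )
  )
}

#' Percent accuracy of parameter estimates
#'
#' `accuracy = 100 (1 - mean(|est - truth| / |truth|))` per parameter, the
#' mean taken over estimate rows (noise draws, configurations). Can be
#' negative when the mean relative error exceeds one.
#'
#' @param estimates A data frame of estimates, one column per parameter.
#' @param truth Named numeric vector of true values (all nonzero).
#' @return A tibble with `parameter` and `accuracy` (%).
#' @examples
#' parameter_accuracy(data.frame(f_r = c(0.48, 0.52)), c(f_r = 0.5))
#' @export
parameter_accuracy <- function(estimates, truth) {
  pars <- intersect(names(truth), names(estimates))
  if (!length(pars)) stop("no matching parameters", call. = FALSE)
  if (any(truth[pars] == 0)) {
    stop("accuracy undefined for zero truth", call. = FALSE)
  }
  acc <- vapply(pars, function(p) {
    100 * (1 - mean(abs(estimates[[p]] - truth[[p]]) / abs(truth[[p]])))
  }, numeric(1))
  tibble::tibble(parameter = pars, accuracy = unname(acc))
}

#' @export
coef.axt_fit <- function(object, ...) object$estimates

#' @export
print.axt_fit <- function(x, ...) {
  cat("<axontime fit: ", x$variant, ">\n", sep = "")
  print(round(x$estimates, 5))
  cat(
    "residual norm ", format(x$residual_norm, digits = 5),
    if (x$converged) ", converged" else ", NOT converged",
    " (", x$n_iter, " iterations)\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a fitted model
#'
#' @param x An `axt_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`.
#' @method tidy axt_fit
#' @export
tidy.axt_fit <- function(x, ...) {
  terms <- names(x$estimates)
  tibble::tibble(
    term = terms,
    estimate = unname(x$estimates),
    std.error = unname(x$se[terms])
  )
}

#' One-row fit summary
#'
#' @param x An `axt_fit`.
#' @param ... Unused.
#' @return A tibble with the variant, residual norm, iteration count,
#'   convergence flag and number of observations.
#' @method glance axt_fit
#' @export
glance.axt_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    residual.norm = x$residual_norm,
    n.iter = x$n_iter,
    converged = x$converged,
    nobs = x$n_obs
  )
}
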