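#' Monte Carlo walker configuration
#'
#' Walkers perform an equal-step random-direction walk in the transverse
#' plane (step length `sqrt(4 D_f dt)`) with specular reflection off
#' impermeable cylinder walls, plus an independent free 1D walk along the
#' cylinder axis. A fraction `intra_fraction` of walkers is seeded uniformly
#' inside cylinders (choosing cylinders in proportion to their
#' cross-section) and the rest uniformly in the extra-cylinder space; the
#' seeding proportion, not the substrate area fraction, sets the restricted
#' signal fraction.
#'
#' When `n_steps` is `NULL` it is chosen as the smallest count (at least
#' `min_steps`) for which the transverse step length does not exceed half
#' the smallest cylinder radius, the resolution below which specular
#' reflection is unbiased.
#'
#' @param n_walkers Number of walkers.
#' @param duration Walk duration, ms (must cover `max(Delta) + delta` of the
#'   scheme to be simulated).
#' @param D_f Walker diffusivity (same in both compartments), um^2/ms.
#' @param n_steps Number of time steps, or `NULL` to auto-resolve.
#' @param intra_fraction Fraction of walkers seeded intra-cylinder.
#' @param min_steps Floor for the auto-chosen step count.
#' @return A list of class `axt_mc_config`.
#' @export
mc_config <- function(n_walkers = 1e4, duration = 212, D_f = 1.5,
                      n_steps = NULL, intra_fraction = 0.6,
                      min_steps = 2000) {
  stopifnot(
    n_walkers >= 1, duration > 0, D_f > 0,
    intra_fraction >= 0, intra_fraction <= 1
  )
  structure(
    list(
      n_walkers = as.integer(n_walkers), duration = duration, D_f = D_f,
      n_steps = n_steps, intra_fraction = intra_fraction,
      min_steps = min_steps
    ),
    class = "axt_mc_config"
  )
}

.resolve_steps <- function(config, substrate) {
  if (!is.null(config$n_steps)) {
    n <- as.integer(config$n_steps)
    dt <- config$duration / n
    ell <- sqrt(4 * config$D_f * dt)
    rmin <- min(substrate$cylinders$r)
    if (ell > rmin / 2) {
      stop(
        "step length ", signif(ell, 3), " um exceeds half the smallest ",
        "cylinder radius (", signif(rmin, 3),
        " um): discretization too coarse; increase n_steps",
        call. = FALSE
      )
    }
    return(n)
  }
  rmin <- min(substrate$cylinders$r)
  dt_max <- (rmin / 2)^2 / (4 * config$D_f)
  max(config$min_steps, as.integer(ceiling(config$duration / dt_max)))
}

.seed_walkers <- function(substrate, n_walkers, intra_fraction) {
  cyl <- substrate$cylinders
  L <- substrate$box
  n_in <- round(intra_fraction * n_walkers)
  n_out <- n_walkers - n_in
  mem <- integer(0)
  y <- z <- numeric(0)
  if (n_in > 0) {
    idx <- sample.int(nrow(cyl), n_in, replace = TRUE, prob = cyl$r^2)
    u <- sqrt(stats::runif(n_in))
    th <- stats::runif(n_in, 0, 2 * pi)
    y <- cyl$y[idx] + u * cyl$r[idx] * cos(th)
    z <- cyl$z[idx] + u * cyl$r[idx] * sin(th)
    mem <- idx - 1L
  }
  if (n_out > 0) {
    got <- 0
    oy <- oz <- numeric(n_out)
    while (got < n_out) {
      m <- (n_out - got) * 2 + 16
      ty <- stats::runif(m, 0, L)
      tz <- stats::runif(m, 0, L)
      inside <- rep(FALSE, m)
      for (i in seq_len(nrow(cyl))) {
        dy <- ty - cyl$y[i]
        dy <- dy - L * round(dy / L)
        dz <- tz - cyl$z[i]
        dz <- dz - L * round(dz / L)
        inside <- inside | (dy^2 + dz^2 < cyl$r[i]^2)
      }
      ok <- which(!inside)
      take <- utils::head(ok, n_out - got)
      oy[got + seq_along(take)] <- ty[take]
      oz[got + seq_along(take)] <- tz[take]
      got <- got + length(take)
    }
    y <- c(y, oy)
    z <- c(z, oz)
    mem <- c(mem, rep(-1L, n_out))
  }
  list(y = y, z = z, membership = mem)
}

#' Run a random walk in a cylinder substrate
#'
#' @param substrate An `axt_substrate` from [pack_cylinders()].
#' @param config An [mc_config()].
#' @param checkpoint_times Sorted times (ms) at which running position
#'   integrals are recorded for later diffusion-encoding phase computation
#'   (supplied by [mc_signal()]; may be empty).
#' @param seed Optional integer seed.
#' @return A list of class `axt_walk`: seeded and final unwrapped positions,
#'   compartment membership before and after (impermeability audit),
#'   checkpointed position integrals, and the step geometry (`dt`, step
#'   length).
#' @export
random_walk <- function(substrate, config, checkpoint_times = numeric(0),
                        seed = NULL) {
  stopifnot(
    inherits(substrate, "axt_substrate"),
    inherits(config, "axt_mc_config")
  )
  n_steps <- .resolve_steps(config, substrate)
  dt <- config$duration / n_steps
  if (length(checkpoint_times) > 0) {
    stopifnot(
      !is.unsorted(checkpoint_times),
      max(checkpoint_times) <= config$duration + 1e-9
    )
  }
  run <- function() {
    st <- .seed_walkers(substrate, config$n_walkers, config$intra_fraction)
    res <- .cpp_random_walk(
      substrate$cylinders$y, substrate$cylinders$z, substrate$cylinders$r,
      substrate$box, st$membership, st$y, st$z,
      n_steps, dt, config$D_f, as.numeric(checkpoint_times)
    )
    structure(
      list(
        y0 = st$y, z0 = st$z, x0 = rep(0, config$n_walkers),
        y = res$y, z = res$z, x = res$x,
        membership = st$membership, membership_end = res$membership_end,
        int_y = res$int_y, int_z = res$int_z, int_x = res$int_x,
        checkpoint_times = as.numeric(checkpoint_times),
        dt = dt, n_steps = n_steps,
        step_length = sqrt(4 * config$D_f * dt),
        duration = config$duration, D_f = config$D_f
      ),
      class = "axt_walk"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Synthesise diffusion-weighted signals from a random walk
#'
#' Phase accumulation under rectangular gradient lobes (+g over `[0, delta]`,
#' -g over `[Delta, Delta + delta]`, the effective pulsed-gradient reading of
#' the STEAM encoding): `phi_w = gamma g n . (I(delta) - I(Delta + delta) +
#' I(Delta))` where `I(t)` is the walker's running position integral. The
#' per-measurement signal is `|mean(exp(i phi))|`, scaled analytically by the
#' mixing-time T1 decay `exp(-TM/T1)`; b = 0 rows carry the T1 decay alone.
#'
#' @param substrate An `axt_substrate`.
#' @param scheme A scheme tibble; requires
#'   `duration >= max(Delta) + delta`.
#' @param config An [mc_config()].
#' @param T1 Longitudinal relaxation time, ms.
#' @param S0 Amplitude at b = 0, TM = 0.
#' @param snr Optional Rician SNR; noise is referenced to the b = 0
#'   amplitude of the largest-Delta group.
#' @param seed Optional integer seed (walk and noise).
#' @param walk Optionally reuse an existing [random_walk()] result (its
#'   checkpoints must have been generated for this scheme).
#' @return The scheme tibble with a `signal` column.
#' @export
mc_signal <- function(substrate, scheme, config, T1 = 800, S0 = 1,
                      snr = NULL, seed = NULL, walk = NULL) {
  validate_scheme(scheme)
  delta <- scheme$delta[1]
  uDelta <- sort(unique(scheme$Delta))
  if (max(uDelta) + delta > config$duration + 1e-9) {
    stop("scheme timing exceeds walk duration (need >= max(Delta) + delta)",
      call. = FALSE
    )
  }
  ck <- sort(unique(c(delta, uDelta, uDelta + delta)))
  if (is.null(walk)) {
    walk <- random_walk(substrate, config, checkpoint_times = ck, seed = seed)
  } else if (!isTRUE(all.equal(walk$checkpoint_times, ck))) {
    stop("supplied walk was not checkpointed for this scheme", call. = FALSE)
  }
  i_d <- match(delta, ck)
  sig <- numeric(nrow(scheme))
  decay <- exp(-scheme$TM / T1) * S0
  for (i in seq_len(nrow(scheme))) {
    if (scheme$is_b0[i]) {
      sig[i] <- decay[i]
      next
    }
    i1 <- match(scheme$Delta[i], ck)
    i2 <- match(scheme$Delta[i] + delta, ck)
    # n . (I(delta) - I(Delta+delta) + I(Delta)) per walker
    proj <- scheme$nx[i] * (walk$int_x[, i_d] - walk$int_x[, i2] +
      walk$int_x[, i1]) +
      scheme$ny[i] * (walk$int_y[, i_d] - walk$int_y[, i2] +
        walk$int_y[, i1]) +
      scheme$nz[i] * (walk$int_z[, i_d] - walk$int_z[, i2] +
        walk$int_z[, i1])
    phi <- .gamma_ms * (scheme$g[i] * 1e-9) * proj
    sig[i] <- decay[i] * Mod(mean(exp(1i * phi)))
  }
  out <- dplyr::mutate(scheme, signal = sig)
  if (!is.null(snr)) {
    i_ref <- which(scheme$is_b0 & scheme$Delta == max(scheme$Delta))[1]
    out$signal <- add_rician_noise(out$signal, snr,
      s_ref = decay[i_ref],
      seed = if (is.null(seed)) NULL else seed + 1L
    )
  }
  out
}

#' Apparent perpendicular diffusivity per diffusion time
#'
#' Low-b mono-exponential readout of the diffusion coefficient orthogonal to
#' the fiber axis: for each diffusion time, the least-squares slope of
#' `-log(S / S0)` against b (through the origin) over measurements with
#' `b <= b_max` along the two perpendicular axes `[0 1 0]` and `[0 0 1]`,
#' averaged over the two directions. `S0` is the mean b = 0 signal of the
#' group.
#'
#' @param signals A scheme tibble with a `signal` column.
#' @param b_max Largest b-value used, s/mm^2.
#' @return A tibble with `Delta` and `adc` (um^2/ms).
#' @export
apparent_dperp <- function(signals, b_max = 1000) {
  stopifnot("signal" %in% names(signals))
  perp <- dplyr::filter(
    signals,
    (abs(.data$ny) == 1 | abs(.data$nz) == 1) & .data$nx == 0,
    !.data$is_b0, .data$b <= b_max
  )
  if (nrow(perp) == 0) stop("no perpendicular low-b measurements", call. = FALSE)
  b0 <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(signals, .data$is_b0), .data$Delta),
    s0 = mean(.data$signal), .groups = "drop"
  )
  perp <- dplyr::left_join(perp, b0, by = "Delta")
  if (any(perp$signal <= 0)) stop("nonpositive signals", call. = FALSE)
  fit_one <- function(d) {
    # slope through origin of -log(S/S0) on b, per direction, then average
    per_dir <- dplyr::group_by(d, dir = paste(.data$ny, .data$nz))
    sl <- dplyr::summarise(per_dir,
      slope = {
        yy <- -log(.data$signal / .data$s0)
        bb <- .data$b / 1000 # internal units -> um^2/ms
        sum(bb * yy) / sum(bb^2)
      },
      .groups = "drop"
    )
    mean(sl$slope)
  }
  dplyr::summarise(
    dplyr::group_by(perp, .data$Delta),
    adc = fit_one(dplyr::pick(dplyr::everything())),
    .groups = "drop"
  )
}
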