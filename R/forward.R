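# Forward signal model: restricted (intra-axonal) cylinder signal via Van
# Gelderen's series, hindered (extra-axonal) Gaussian tensor in three
# variants, STEAM T1 decay over the mixing time, and Rician noise.

.axt_cache <- new.env(parent = emptyenv())

# Universal positive roots x_m of J1'(x) = 0; alpha_m = x_m / R.
.scaled_bessel_roots <- function(m_max) {
  cached <- .axt_cache$j1p_roots
  if (!is.null(cached) && length(cached) >= m_max) {
    return(cached[seq_len(m_max)])
  }
  f <- function(x) besselJ(x, 0) - besselJ(x, 1) / x # J1'(x)
  # roots are ~pi apart; scan a fine grid and refine each bracket
  upper <- (m_max + 2) * pi
  xs <- seq(0.5, upper, by = 0.01)
  fx <- f(xs)
  sgn <- which(fx[-1] * fx[-length(fx)] < 0)
  roots <- vapply(sgn, function(i) {
    stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-14)$root
  }, numeric(1))
  roots <- roots[seq_len(min(length(roots), max(m_max, 64)))]
  .axt_cache$j1p_roots <- roots
  roots[seq_len(m_max)]
}

#' Roots of the cylinder boundary condition
#'
#' Ascending positive roots `alpha_m` of `J1'(alpha R) = 0`, the eigenvalue
#' condition for diffusion restricted in an impermeable cylinder of radius
#' `R`. The scaled roots `alpha_m * R` are universal constants (1.8412,
#' 5.3314, ...), so roots for any radius are obtained by rescaling.
#'
#' @param R Cylinder radius, um.
#' @param m_max Number of roots.
#' @return Numeric vector of `m_max` strictly increasing roots, um^-1.
#' @examples
#' bessel_alpha_roots(1, 3)
#' @export
bessel_alpha_roots <- function(R, m_max = 30) {
  if (R <= 0) stop("R must be > 0", call. = FALSE)
  stopifnot(m_max >= 1)
  .scaled_bessel_roots(m_max) / R
}

# Van Gelderen series sum C(Delta; R) such that
# ln S_perp = -8 pi^2 q_perp^2 * C. Returns a length(Delta) x length(R)
# matrix. Units: C in um^2 * ms ... (q^2 * C dimensionless).
.vg_sum <- function(Delta, delta, D_f, R, m_max = 30) {
  x <- .scaled_bessel_roots(m_max)
  out <- matrix(0, length(Delta), length(R))
  if (D_f <= 0) {
    return(out)
  }
  flag <- FALSE
  for (j in seq_along(R)) {
    alpha2 <- (x / R[j])^2
    a <- D_f * alpha2 # 1/ms
    inv_den <- 1 / (delta^2 * D_f^2 * alpha2^3 * (x^2 - 1))
    # constant-in-Delta part of the numerator, then the Delta-dependent
    # exponentials as length(Delta) x m_max matrices
    base <- 2 * a * delta - 2 + 2 * exp(-a * delta)
    oD <- outer(Delta, a)
    od <- outer(rep(delta, length(Delta)), a)
    num <- rep(base, each = length(Delta)) +
      2 * exp(-oD) - exp(-(oD - od)) - exp(-(oD + od))
    terms <- num * rep(inv_den, each = length(Delta))
    out[, j] <- rowSums(terms)
    # alpha^-6 decay: the tail beyond m_max is of the order of the last
    # term, so a last-term share above 1e-9 marks a truncated series --
    # provided the tail is also large enough in absolute terms to move a
    # signal at the q-values of interest (1e-8 in the series sum is ~2e-9
    # in signal at b = 4000 s/mm^2)
    tail_rel <- abs(terms[, m_max]) / pmax(abs(out[, j]), 1e-300)
    if (any(tail_rel > 1e-9 & abs(terms[, m_max]) > 1e-8)) flag <- TRUE
  }
  if (flag) {
    warning(
      "restricted-cylinder series not converged at m_max = ", m_max,
      "; increase m_max",
      call. = FALSE
    )
  }
  out
}

#' Restricted signal perpendicular to a cylinder
#'
#' Diffusion-weighted signal of water restricted in an impermeable cylinder,
#' measured perpendicular to its axis, under finite-width rectangular
#' gradient pulses (Van Gelderen's series solution). The log-signal is
#' `-8 pi^2 q_perp^2` times a sum over cylinder eigenmodes; the series is
#' truncated at `m_max` terms (terms decay as `alpha_m^-6`; 30 terms are
#' ample for radii up to 5 um and b up to 4000 s/mm^2) and a warning flags
#' the (unreachable in practice) non-converged case.
#'
#' @param q_perp Perpendicular q-value, um^-1 (vectorised).
#' @param Delta,delta Gradient spacing and duration, ms.
#' @param D_f Intrinsic (free) diffusivity inside the cylinder, um^2/ms.
#' @param R Cylinder radius, um.
#' @param m_max Series truncation.
#' @return Signal in `(0, 1]`; exactly 1 at `q_perp = 0`.
#' @examples
#' q <- q_from_gradient(gradient_from_b(4000, 17, 48), 17)
#' restricted_perp_signal(q, Delta = 48, delta = 17, D_f = 0.7, R = 1)
#' @export
restricted_perp_signal <- function(q_perp, Delta, delta, D_f, R, m_max = 30) {
  if (R <= 0) stop("R must be > 0", call. = FALSE)
  stopifnot(delta > 0, Delta >= delta, D_f >= 0, m_max >= 1)
  C <- .vg_sum(Delta, delta, D_f, R, m_max)[1, 1]
  exp(-8 * pi^2 * q_perp^2 * C)
}

#' Restricted signal parallel to the cylinder axis
#'
#' Along the axis the intra-axonal water diffuses freely:
#' `S = exp(-4 pi^2 q_par^2 (Delta - delta/3) D_rpar)`.
#'
#' @param q_par Parallel q-value, um^-1 (vectorised).
#' @param Delta,delta Gradient spacing and duration, ms.
#' @param D_rpar Intra-axonal parallel diffusivity, um^2/ms.
#' @return Signal in `(0, 1]`.
#' @export
restricted_parallel_signal <- function(q_par, Delta, delta, D_rpar) {
  if (D_rpar < 0) stop("D_rpar must be >= 0", call. = FALSE)
  stopifnot(delta > 0, all(Delta >= delta))
  exp(-4 * pi^2 * q_par^2 * (Delta - delta / 3) * D_rpar)
}

#' Perpendicular hindered diffusivity of an extra-axonal tensor variant
#'
#' * `free_tensor`: the stored `D_hperp`.
#' * `tortuosity`: `D_hpar * (1 - f_r)`.
#' * `time_dependent`:
#'   `D_inf + A * (log(Delta/delta) + 3/2) / (Delta - delta/3)` — the
#'   long-time approach to the bulk diffusivity in a short-range-disordered
#'   fiber packing. The logarithmic form assumes `Delta/delta >> 1`; a
#'   warning is emitted (and the expression still evaluated) when
#'   `Delta/delta < 2`.
#'
#' @param spec An [hindered_spec()].
#' @param f_r Restricted signal fraction (used by the tortuosity variant).
#' @param Delta,delta Gradient spacing and duration, ms (vectorised over
#'   `Delta`).
#' @return Perpendicular diffusivity, um^2/ms (recycled to `length(Delta)`).
#' @examples
#' sp <- hindered_spec("time_dependent", D_hpar = 1.5, D_inf = 0.5, A = 2)
#' hindered_dperp(sp, f_r = 0.5, Delta = c(48, 195), delta = 17)
#' @export
hindered_dperp <- function(spec, f_r = NULL, Delta = NULL, delta = NULL) {
  stopifnot(inherits(spec, "axt_hindered"))
  switch(spec$variant,
    free_tensor = rep_len(spec$D_hperp, max(1, length(Delta))),
    tortuosity = {
      stopifnot(!is.null(f_r))
      rep_len(spec$D_hpar * (1 - f_r), max(1, length(Delta)))
    },
    time_dependent = {
      stopifnot(!is.null(Delta), !is.null(delta))
      if (any(Delta / delta < 2)) {
        warning(
          "time-dependent D_hperp uses the log approximation valid for ",
          "Delta/delta >> 1; some Delta/delta < 2",
          call. = FALSE
        )
      }
      spec$D_inf + spec$A * (log(Delta / delta) + 1.5) / (Delta - delta / 3)
    }
  )
}

#' Hindered (extra-axonal) Gaussian signal
#'
#' `S_h = exp(-4 pi^2 (Delta - delta/3) q' D_h q)` with an axially symmetric
#' tensor `D_h` around `fiber_dir`, i.e.
#' `q' D_h q = q_par^2 D_hpar + q_perp^2 D_hperp(Delta)`.
#'
#' @param scheme A scheme tibble (see [steam_scheme()]).
#' @param spec An [hindered_spec()].
#' @param f_r Restricted fraction (tortuosity variant only).
#' @param fiber_dir Unit fiber direction.
#' @return Signal vector, one value per scheme row (1 on b = 0 rows).
#' @export
hindered_signal <- function(scheme, spec, f_r = NULL, fiber_dir = c(1, 0, 0)) {
  geom <- .scheme_geom(scheme, fiber_dir)
  dperp <- hindered_dperp(spec, f_r, geom$Delta, geom$delta)
  if (any(dperp < 0)) {
    stop(
      "hindered tensor not positive semi-definite (derived D_hperp < 0; ",
      "variant = ", spec$variant, ", D_hpar = ", spec$D_hpar, ")",
      call. = FALSE
    )
  }
  exp(-4 * pi^2 * (geom$Delta - geom$delta / 3) *
    (geom$q_par2 * spec$D_hpar + geom$q_perp2 * dperp))
}

#' Restricted (intra-axonal) signal over a diameter distribution
#'
#' Area-weighted mixture of perpendicular cylinder signals times the free
#' parallel decay: `S_r = sum_i w_i S_perp(q_perp; r_i) * S_par(q_par)`.
#'
#' @param scheme A scheme tibble.
#' @param tissue An [tissue_params()] object.
#' @param m_max Series truncation for the perpendicular signal.
#' @return Signal vector, one value per scheme row (1 on b = 0 rows).
#' @export
restricted_signal <- function(scheme, tissue, m_max = 30) {
  geom <- .scheme_geom(scheme, tissue$fiber_dir)
  .restricted_signal_geom(geom, tissue$distribution, tissue$D_rpar,
    tissue$D_f,
    m_max = m_max
  )
}

.restricted_signal_geom <- function(geom, distribution, D_rpar, D_f,
                                    m_max = 30) {
  w <- area_weights(distribution)
  r <- distribution$radius_grid
  # C: unique-Delta x radius matrix of series sums
  C <- .vg_sum(geom$uDelta, geom$delta, D_f, r, m_max)
  # per measurement: sum_i w_i exp(-8 pi^2 q_perp^2 C[Delta, i])
  if (length(r) == 1) {
    s_perp <- exp(-8 * pi^2 * geom$q_perp2 * C[geom$iDelta, 1])
  } else {
    E <- exp(-8 * pi^2 * geom$q_perp2 *
      C[geom$iDelta, , drop = FALSE])
    s_perp <- as.numeric(E %*% w)
  }
  s_par <- exp(-4 * pi^2 * geom$q_par2 * (geom$Delta - geom$delta / 3) *
    D_rpar)
  s_perp * s_par
}

# Precompute per-measurement geometry for a fixed fiber direction.
.scheme_geom <- function(scheme, fiber_dir) {
  stopifnot(length(fiber_dir) == 3)
  q <- q_from_gradient(scheme$g, scheme$delta)
  cosang <- scheme$nx * fiber_dir[1] + scheme$ny * fiber_dir[2] +
    scheme$nz * fiber_dir[3]
  q_par2 <- (q * cosang)^2
  q_perp2 <- pmax(q^2 - q_par2, 0)
  uDelta <- sort(unique(scheme$Delta))
  list(
    q = q, q_par2 = q_par2, q_perp2 = q_perp2,
    Delta = scheme$Delta, delta = scheme$delta[1], TM = scheme$TM,
    is_b0 = scheme$is_b0,
    uDelta = uDelta, iDelta = match(scheme$Delta, uDelta)
  )
}

#' Synthesise the STEAM two-pool signal for a scheme
#'
#' Per measurement:
#' `S = exp(-TM/T1) * S0 * ((1 - f_r) S_h + f_r S_r)`; b = 0 rows carry only
#' the mixing-time T1 decay, `exp(-TM/T1) * S0`.
#'
#' @param scheme A scheme tibble.
#' @param tissue An [tissue_params()] object.
#' @param S0 Signal amplitude at b = 0 and TM = 0.
#' @param m_max Series truncation for the restricted signal.
#' @return The scheme tibble with a `signal` column appended.
#' @examples
#' tis <- tissue_params(
#'   f_r = 0.5,
#'   hindered = hindered_spec("time_dependent", D_hpar = 1, D_inf = 0.5, A = 2),
#'   distribution = axon_distribution("delta", radius = 1.5),
#'   D_rpar = 1, D_f = 1
#' )
#' sig <- steam_signal(steam_scheme(), tis)
#' head(sig$signal)
#' @export
steam_signal <- function(scheme, tissue, S0 = 1, m_max = 30) {
  stopifnot(inherits(tissue, "axt_tissue"))
  s_h <- hindered_signal(scheme, tissue$hindered, tissue$f_r,
    fiber_dir = tissue$fiber_dir
  )
  s_r <- restricted_signal(scheme, tissue, m_max = m_max)
  decay <- exp(-scheme$TM / tissue$T1) * S0
  sig <- decay * ((1 - tissue$f_r) * s_h + tissue$f_r * s_r)
  sig[scheme$is_b0] <- decay[scheme$is_b0]
  dplyr::mutate(scheme, signal = sig)
}

#' Add Rician noise to a signal vector
#'
#' The magnitude of the signal perturbed by independent complex Gaussian
#' noise: `|S + n1 + i n2|` with `n1, n2 ~ N(0, (S_ref/SNR)^2)`. `S_ref` is
#' the noise-reference amplitude; by convention the noiseless b = 0
#' amplitude of the largest-Delta group (the image on which in vivo SNR is
#' quoted).
#'
#' @param signal Numeric signal vector.
#' @param snr Signal-to-noise ratio (> 0).
#' @param s_ref Reference amplitude defining the noise standard deviation
#'   `s_ref / snr`.
#' @param seed Optional integer; when given the draw is made under a local
#'   RNG seed and is reproducible.
#' @return Noisy magnitude signal, same length as `signal`.
#' @export
add_rician_noise <- function(signal, snr, s_ref = 1, seed = NULL) {
  stopifnot(snr > 0, s_ref > 0)
  draw <- function() {
    sigma <- s_ref / snr
    n <- length(signal)
    sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
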