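# Independent oracles used across the suite.

# Long-series, high-precision evaluation of the restricted-cylinder
# perpendicular signal, written directly from the series definition and
# independent of the package's vectorised implementation. Roots are located
# by bracketed bisection on a fine grid of J1'.
oracle_vg_perp <- function(q_perp, Delta, delta, D_f, R, n_terms = 200) {
  j1p <- function(x) besselJ(x, 0) - besselJ(x, 1) / x
  xs <- seq(0.5, (n_terms + 2) * pi, by = 0.005)
  fx <- j1p(xs)
  idx <- which(fx[-1] * fx[-length(fx)] < 0)[seq_len(n_terms)]
  roots <- vapply(idx, function(i) {
    lo <- xs[i]
    hi <- xs[i + 1]
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      if (j1p(lo) * j1p(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  alpha <- roots / R
  a <- D_f * alpha^2
  num <- 2 * a * delta - 2 + 2 * exp(-a * delta) + 2 * exp(-a * Delta) -
    exp(-a * (Delta - delta)) - exp(-a * (Delta + delta))
  den <- delta^2 * D_f^2 * alpha^6 * (R^2 * alpha^2 - 1)
  exp(-8 * pi^2 * q_perp^2 * sum(num / den))
}

# q perpendicular for a b-value on the package's STEAM timing
q_for_b <- function(b, delta = 17, Delta = 48) {
  q_from_gradient(gradient_from_b(b, delta, Delta), delta)
}

# small single-radius tissue for round trips
make_tissue <- function(f_r = 0.4, D = 1.2, R = 1.5, D_inf = 0.5, A = 2,
                        T1 = 800) {
  tissue_params(
    f_r = f_r,
    hindered = hindered_spec("time_dependent",
      D_hpar = D, D_inf = D_inf,
      A = A
    ),
    distribution = axon_distribution("delta", radius = R),
    D_rpar = D, D_f = D, T1 = T1
  )
}
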