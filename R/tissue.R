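#' Extra-axonal (hindered) tensor specifications
#'
#' The hindered compartment is an axially symmetric Gaussian tensor around
#' the fiber direction. Three variants of its perpendicular component are
#' supported:
#'
#' * `free_tensor` — `D_hperp` is an independent parameter;
#' * `tortuosity` — `D_hperp = D_hpar * (1 - f_r)` is derived from the
#'   restricted fraction at evaluation time (NODDI/ActiveAx constraint);
#' * `time_dependent` — packing disorder makes the perpendicular diffusivity
#'   depend on the diffusion time,
#'   `D_hperp(Delta) = D_inf + A * (log(Delta/delta) + 3/2) / (Delta - delta/3)`,
#'   with bulk diffusivity `D_inf` (um^2/ms) and disorder coefficient `A`
#'   (um^2, scaling with the squared correlation length of the fiber
#'   packing).
#'
#' @param variant One of `"free_tensor"`, `"tortuosity"`, `"time_dependent"`.
#' @param D_hpar Parallel hindered diffusivity, um^2/ms.
#' @param D_hperp Perpendicular hindered diffusivity, um^2/ms
#'   (`free_tensor` only).
#' @param D_inf,A Time-dependent variant parameters (um^2/ms, um^2).
#'
#' @return An object of class `axt_hindered`.
#' @examples
#' hindered_spec("time_dependent", D_hpar = 1.5, D_inf = 0.5, A = 2)
#' @export
hindered_spec <- function(variant = c("free_tensor", "tortuosity", "time_dependent"),
                          D_hpar, D_hperp = NULL, D_inf = NULL, A = NULL) {
  variant <- match.arg(variant)
  stopifnot(D_hpar >= 0)
  if (variant == "free_tensor") {
    stopifnot(is.numeric(D_hperp), D_hperp >= 0)
    D_inf <- A <- NULL
  } else if (variant == "tortuosity") {
    if (!is.null(D_hperp)) {
      stop("tortuosity variant derives D_hperp from f_r; do not supply it",
        call. = FALSE
      )
    }
    D_inf <- A <- NULL
  } else {
    stopifnot(is.numeric(D_inf), D_inf >= 0, is.numeric(A), A >= 0)
    D_hperp <- NULL
  }
  structure(
    list(
      variant = variant, D_hpar = D_hpar, D_hperp = D_hperp,
      D_inf = D_inf, A = A
    ),
    class = "axt_hindered"
  )
}

#' Tissue parameters of the two-pool model
#'
#' @param f_r Restricted (intra-axonal) signal fraction in `[0, 1]`; the
#'   hindered fraction is `1 - f_r`.
#' @param hindered An [hindered_spec()].
#' @param distribution An [axon_distribution()].
#' @param D_rpar Intra-axonal parallel diffusivity, um^2/ms.
#' @param D_f Intrinsic intra-axonal diffusivity perpendicular to the fiber
#'   (the free diffusion coefficient of the restricted-cylinder model),
#'   um^2/ms.
#' @param T1 Longitudinal relaxation time, ms.
#' @param fiber_dir Unit fiber direction (3-vector).
#'
#' @return An object of class `axt_tissue`.
#' @examples
#' tissue_params(
#'   f_r = 0.5,
#'   hindered = hindered_spec("time_dependent", D_hpar = 1, D_inf = 0.5, A = 2),
#'   distribution = axon_distribution("delta", radius = 1.5),
#'   D_rpar = 1, D_f = 1
#' )
#' @export
tissue_params <- function(f_r, hindered, distribution, D_rpar, D_f,
                          T1 = 800, fiber_dir = c(1, 0, 0)) {
  stopifnot(
    f_r >= 0, f_r <= 1, inherits(hindered, "axt_hindered"),
    inherits(distribution, "axt_distribution"),
    D_rpar >= 0, D_f >= 0, T1 > 0, length(fiber_dir) == 3
  )
  nrm <- sqrt(sum(fiber_dir^2))
  if (abs(nrm - 1) > 1e-9) {
    stop("fiber_dir must be a unit vector", call. = FALSE)
  }
  structure(
    list(
      f_r = f_r, hindered = hindered, distribution = distribution,
      D_rpar = D_rpar, D_f = D_f, T1 = T1,
      fiber_dir = as.numeric(fiber_dir)
    ),
    class = "axt_tissue"
  )
}
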