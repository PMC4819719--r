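#' Voxelwise model fitting over a 4D volume
#'
#' Applies a model fit to every in-mask voxel of a 4D signal array whose
#' fourth dimension matches the scheme rows, producing one 3D parameter map
#' per estimate plus a convergence map. Out-of-mask voxels are `NA`.
#'
#' @param volume 4D numeric array `(x, y, z, measurement)`, or a path to a
#'   NIfTI file (read with RNifti when installed).
#' @param scheme A scheme tibble with `nrow(scheme) == dim(volume)[4]`.
#' @param mask Logical 3D array (default: all voxels).
#' @param model `"diameter_time_dependent"`, `"diameter_time_independent"`,
#'   `"density_free_tensor"` or `"density_tortuosity"` (density models
#'   require a single-Delta scheme).
#' @param fiber_dir Fiber direction supplied to the fits.
#' @param config A [fit_config()].
#' @param ... Passed to the underlying fit function.
#' @return A named list of 3D arrays (class `axt_maps`): one per parameter,
#'   plus `converged`.
#' @export
fit_volume <- function(volume, scheme, mask = NULL,
                       model = c(
                         "diameter_time_dependent",
                         "diameter_time_independent",
                         "density_free_tensor", "density_tortuosity"
                       ),
                       fiber_dir = c(1, 0, 0), config = fit_config(), ...) {
  model <- match.arg(model)
  if (is.character(volume)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI volumes requires the RNifti package", call. = FALSE)
    }
    volume <- as.array(RNifti::readNifti(volume))
  }
  stopifnot(length(dim(volume)) == 4)
  dims <- dim(volume)
  if (dims[4] != nrow(scheme)) {
    stop(
      "volume has ", dims[4], " measurements but the scheme has ",
      nrow(scheme), " rows",
      call. = FALSE
    )
  }
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  stopifnot(identical(dim(mask), dims[1:3]))
  fit_fun <- switch(model,
    diameter_time_dependent = function(d, ...) {
      fit_diameter(d, time_dependent = TRUE, fiber_dir = fiber_dir,
        config = config, ...)
    },
    diameter_time_independent = function(d, ...) {
      fit_diameter(d, time_dependent = FALSE, fiber_dir = fiber_dir,
        config = config, ...)
    },
    density_free_tensor = function(d, ...) {
      fit_density(d, "free_tensor", fiber_dir = fiber_dir,
        config = config, ...)
    },
    density_tortuosity = function(d, ...) {
      fit_density(d, "tortuosity", fiber_dir = fiber_dir,
        config = config, ...)
    }
  )
  maps <- NULL
  idx <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    i <- idx[v, 1]
    j <- idx[v, 2]
    k <- idx[v, 3]
    d <- dplyr::mutate(scheme, signal = volume[i, j, k, ])
    fit <- fit_fun(d, ...)
    est <- c(coef(fit), converged = as.numeric(fit$converged))
    if (is.null(maps)) {
      maps <- purrr::map(est, ~ array(NA_real_, dims[1:3]))
      names(maps) <- names(est)
    }
    for (nm in names(est)) maps[[nm]][i, j, k] <- est[[nm]]
  }
  structure(maps, class = "axt_maps")
}

#' Write parameter maps to NIfTI files
#'
#' One float32 NIfTI-1 file per parameter, named `<prefix>_<parameter>.nii`;
#' the affine/header is copied from `reference` when given.
#'
#' @param maps An `axt_maps` list from [fit_volume()].
#' @param prefix Output path prefix.
#' @param reference Optional NIfTI file or image supplying the header.
#' @return Paths written, invisibly.
#' @export
write_parameter_maps <- function(maps, prefix, reference = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI maps requires the RNifti package", call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(maps)) {
    img <- maps[[nm]]
    if (!is.null(reference)) {
      img <- RNifti::asNifti(img, reference = RNifti::readNifti(reference))
    }
    path <- paste0(prefix, "_", nm, ".nii")
    RNifti::writeNifti(img, path, datatype = "float")
    paths <- c(paths, path)
  }
  invisible(paths)
}
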