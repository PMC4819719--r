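#' STEAM acquisition schemes
#'
#' An acquisition scheme is a tibble with one diffusion-weighted (or
#' unweighted) measurement per row and columns:
#'
#' * `nx`, `ny`, `nz` — unit gradient direction in the scanner frame
#'   (all zero on b = 0 rows),
#' * `g` — gradient amplitude, mT/m,
#' * `delta` — gradient pulse duration, ms,
#' * `Delta` — gradient pulse spacing (diffusion time), ms,
#' * `TM` — STEAM mixing time, ms,
#' * `b` — b-value, s/mm^2 (rectangular-pulse convention),
#' * `is_b0` — logical flag for unweighted measurements.
#'
#' `steam_scheme()` builds the nine-diffusion-time STEAM protocol used
#' throughout the package: `variant = "main"` has delta = 17 ms,
#' Delta = 48, 60, 80, 100, 120, 140, 160, 180, 195 ms, b-values
#' 500/1000/2000/4000 s/mm^2 on five directions (two in-plane diagonals, the
#' two in-plane axes and the fiber axis) plus two b = 0 rows per
#' diffusion time; `variant = "low_delta"` has delta = 12 ms, Delta starting
#' at 38 ms and b-values 250/500/1000/2000 s/mm^2. The mixing time follows
#' `TM = Delta - 33.6` ms (see [STEAM_TM_OFFSET]). Diagonal directions are
#' realised by energising two gradient axes simultaneously, which the scanner
#' treats as a single larger amplitude on a unit direction (70 sqrt(2) ~ 99
#' mT/m ceiling).
#'
#' @param variant `"main"` or `"low_delta"`.
#' @param n_b0 Number of b = 0 measurements per diffusion time.
#'
#' @return A scheme tibble (class `axt_scheme`).
#' @examples
#' sch <- steam_scheme()
#' dplyr::count(sch, Delta)
#' @export
steam_scheme <- function(variant = c("main", "low_delta"), n_b0 = 2) {
  variant <- match.arg(variant)
  if (variant == "main") {
    delta <- 17
    Deltas <- c(48, 60, 80, 100, 120, 140, 160, 180, 195)
    bvals <- c(500, 1000, 2000, 4000)
  } else {
    delta <- 12
    Deltas <- c(38, 60, 80, 100, 120, 140, 160, 180, 195)
    bvals <- c(250, 500, 1000, 2000)
  }
  dirs <- rbind(
    c(0, 1, 1) / sqrt(2),
    c(0, -1, 1) / sqrt(2),
    c(0, 1, 0),
    c(0, 0, 1),
    c(1, 0, 0)
  )
  rows <- purrr::map(Deltas, function(D) {
    dw <- tidyr::expand_grid(b = bvals, idir = seq_len(nrow(dirs)))
    dw <- dplyr::mutate(dw,
      nx = dirs[.data$idir, 1], ny = dirs[.data$idir, 2],
      nz = dirs[.data$idir, 3],
      g = gradient_from_b(.data$b, delta, D),
      delta = delta, Delta = D, TM = D - STEAM_TM_OFFSET,
      is_b0 = FALSE
    )
    b0 <- tibble::tibble(
      b = 0, idir = NA_integer_, nx = 0, ny = 0, nz = 0, g = 0,
      delta = delta, Delta = D, TM = D - STEAM_TM_OFFSET,
      is_b0 = TRUE, .rows = n_b0
    )
    dplyr::bind_rows(dw, b0)
  })
  sch <- dplyr::select(
    dplyr::bind_rows(rows),
    "nx", "ny", "nz", "g", "delta", "Delta", "TM", "b", "is_b0"
  )
  new_scheme(sch)
}

new_scheme <- function(x) {
  x <- tibble::as_tibble(x)
  class(x) <- c("axt_scheme", class(x))
  validate_scheme(x)
  x
}

#' Validate an acquisition scheme
#'
#' Checks the measurement-level invariants (unit directions off b = 0 rows,
#' positive timings, b/g consistency under the rectangular-pulse identity)
#' and the scheme-level invariants (a single pulse duration delta, at least
#' one b = 0 row per diffusion-time group).
#'
#' @param scheme A scheme tibble as returned by [steam_scheme()].
#' @return The scheme, invisibly; errors name the offending rows.
#' @export
validate_scheme <- function(scheme) {
  req <- c("nx", "ny", "nz", "g", "delta", "Delta", "TM", "b", "is_b0")
  miss <- setdiff(req, names(scheme))
  if (length(miss)) {
    stop("scheme is missing columns: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  nrm <- sqrt(scheme$nx^2 + scheme$ny^2 + scheme$nz^2)
  bad <- which(!scheme$is_b0 & abs(nrm - 1) > 1e-9)
  if (length(bad)) {
    stop("non-unit gradient direction on non-b0 rows: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- which(scheme$delta <= 0 | scheme$Delta < scheme$delta | scheme$TM < 0)
  if (length(bad)) {
    stop("invalid timings (need delta > 0, Delta >= delta, TM >= 0) on rows: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(unique(scheme$delta)) > 1) {
    off <- which(scheme$delta != scheme$delta[1])
    stop("scheme mixes pulse durations delta; offending rows: ",
      paste(off, collapse = ", "),
      call. = FALSE
    )
  }
  b_chk <- b_from_gradient(scheme$g, scheme$delta, scheme$Delta)
  bad <- which(!scheme$is_b0 &
    abs(b_chk - scheme$b) > 0.005 * pmax(scheme$b, 1))
  if (length(bad)) {
    stop("b and g inconsistent (> 0.5%) on rows: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  n_b0 <- tapply(scheme$is_b0, scheme$Delta, sum)
  if (any(n_b0 < 1)) {
    stop("every Delta group needs at least one b = 0 measurement",
      call. = FALSE
    )
  }
  invisible(scheme)
}

#' Read and write scheme files
#'
#' Plain-text scheme files hold one measurement per row with
#' whitespace-separated columns `nx ny nz g_mTm delta_ms Delta_ms TM_ms`
#' (gradient amplitude in mT/m) after a header line naming the columns.
#' Lines starting with `#` are comments. If the header names the fourth
#' column `b_smm2` the file stores b-values instead of gradient amplitudes
#' and `read_scheme()` converts. Written files round-trip all fields at full
#' double precision.
#'
#' @param path File path.
#' @param scheme A scheme tibble.
#' @param b_column Write the b-value column (`b_smm2`) instead of the
#'   gradient amplitude.
#' @return `read_scheme()` returns a validated scheme tibble;
#'   `write_scheme()` returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (length(lines) < 2) stop("scheme file has no data rows", call. = FALSE)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  amp_col <- header[4]
  if (!amp_col %in% c("g_mTm", "b_smm2")) {
    stop("unrecognised scheme header (column 4 must be g_mTm or b_smm2)",
      call. = FALSE
    )
  }
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  n_fld <- lengths(rows)
  if (any(n_fld != 7)) {
    stop("malformed scheme row(s) (expected 7 columns): ",
      paste(which(n_fld != 7), collapse = ", "),
      call. = FALSE
    )
  }
  num <- suppressWarnings(
    matrix(as.numeric(unlist(rows)), ncol = 7, byrow = TRUE)
  )
  if (anyNA(num)) {
    bad <- unique(which(is.na(num), arr.ind = TRUE)[, 1])
    stop("non-numeric scheme row(s): ", paste(sort(bad), collapse = ", "),
      call. = FALSE
    )
  }
  sch <- tibble::tibble(
    nx = num[, 1], ny = num[, 2], nz = num[, 3],
    delta = num[, 5], Delta = num[, 6], TM = num[, 7]
  )
  if (amp_col == "g_mTm") {
    sch$g <- num[, 4]
    sch$b <- b_from_gradient(sch$g, sch$delta, sch$Delta)
  } else {
    sch$b <- num[, 4]
    sch$g <- gradient_from_b(sch$b, sch$delta, sch$Delta)
  }
  nrm <- sqrt(sch$nx^2 + sch$ny^2 + sch$nz^2)
  sch$is_b0 <- sch$g == 0 & nrm == 0
  sch$b[sch$is_b0] <- 0
  new_scheme(sch[, c(
    "nx", "ny", "nz", "g", "delta", "Delta", "TM", "b",
    "is_b0"
  )])
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path, b_column = FALSE) {
  validate_scheme(scheme)
  amp <- if (b_column) "b_smm2" else "g_mTm"
  val <- if (b_column) scheme$b else scheme$g
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# STEAM diffusion acquisition scheme",
    paste("nx ny nz", amp, "delta_ms Delta_ms TM_ms")
  ), con)
  body <- sprintf(
    "%.17g %.17g %.17g %.17g %.17g %.17g %.17g",
    scheme$nx, scheme$ny, scheme$nz, val,
    scheme$delta, scheme$Delta, scheme$TM
  )
  writeLines(body, con)
  invisible(path)
}
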