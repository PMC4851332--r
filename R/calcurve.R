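#' Construct a calibration curve
#'
#' A calibration curve maps calendar years BP (years before AD 1950) to
#' conventional radiocarbon ages (mu, in 14C years BP) with a 1-sigma curve
#' error. Grids are stored in strictly decreasing cal BP order (the IntCal
#' file convention: larger = older); increasing input is reversed.
#'
#' @param calbp numeric, strictly monotone calendar years BP.
#' @param mu numeric, 14C age BP at each grid year.
#' @param sigma numeric, 1-sigma curve error (14C years) at each grid year;
#'   must be >= 0 (zero is permitted so that toy curves have a closed-form
#'   Gaussian calibration limit).
#' @param name free-text curve label.
#' @return An object of class `calcurve`.
#' @seealso [read_calcurve()], [interpolate_curve()], [toy_identity_curve()]
#' @export
calcurve <- function(calbp, mu, sigma, name = "curve") {
  calbp <- as.numeric(calbp)
  mu <- as.numeric(mu)
  sigma <- as.numeric(sigma)
  n <- length(calbp)
  if (n < 2L)
    stop("a calibration curve needs at least two grid points")
  if (length(mu) != n || length(sigma) != n)
    stop("calbp, mu and sigma must have equal length")
  if (!all(is.finite(calbp)) || !all(is.finite(mu)) || !all(is.finite(sigma)))
    stop("calibration curve contains missing or non-finite values")
  d <- diff(calbp)
  if (all(d > 0)) {
    calbp <- rev(calbp)
    mu <- rev(mu)
    sigma <- rev(sigma)
  } else if (!all(d < 0)) {
    stop("calbp grid must be strictly monotone (duplicated or unordered years)")
  }
  if (any(sigma < 0))
    stop("sigma_curve must be >= 0 everywhere")
  ord <- order(mu)
  structure(
    list(calbp = calbp, mu = mu, sigma = sigma, name = name,
         mu_ord = ord, mu_sorted = mu[ord], sigma_max = max(sigma),
         cache = new.env(parent = emptyenv())),
    class = "calcurve"
  )
}

#' Read a calibration curve file
#'
#' Supports the IntCal plain-text dialect (comment lines starting with `#`;
#' comma- or whitespace-delimited rows whose first three fields are cal BP,
#' 14C age BP and 1-sigma error; trailing columns such as Delta-14C are
#' ignored) and a `simple` three-column CSV dialect with header
#' `calbp,c14age,error` used for fixtures.
#'
#' @param path path to the curve file.
#' @param dialect `"intcal"` or `"simple"`.
#' @param name curve label; defaults to the file name without extension.
#' @return A [calcurve()] at the file's native resolution, ordered by
#'   decreasing cal BP.
#' @export
read_calcurve <- function(path, dialect = c("intcal", "simple"), name = NULL) {
  dialect <- match.arg(dialect)
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("calibration curve file not found: ", path)
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  idx <- which(!grepl("^\\s*(#|$)", lines))
  if (dialect == "simple") {
    if (length(idx) < 1L) stop("empty curve file: ", path)
    idx <- idx[-1L] # header row
  }
  if (length(idx) < 2L)
    stop("curve file has fewer than two data rows: ", path)
  parts <- strsplit(trimws(lines[idx]), "[,\t ]+")
  short <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(short))
    stop("cannot parse line ", idx[short[1L]], " of ", path,
         " (fewer than 3 fields)")
  col <- function(k) suppressWarnings(as.numeric(vapply(parts, `[[`, "", k)))
  calbp <- col(1L)
  mu <- col(2L)
  sig <- col(3L)
  bad <- which(is.na(calbp) | is.na(mu) | is.na(sig))
  if (length(bad))
    stop("non-numeric value at line ", idx[bad[1L]], " of ", path)
  calcurve(calbp, mu, sig, name = name)
}

#' Write a calibration curve file
#'
#' Inverse of [read_calcurve()]: the `simple` dialect round-trips a curve
#' bit-exactly through [read_calcurve()].
#'
#' @param curve a [calcurve()].
#' @param path output path.
#' @param dialect `"simple"` (CSV with header) or `"intcal"` (comment header
#'   plus comma-separated rows).
#' @return `path`, invisibly.
#' @export
write_calcurve <- function(curve, path, dialect = c("simple", "intcal")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(curve, "calcurve"))
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 17)
  rows <- paste(fmt(curve$calbp), fmt(curve$mu), fmt(curve$sigma), sep = ",")
  if (dialect == "simple") {
    writeLines(c("calbp,c14age,error", rows), path)
  } else {
    writeLines(c(paste0("# ", curve$name), "# calbp,c14age,error", rows), path)
  }
  invisible(path)
}

#' Interpolate a calibration curve onto a regular grid
#'
#' Linear interpolation of both `mu` and `sigma` onto a grid of the given
#' resolution spanning the curve's range. Interpolation is exact at the
#' original knots; interpolated values are bounded by the bracketing knots.
#'
#' @param curve a [calcurve()].
#' @param resolution grid spacing in calendar years (default 1).
#' @return A [calcurve()] on the regular grid.
#' @export
interpolate_curve <- function(curve, resolution = 1) {
  stopifnot(inherits(curve, "calcurve"))
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      !is.finite(resolution) || resolution <= 0)
    stop("resolution must be a positive number of years")
  grid <- seq(curve$calbp[1L], curve$calbp[length(curve$calbp)],
              by = -resolution)
  mu <- stats::approx(curve$calbp, curve$mu, xout = grid)$y
  sg <- stats::approx(curve$calbp, curve$sigma, xout = grid)$y
  calcurve(grid, mu, sg, name = curve$name)
}

#' Toy identity calibration curve
#'
#' A curve with `mu(t) = t` and constant curve error, on an annual grid.
#' With `sigma = 0`, calibrating a CRA of `x +/- e` against it reduces to a
#' Gaussian in calendar time centred on `x` with sd `e`, which gives the
#' test-suite a closed-form oracle.
#'
#' @param start oldest calendar year BP (`start > end`).
#' @param end youngest calendar year BP (`end >= 0`).
#' @param sigma constant curve error in 14C years (default 0).
#' @return A [calcurve()].
#' @export
toy_identity_curve <- function(start, end, sigma = 0) {
  if (!(start > end && end >= 0))
    stop("need start > end >= 0")
  grid <- seq(start, end, by = -1)
  calcurve(grid, grid, rep(as.numeric(sigma), length(grid)),
           name = "toy_identity")
}

#' Toy wiggly calibration curve
#'
#' An identity curve perturbed by a sinusoid,
#' `mu(t) = t + amplitude * sin(2 * pi * t / period)`, emulating the
#' short-term wiggles of real atmospheric curves that produce multimodal
#' calibrated densities and plateaux.
#'
#' @param start,end oldest/youngest calendar year BP.
#' @param sigma constant curve error in 14C years.
#' @param amplitude wiggle amplitude in 14C years.
#' @param period wiggle period in calendar years.
#' @return A [calcurve()].
#' @export
toy_wiggle_curve <- function(start, end, sigma = 10, amplitude = 20,
                             period = 500) {
  if (!(start > end && end >= 0))
    stop("need start > end >= 0")
  grid <- seq(start, end, by = -1)
  mu <- grid + amplitude * sin(2 * pi * grid / period)
  calcurve(grid, mu, rep(as.numeric(sigma), length(grid)),
           name = "toy_wiggle")
}

#' @export
print.calcurve <- function(x, ...) {
  res <- if (length(x$calbp) > 1L) abs(x$calbp[1L] - x$calbp[2L]) else NA
  cat(sprintf(
    "Calibration curve '%s': %d knots, %s-%s cal BP, spacing %s yr\n",
    x$name, length(x$calbp), format(x$calbp[1L]),
    format(x$calbp[length(x$calbp)]), format(res)))
  invisible(x)
}

# annual-grid helpers -------------------------------------------------------

is_annual <- function(curve) {
  all(abs(diff(curve$calbp) + 1) < 1e-9)
}

ensure_annual <- function(curve) {
  stopifnot(inherits(curve, "calcurve"))
  if (is_annual(curve)) curve else interpolate_curve(curve, 1)
}

curve_span <- function(curve) {
  c(old = curve$calbp[1L], young = curve$calbp[length(curve$calbp)])
}

# linear interpolation of mu/sigma at calendar years y on an ANNUAL curve,
# by direct index arithmetic (much faster than approx in tight loops)
interp_annual <- function(curve, y) {
  n <- length(curve$calbp)
  pos <- curve$calbp[1L] - y # 0 .. n-1, possibly fractional
  i <- pmin(pmax(floor(pos), 0), n - 2L)
  w <- pos - i
  list(mu = curve$mu[i + 1L] * (1 - w) + curve$mu[i + 2L] * w,
       sigma = curve$sigma[i + 1L] * (1 - w) + curve$sigma[i + 2L] * w)
}
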