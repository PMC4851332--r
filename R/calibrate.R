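#' Calibrate a radiocarbon determination
#'
#' Converts a conventional radiocarbon age (CRA) with 1-sigma lab error into
#' a probability mass function over the annual calendar grid by direct
#' numerical integration: at each calendar year `t` the unnormalised mass is
#' the normal density of the CRA under `mu(t)` with combined error
#' `sqrt(error^2 + sigma_curve(t)^2)`. Masses below `eps` times the per-date
#' maximum are zeroed, the result renormalised to sum to one, and the
#' support trimmed to the smallest contiguous window holding all non-zero
#' mass.
#'
#' @param cra conventional radiocarbon age, 14C years BP.
#' @param error 1-sigma lab error, 14C years (> 0 unless the curve carries
#'   positive error).
#' @param curve a [calcurve()]; interpolated to an annual grid if needed.
#' @param eps probability floor as a fraction of the per-date maximum
#'   (default 1e-5); bounds the support length.
#' @return A `cal_density`: list with `calbp` (decreasing annual grid),
#'   `prob` (per-year probability mass summing to 1) and `normalised`.
#' @examples
#' tc <- toy_identity_curve(8000, 2000)
#' d <- calibrate(5000, 20, tc)
#' sum(d$prob)
#' @export
calibrate <- function(cra, error, curve, eps = 1e-5) {
  stopifnot(inherits(curve, "calcurve"), length(cra) == 1L,
            length(error) == 1L, is.finite(cra), is.finite(error))
  if (error < 0 || (error == 0 && all(curve$sigma == 0)))
    stop("error must be > 0 (or the curve must carry positive sigma)")
  curve <- ensure_annual(curve)
  v <- calibrate_cached(cra, error, curve, eps)
  n <- length(v$prob)
  new_cal_density(seq(v$start, by = -1, length.out = n), v$prob)
}

# cached kernel: returns list(start = oldest cal BP of support, prob).
# Cache lives in the curve's environment so repeated (cra, error) pairs --
# ubiquitous in Monte-Carlo back-calibration -- calibrate once.
calibrate_cached <- function(cra, error, curve, eps = 1e-5) {
  key <- paste0(cra, "|", error, "|", eps)
  hit <- curve$cache[[key]]
  if (!is.null(hit))
    return(hit)
  # the integrand is negligible (< e^-32 of the peak, far below the default
  # floor) beyond 8 combined sigma from the CRA, so evaluate only the grid
  # years whose mu falls in that band (located via the sorted-mu index)
  sd0 <- 8 * sqrt(error^2 + curve$sigma_max^2)
  j1 <- findInterval(cra - sd0, curve$mu_sorted) + 1L
  j2 <- findInterval(cra + sd0, curve$mu_sorted)
  if (j1 > j2)
    stop("CRA ", cra, " +/- ", error, " attains no probability mass on curve '",
         curve$name, "' (", min(curve$mu), "-", max(curve$mu),
         " 14C BP); is the date outside the curve's range?")
  idx <- curve$mu_ord[j1:j2]
  i1 <- min(idx)
  i2 <- max(idx)
  d <- stats::dnorm(cra, mean = curve$mu[i1:i2],
                    sd = sqrt(error^2 + curve$sigma[i1:i2]^2))
  mx <- max(d)
  if (!is.finite(mx) || mx <= 0)
    stop("CRA ", cra, " +/- ", error, " attains no probability mass on curve '",
         curve$name, "'")
  d[d < eps * mx] <- 0
  d <- d / sum(d)
  nz <- which(d > 0)
  val <- list(start = curve$calbp[i1 + nz[1L] - 1L],
              prob = d[nz[1L]:nz[length(nz)]])
  curve$cache[[key]] <- val
  val
}

new_cal_density <- function(calbp, prob, normalised = TRUE) {
  structure(list(calbp = calbp, prob = prob, normalised = normalised),
            class = "cal_density")
}

#' Calibrate every date of a table
#'
#' @param table a `date_table` (see [read_dates()]).
#' @param curve a [calcurve()].
#' @param eps probability floor passed to [calibrate()].
#' @return A list of `cal_density`, one per row of `table`.
#' @export
calibrate_table <- function(table, curve, eps = 1e-5) {
  curve <- ensure_annual(curve)
  lapply(seq_len(nrow(table)), function(i) {
    v <- calibrate_cached(table$cra[i], table$error[i], curve, eps)
    new_cal_density(seq(v$start, by = -1, length.out = length(v$prob)),
                    v$prob)
  })
}

#' Curve lookup at a calendar year (back-calibration kernel)
#'
#' Returns the interpolated curve values at given calendar years: the 14C
#' age `mu` and curve error `sigma` a sample of that true age would be
#' measured around.
#'
#' @param cal_year calendar year(s) BP, within the curve span.
#' @param curve a [calcurve()].
#' @return A list with numeric `mu` and `sigma` of the same length as
#'   `cal_year`.
#' @export
uncalibrate <- function(cal_year, curve) {
  stopifnot(inherits(curve, "calcurve"), is.numeric(cal_year))
  sp <- curve_span(curve)
  if (any(cal_year > sp[["old"]] | cal_year < sp[["young"]]))
    stop("cal_year outside curve span (", sp[["young"]], "-", sp[["old"]],
         " cal BP)")
  list(mu = stats::approx(curve$calbp, curve$mu, xout = cal_year)$y,
       sigma = stats::approx(curve$calbp, curve$sigma, xout = cal_year)$y)
}

#' Sample a simulated CRA for a calendar year
#'
#' The engine of the Monte-Carlo null-model test: draws a conventional
#' radiocarbon age `Normal(mu(t), sqrt(sigma_curve(t)^2 + lab_error^2))`,
#' rounded to integer 14C years (the reporting convention of
#' determinations; the effect is far below the lab error). Vectorised over
#' `cal_year` (with `lab_error` recycled); uses the current RNG stream.
#'
#' @param cal_year calendar year(s) BP within the curve span.
#' @param lab_error 1-sigma lab error(s), 14C years, > 0.
#' @param curve a [calcurve()].
#' @return Integer-valued numeric vector of simulated CRAs.
#' @export
sample_cra <- function(cal_year, lab_error, curve) {
  if (any(lab_error <= 0))
    stop("lab_error must be > 0")
  curve <- ensure_annual(curve)
  sp <- curve_span(curve)
  if (any(cal_year > sp[["old"]] | cal_year < sp[["young"]]))
    stop("cal_year outside curve span (", sp[["young"]], "-", sp[["old"]],
         " cal BP)")
  u <- interp_annual(curve, cal_year)
  round(stats::rnorm(length(u$mu), mean = u$mu,
                     sd = sqrt(u$sigma^2 + lab_error^2)))
}

#' Quantiles of a calibrated density
#'
#' The p-quantile is the first grid year (scanning from the oldest end) at
#' which the cumulative mass reaches `p`.
#'
#' @param x a `cal_density`.
#' @param probs quantile levels.
#' @param ... unused.
#' @return Named numeric vector of calendar years BP.
#' @export
quantile.cal_density <- function(x, probs = c(0.025, 0.5, 0.975), ...) {
  cw <- cumsum(x$prob) / sum(x$prob)
  out <- vapply(probs, function(p) x$calbp[which(cw >= p)[1L]], numeric(1))
  names(out) <- paste0(format(100 * probs, trim = TRUE), "%")
  out
}

#' @export
mean.cal_density <- function(x, ...) {
  sum(x$calbp * x$prob) / sum(x$prob)
}

#' @export
print.cal_density <- function(x, ...) {
  q <- quantile(x, c(0.025, 0.5, 0.975))
  cat(sprintf(
    "Calibrated density: %d-%d cal BP (%d yr support), median %d cal BP, 95%% range %d-%d\n",
    round(x$calbp[1L]), round(x$calbp[length(x$calbp)]), length(x$calbp),
    round(q[[2L]]), round(q[[1L]]), round(q[[3L]])))
  invisible(x)
}

#' Write a calibrated density as two-column CSV
#'
#' @param x a `cal_density`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cal_density <- function(x, path) {
  utils::write.csv(data.frame(calbp = x$calbp, prob = x$prob), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# sum the calibrated densities of the dates (cras[i], errs[i]) into an
# accumulator over a decreasing annual grid; cache keys are vectorised once
spd_accumulate <- function(cras, errs, curve, grid, eps = 1e-5) {
  acc <- numeric(length(grid))
  keys <- paste0(cras, "|", errs, "|", eps)
  env <- curve$cache
  g1 <- grid[1L]
  for (i in seq_along(cras)) {
    v <- env[[keys[i]]]
    if (is.null(v))
      v <- calibrate_cached(cras[i], errs[i], curve, eps)
    acc <- acc_add(acc, g1, v$start, v$prob)
  }
  acc
}

# add an annual density (oldest year d_start, masses prob) into the
# accumulator acc whose decreasing annual grid starts at g_start; returns acc
acc_add <- function(acc, g_start, d_start, prob) {
  i0 <- as.integer(round(g_start - d_start)) + 1L
  n <- length(prob)
  j1 <- max(1L, i0)
  j2 <- min(length(acc), i0 + n - 1L)
  if (j1 <= j2)
    acc[j1:j2] <- acc[j1:j2] + prob[(j1 - i0 + 1L):(j2 - i0 + 1L)]
  acc
}
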