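#' Demographic (calendar-date) density for synthetic data
#'
#' A probability density over an annual cal BP grid from which calendar
#' years of synthetic dates are drawn. Kinds:
#' \describe{
#'   \item{uniform}{constant over the range.}
#'   \item{exponential}{proportional to `exp(rate * t)` with `t` in cal BP,
#'     matching the parameterisation recovered by [fit_null()]; negative
#'     rates grow toward the present.}
#'   \item{rise_fall}{a piecewise-linear tent from `floor` at the range
#'     edges to 1 at `peak` (default the midpoint), the simplest shape of a
#'     population boom and bust.}
#'   \item{step}{piecewise-constant `levels` between `breaks`.}
#'   \item{custom}{a user-supplied density vector over the annual grid.}
#' }
#'
#' @param kind density shape, see above.
#' @param range `c(old, young)` cal BP.
#' @param rate exponential rate per cal BP year.
#' @param peak tent apex in cal BP (`rise_fall`).
#' @param floor relative tent height at the range edges (`rise_fall`),
#'   in `[0, 1]`.
#' @param breaks interior change-points in cal BP (`step`), decreasing.
#' @param levels relative level of each step (`length(breaks) + 1` values).
#' @param density density vector over the annual grid (`custom`).
#' @return A `demographic_curve`: list with `kind`, `grid` (decreasing
#'   annual cal BP), `density` (summing to 1) and `range`.
#' @export
demographic_curve <- function(kind = c("uniform", "exponential", "rise_fall",
                                       "step", "custom"),
                              range = c(7000, 3000), rate = 0.001,
                              peak = NULL, floor = 0, breaks = NULL,
                              levels = NULL, density = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(range) == 2L, range[1L] > range[2L])
  grid <- seq(range[1L], range[2L], by = -1)
  dens <- switch(kind,
    uniform = rep(1, length(grid)),
    exponential = exp(rate * (grid - mean(grid))),
    rise_fall = {
      if (is.null(peak))
        peak <- mean(range)
      if (peak > range[1L] || peak < range[2L])
        stop("peak must lie inside range")
      stopifnot(floor >= 0, floor <= 1)
      up <- grid >= peak # older flank
      d <- numeric(length(grid))
      if (range[1L] > peak)
        d[up] <- floor + (1 - floor) * (range[1L] - grid[up]) / (range[1L] - peak)
      else
        d[up] <- 1
      if (peak > range[2L])
        d[!up] <- floor + (1 - floor) * (grid[!up] - range[2L]) / (peak - range[2L])
      else
        d[!up] <- 1
      d
    },
    step = {
      if (is.null(breaks) || is.null(levels) ||
          length(levels) != length(breaks) + 1L)
        stop("step density needs breaks and length(breaks) + 1 levels")
      idx <- findInterval(-grid, sort(-c(range[1L], breaks))) # segment index
      levels[pmin(idx, length(levels))]
    },
    custom = {
      if (is.null(density) || length(density) != length(grid))
        stop("custom density must match the annual grid length")
      as.numeric(density)
    }
  )
  if (any(dens < 0) || all(dens == 0))
    stop("demographic density must be non-negative and not identically zero")
  structure(list(kind = kind, grid = grid, density = dens / sum(dens),
                 range = as.numeric(range)),
            class = "demographic_curve")
}

#' Simulate a table of radiocarbon dates with known structure
#'
#' Draws `n` true calendar years from a demographic density, back-calibrates
#' each through the calibration curve via [sample_cra()] with a lab error
#' resampled from `error_pool`, and assigns dates to sites uniformly at
#' random (multinomial). The true calendar year of every date is kept in a
#' `true_calbp` column. The returned table passes [as_date_table()]
#' validation and feeds the full pipeline.
#'
#' @param dcurve a [demographic_curve()].
#' @param n number of dates (>= 1).
#' @param calcurve a [calcurve()] spanning at least the density's range.
#' @param error_pool lab errors (14C years) resampled with replacement;
#'   default `c(20, 25, 30, 40, 50)`, typical AMS magnitudes.
#' @param sites number of sites to spread dates over.
#' @param set_label set/region label attached to every date.
#' @param site_assignment `"multinomial"` (uniformly random site per date)
#'   or `"round_robin"` (deterministic cycling; with `sites = n` every date
#'   gets its own site, hence its own bin).
#' @param seed optional integer seed.
#' @return A `date_table` with an extra `true_calbp` column.
#' @export
simulate_dates <- function(dcurve, n, calcurve,
                           error_pool = c(20, 25, 30, 40, 50),
                           sites = 10, set_label = "sim",
                           site_assignment = c("multinomial", "round_robin"),
                           seed = NULL) {
  site_assignment <- match.arg(site_assignment)
  stopifnot(inherits(dcurve, "demographic_curve"),
            inherits(calcurve, "calcurve"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("n must be >= 1")
  if (length(error_pool) < 1L || any(error_pool <= 0))
    stop("error_pool must hold positive lab errors")
  if (!is.null(seed))
    set.seed(seed)
  n <- as.integer(n)
  years <- sample(dcurve$grid, n, replace = TRUE, prob = dcurve$density)
  errs <- sample(as.numeric(error_pool), n, replace = TRUE)
  cras <- sample_cra(years, errs, calcurve)
  ns <- max(1L, as.integer(sites))
  site_idx <- if (site_assignment == "multinomial")
    sample.int(ns, n, replace = TRUE) else (seq_len(n) - 1L) %% ns + 1L
  site_ids <- sprintf("%s_site%02d", set_label, site_idx)
  df <- data.frame(
    lab_id = sprintf("%s_%05d", set_label, seq_len(n)),
    site_id = site_ids,
    set_label = set_label,
    cra = cras,
    error = errs,
    delta13c = NA_real_,
    method = "AMS",
    material = "terrestrial",
    stringsAsFactors = FALSE
  )
  out <- as_date_table(df)
  out$true_calbp <- years
  out
}

#' Two-region scenario with a localised divergence
#'
#' Region A is sampled from the shared demographic density; region B from
#' the same density with the mass inside `window` multiplied by
#' `multiplier` and the result renormalised. `multiplier = 1` makes the two
#' regions exchangeable (the null case); `0` carves a gap; values above 1
#' plant a boom. The standard power fixture for [perm_test()].
#'
#' @param shared a [demographic_curve()].
#' @param window `c(old, young)` cal BP where region B's density is scaled.
#' @param multiplier non-negative scale factor inside `window`.
#' @param n_per_region dates per region.
#' @param calcurve a [calcurve()].
#' @param error_pool,sites_per_region passed to [simulate_dates()].
#' @param labels the two region labels.
#' @param seed optional integer seed.
#' @return Named list of two `date_table`s (`labels[1]`, `labels[2]`); bind
#'   them with `rbind` before calling [perm_test()].
#' @export
two_region_scenario <- function(shared, window, multiplier, n_per_region,
                                calcurve,
                                error_pool = c(20, 25, 30, 40, 50),
                                sites_per_region = 20,
                                labels = c("A", "B"), seed = NULL) {
  stopifnot(inherits(shared, "demographic_curve"), length(window) == 2L,
            window[1L] > window[2L], multiplier >= 0,
            length(labels) == 2L)
  inside <- shared$grid <= window[1L] & shared$grid >= window[2L]
  if (!any(inside))
    stop("window does not overlap the shared density's range")
  if (!is.null(seed))
    set.seed(seed)
  dens_b <- shared$density
  dens_b[inside] <- dens_b[inside] * multiplier
  if (all(dens_b == 0))
    stop("multiplier removes all mass from region B's density")
  diverged <- demographic_curve("custom", range = shared$range,
                                density = dens_b)
  a <- simulate_dates(shared, n_per_region, calcurve, error_pool,
                      sites_per_region, set_label = labels[1L])
  b <- simulate_dates(diverged, n_per_region, calcurve, error_pool,
                      sites_per_region, set_label = labels[2L])
  out <- list(a, b)
  names(out) <- labels
  out
}
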