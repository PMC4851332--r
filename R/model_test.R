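#' Fit a null model to an observed SPD
#'
#' The uniform null is a constant density over the analysis range. The
#' exponential null — a proxy for both time-increasing taphonomic loss and
#' long-term population growth — is fitted by ordinary least squares of
#' `log(density + delta)` on the calendar year (`delta` machine-small
#' positive), giving a sampling density proportional to `exp(rate * t)`
#' with `t` in cal BP. Either fit is normalised to a sampling distribution
#' over the SPD's grid.
#'
#' @param spd an `spd` with positive density somewhere.
#' @param kind `"uniform"` or `"exponential"`.
#' @return A `null_model`: list with `kind`, `rate` (per cal BP year; 0 for
#'   uniform), `grid`, `density` (summing to 1) and `range`.
#' @export
fit_null <- function(spd, kind = c("exponential", "uniform")) {
  kind <- match.arg(kind)
  stopifnot(inherits(spd, "spd"))
  d <- spd$density
  if (all(d == 0))
    stop("cannot fit a null model to an all-zero SPD")
  t <- spd$grid
  if (kind == "uniform") {
    rate <- 0
    dens <- rep(1 / length(t), length(t))
  } else {
    # zero-density years carry no information about the log-linear trend
    # and their floored logs would dominate the fit; use positive years
    pos <- d > 0
    if (sum(pos) < 2L || length(unique(t[pos])) < 2L)
      stop("too few positive-density years to fit an exponential null")
    fit <- stats::lm(log(d[pos]) ~ t[pos])
    rate <- unname(stats::coef(fit)[2L])
    dens <- exp(rate * (t - mean(t)))
    dens <- dens / sum(dens)
  }
  structure(list(kind = kind, rate = rate, grid = t, density = dens,
                 range = spd$range),
            class = "null_model")
}

#' Simulate one SPD under a null model
#'
#' Draws `n` calendar years from the null sampling density, back-calibrates
#' each into a simulated CRA via [sample_cra()] with a lab error resampled
#' (with replacement) from the observed error pool, calibrates each
#' simulated date, and sums them — each simulated date is its own bin — into
#' an SPD over the null's range. Uses the current RNG stream.
#'
#' @param model a `null_model` from [fit_null()].
#' @param n number of simulated dates (one per observed bin).
#' @param error_pool non-empty numeric vector of observed lab errors.
#' @param curve a [calcurve()].
#' @param eps calibration probability floor.
#' @return An `spd`.
#' @export
simulate_null_spd <- function(model, n, error_pool, curve, eps = 1e-5) {
  stopifnot(inherits(model, "null_model"), n >= 1, length(error_pool) >= 1)
  curve <- ensure_annual(curve)
  years <- sample(model$grid, n, replace = TRUE, prob = model$density)
  errs <- sample(as.numeric(error_pool), n, replace = TRUE)
  cras <- sample_cra(years, errs, curve)
  grid <- model$grid
  acc <- spd_accumulate(cras, errs, curve, grid, eps)
  structure(list(grid = grid, density = acc, set_label = "simulated",
                 n_bins = n, n_dates = n, range = model$range),
            class = "spd")
}

#' Monte-Carlo null-model test of an SPD
#'
#' Builds the observed binned SPD of `table`, fits the requested null
#' model, generates `nsim` back-calibrated SPDs of `n_bins` simulated dates
#' each, and compares observed and simulated curves on the z-score scale:
#' with per-year mean `m(t)` and standard deviation `s(t)` taken over the
#' ensemble of observed plus simulated curves, every curve `x` is
#' standardised to `z_x(t) = (x(t) - m(t)) / s(t)`, which removes both the
#' short-term calibration wiggles and the underlying trend of the null.
#' The 95% confidence envelope is the per-year 2.5th/97.5th percentile of
#' the ensemble's z-scores; observed excursions outside it are the
#' significant local deviations. Including the observed curve in the
#' reference ensemble treats all curves symmetrically, so under the null
#' the rank-based p-value is exact (and slightly conservative), at any
#' `nsim`. The global statistic is the total area outside the envelope,
#' `sum_t max(0, z_x(t) - hi(t)) + max(0, lo(t) - z_x(t))`, and the global
#' p-value is `(1 + #{simulations with statistic >= observed}) /
#' (nsim + 1)`. Years where `s(t) = 0` contribute nothing and are flagged.
#'
#' @param table a filtered `date_table` (a single set).
#' @param curve a [calcurve()].
#' @param kind null model: `"exponential"` or `"uniform"`.
#' @param nsim number of Monte-Carlo simulations (default 10000).
#' @param range `c(old, young)` cal BP analysis window.
#' @param h binning threshold in 14C years.
#' @param eps calibration probability floor.
#' @param min_run shortest run of years reported as a significant interval.
#' @param seed optional integer seed for reproducibility.
#' @return An `envelope_result`: list with `grid`, `obs_density`, `obs_z`,
#'   `lo`, `hi`, `mean`, `sd`, `pos_intervals`, `neg_intervals`,
#'   `global_stat`, `sim_stats`, `pvalue`, `nsim`, `kind`, `null`,
#'   `n_bins`, `n_dates`, `zero_sd_years`, `range`.
#' @export
model_test <- function(table, curve, kind = c("exponential", "uniform"),
                       nsim = 10000, range = c(7000, 3000), h = 200,
                       eps = 1e-5, min_run = 1, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(nsim >= 1)
  if (!is.null(seed))
    set.seed(seed)
  curve <- ensure_annual(curve)
  dens <- calibrate_table(table, curve, eps)
  bins <- make_bins(table, h)
  obs <- sum_spd(bins, dens, range)
  null <- fit_null(obs, kind)
  pool <- table$error

  # batched equivalent of nsim calls to simulate_null_spd()
  n <- obs$n_bins
  nall <- nsim * n
  years <- sample(null$grid, nall, replace = TRUE, prob = null$density)
  errs <- sample(as.numeric(pool), nall, replace = TRUE)
  cras <- sample_cra(years, errs, curve)
  G <- length(obs$grid)
  S <- matrix(0, nrow = nsim, ncol = G)
  for (s in seq_len(nsim)) {
    block <- ((s - 1L) * n + 1L):(s * n)
    S[s, ] <- spd_accumulate(cras[block], errs[block], curve, obs$grid, eps)
  }

  # mean, sd and envelope are taken over the ensemble of observed +
  # simulated curves, so every curve's statistic is measured against the
  # same reference: under the null the observed SPD is exchangeable with
  # the simulations and the rank p-value is exact (slightly conservative)
  n1 <- nsim + 1
  m <- (colSums(S) + obs$density) / n1
  msq <- (colSums(S * S) + obs$density^2) / n1
  sdev <- sqrt(pmax(0, msq - m^2) * n1 / max(1, n1 - 1))
  zero <- !is.finite(sdev) | sdev == 0
  div <- ifelse(zero, 1, sdev)

  obs_z <- (obs$density - m) / div
  obs_z[zero] <- 0
  S <- sweep(S, 2L, m, "-")
  S <- sweep(S, 2L, div, "/")
  if (any(zero))
    S[, zero] <- 0
  S <- rbind(obs_z, S)

  q <- apply(S, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  lo <- q[1L, ]
  hi <- q[2L, ]

  stats_all <- rowSums(pmax(sweep(S, 2L, hi, "-"), 0)) +
    rowSums(pmax(sweep(-S, 2L, lo, "+"), 0))
  obs_stat <- stats_all[1L]
  sim_stats <- stats_all[-1L]
  pvalue <- (1 + sum(sim_stats >= obs_stat)) / n1

  structure(
    list(grid = obs$grid, obs_density = obs$density, obs_z = obs_z,
         lo = lo, hi = hi, mean = m, sd = sdev,
         pos_intervals = runs_to_intervals(obs_z > hi & !zero, obs$grid, min_run),
         neg_intervals = runs_to_intervals(obs_z < lo & !zero, obs$grid, min_run),
         global_stat = obs_stat, sim_stats = sim_stats, pvalue = pvalue,
         nsim = nsim, kind = kind, null = null,
         n_bins = obs$n_bins, n_dates = obs$n_dates,
         zero_sd_years = obs$grid[zero], range = obs$range),
    class = "envelope_result"
  )
}

# contiguous runs of TRUE -> data.frame(start, end) in cal BP (start older);
# runs shorter than min_run years are dropped.
runs_to_intervals <- function(flag, grid, min_run = 1) {
  r <- rle(as.logical(flag))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(start = grid[starts[keep]], end = grid[ends[keep]])
}

#' @export
print.envelope_result <- function(x, ...) {
  cat(sprintf(
    "Monte-Carlo %s null-model test: %d bins (%d dates), %s-%s cal BP\n",
    x$kind, x$n_bins, x$n_dates, format(x$grid[1L]),
    format(x$grid[length(x$grid)])))
  cat(sprintf("  nsim = %d, global statistic = %.3f, p-value = %.4g\n",
              x$nsim, x$global_stat, x$pvalue))
  fmt_iv <- function(iv) if (nrow(iv) == 0L) "none" else
    paste(sprintf("%d-%d", round(iv$start), round(iv$end)), collapse = ", ")
  cat("  positive deviations (cal BP): ", fmt_iv(x$pos_intervals), "\n", sep = "")
  cat("  negative deviations (cal BP): ", fmt_iv(x$neg_intervals), "\n", sep = "")
  if (length(x$zero_sd_years))
    cat("  note: ", length(x$zero_sd_years),
        " year(s) with zero simulation sd contributed nothing\n", sep = "")
  invisible(x)
}
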