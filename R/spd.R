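#' Group dates into site-level bins
#'
#' Within each site (and set), CRAs are clustered by complete-linkage
#' agglomeration and the dendrogram cut at height `h`: every merge joins the
#' pair of clusters whose maximum pairwise CRA difference is smallest, and
#' merging stops once that difference would exceed `h`. Each resulting
#' cluster is a bin, the exchangeable unit of both significance tests;
#' binning curbs the "wealth bias" of intensively dated sites. Equal-height
#' merges are resolved toward the pair containing the smaller lowest CRA,
#' which makes the partition deterministic and independent of row order.
#'
#' `h = 0` yields one bin per distinct CRA per site; `h = Inf` one bin per
#' site.
#'
#' @param table a `date_table` (normally already filtered).
#' @param h clustering threshold in 14C years (default 200).
#' @return A `bin_set`: data frame with columns `row` (row index into
#'   `table`), `lab_id`, `site_id`, `set_label`, `bin_id`, and attribute
#'   `h`.
#' @export
make_bins <- function(table, h = 200) {
  stopifnot(inherits(table, "date_table"), is.numeric(h), length(h) == 1L,
            h >= 0)
  grp <- paste(table$set_label, table$site_id, sep = "\r")
  out <- vector("list", length(unique(grp)))
  k <- 0L
  for (g in unique(grp)) {
    rows <- which(grp == g)
    memb <- cluster_cras(table$cra[rows], h)
    # number bins by increasing minimum CRA within the site
    mins <- tapply(table$cra[rows], memb, min)
    rank <- match(memb, as.integer(names(sort(mins))))
    k <- k + 1L
    out[[k]] <- data.frame(
      row = rows,
      lab_id = table$lab_id[rows],
      site_id = table$site_id[rows],
      set_label = table$set_label[rows],
      bin_id = paste0(table$site_id[rows], "_", rank),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$row), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "h") <- h
  class(res) <- c("bin_set", "data.frame")
  res
}

# complete-linkage cut at height h for 1-d data. After sorting, clusters are
# contiguous intervals and the smallest complete-linkage distance is always
# between adjacent clusters (for intervals A < B, d(A,B) = max(B) - min(A)),
# so agglomeration reduces to repeated adjacent merges. Ties are broken
# toward the leftmost pair, i.e. the smaller lowest member CRA.
cluster_cras <- function(x, h) {
  n <- length(x)
  if (n == 1L)
    return(1L)
  ord <- order(x)
  xs <- x[ord]
  lo <- xs
  hi <- xs
  first <- seq_len(n) # index of first sorted element of each cluster
  m <- n
  repeat {
    if (m == 1L)
      break
    d <- hi[2:m] - lo[1:(m - 1L)]
    j <- which.min(d) # leftmost minimum
    if (d[j] > h)
      break
    hi[j] <- hi[j + 1L]
    lo <- lo[-(j + 1L)]
    hi <- hi[-(j + 1L)]
    first <- first[-(j + 1L)]
    m <- m - 1L
  }
  memb_sorted <- rep(seq_len(m), times = diff(c(first, n + 1L)))
  memb <- integer(n)
  memb[ord] <- memb_sorted
  memb
}

#' Pooled mean density of a bin
#'
#' The year-wise arithmetic mean of the member densities, aligned on the
#' union of their annual grids with zero fill. A bin's density sums to at
#' most one (exactly one when every member's support lies inside the grid),
#' so each bin contributes one "unit" to an SPD regardless of how many
#' dates it holds.
#'
#' @param members non-empty list of `cal_density`.
#' @return A `cal_density` (not necessarily summing to 1 after clipping).
#' @export
bin_density <- function(members) {
  if (length(members) == 0L)
    stop("bin has no member densities")
  if (length(members) == 1L)
    return(members[[1L]])
  start <- max(vapply(members, function(d) d$calbp[1L], numeric(1)))
  end <- min(vapply(members, function(d) d$calbp[length(d$calbp)], numeric(1)))
  grid <- seq(start, end, by = -1)
  acc <- numeric(length(grid))
  for (d in members)
    acc <- acc_add(acc, start, d$calbp[1L], d$prob)
  new_cal_density(grid, acc / length(members), normalised = FALSE)
}

#' Summed probability distribution of a bin set
#'
#' Year-wise sum of the pooled-mean bin densities, restricted to the
#' analysis range. Mass falling outside the range is retained by the
#' calibration but excluded here, so the total density is at most the
#' number of bins.
#'
#' @param bins a `bin_set` from [make_bins()].
#' @param densities per-date calibrated densities, indexed by table row
#'   (from [calibrate_table()]).
#' @param range `c(old, young)` cal BP analysis window.
#' @return An `spd`: list with `grid` (decreasing annual cal BP), `density`,
#'   `set_label`, `n_bins`, `n_dates`, `range`.
#' @export
sum_spd <- function(bins, densities, range = c(7000, 3000)) {
  stopifnot(inherits(bins, "bin_set"), is.list(densities),
            length(range) == 2L, range[1L] > range[2L])
  grid <- seq(range[1L], range[2L], by = -1)
  acc <- numeric(length(grid))
  groups <- split(seq_len(nrow(bins)), bins$bin_id)
  for (members in groups) {
    bd <- bin_density(densities[bins$row[members]])
    acc <- acc_add(acc, grid[1L], bd$calbp[1L], bd$prob)
  }
  labs <- unique(bins$set_label)
  structure(
    list(grid = grid, density = acc,
         set_label = if (length(labs) == 1L) labs else "all",
         n_bins = length(groups), n_dates = nrow(bins),
         range = as.numeric(range)),
    class = "spd"
  )
}

#' Rolling mean of an SPD
#'
#' Centred moving average for visual smoothing of calibration wiggles; edge
#' years are averaged over the truncated window. Even window widths are
#' rounded up to the next odd number of years so the window is centred
#' (e.g. the default 200 spans each year +/- 100). Smoothing is
#' display-only: test statistics always use the raw annual SPD.
#'
#' @param spd an `spd`.
#' @param window window width in years (default 200).
#' @return A smoothed copy of `spd`; the input is untouched.
#' @export
rolling_mean <- function(spd, window = 200) {
  stopifnot(inherits(spd, "spd"))
  if (!is.numeric(window) || length(window) != 1L || window < 1)
    stop("window must be >= 1 year")
  w <- as.integer(window)
  if (w %% 2L == 0L)
    w <- w + 1L
  half <- (w - 1L) %/% 2L
  x <- spd$density
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  a <- pmax(1L, i - half)
  b <- pmin(n, i + half)
  out <- spd
  out$density <- (cs[b + 1L] - cs[a]) / (b - a + 1L)
  attr(out, "smoothed") <- w
  out
}

#' @export
print.spd <- function(x, ...) {
  cat(sprintf(
    "SPD '%s': %s-%s cal BP, %d bins / %d dates, total density %.3f\n",
    x$set_label, format(x$grid[1L]), format(x$grid[length(x$grid)]),
    x$n_bins, x$n_dates, sum(x$density)))
  invisible(x)
}

#' Write an SPD as two-column CSV
#'
#' @param spd an `spd`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spd <- function(spd, path) {
  utils::write.csv(data.frame(calbp = spd$grid, density = spd$density),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a bin assignment table as CSV
#'
#' @param bins a `bin_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bins <- function(bins, path) {
  utils::write.csv(
    data.frame(lab_id = bins$lab_id, site_id = bins$site_id,
               set_label = bins$set_label, bin_id = bins$bin_id),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
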