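# Independent oracles and small fixture builders shared across tests.

# brute-force calibration quantile on a dense sub-annual grid; shares no
# code with the implementation's windowed/floored/cached kernel
oracle_calibrate_quantile <- function(cra, error, curve, p = 0.5,
                                      step = 0.2) {
  tt <- seq(curve$calbp[1L], curve$calbp[length(curve$calbp)], by = -step)
  mu <- stats::approx(curve$calbp, curve$mu, xout = tt)$y
  sg <- stats::approx(curve$calbp, curve$sigma, xout = tt)$y
  w <- stats::dnorm(cra, mu, sqrt(error^2 + sg^2))
  w <- w / sum(w)
  tt[which(cumsum(w) >= p)[1L]]
}

# naive complete-linkage agglomeration: full pairwise search at every step,
# ties toward the smaller lowest member value
oracle_complete_linkage <- function(x, h) {
  cl <- as.list(seq_along(x))
  repeat {
    m <- length(cl)
    if (m == 1L)
      break
    bestd <- Inf
    bestlo <- Inf
    best <- NULL
    for (i in 1:(m - 1L)) {
      for (j in (i + 1L):m) {
        d <- max(abs(outer(x[cl[[i]]], x[cl[[j]]], "-")))
        lo <- min(x[c(cl[[i]], cl[[j]])])
        if (d < bestd - 1e-9 || (abs(d - bestd) <= 1e-9 && lo < bestlo)) {
          bestd <- d
          best <- c(i, j)
          bestlo <- lo
        }
      }
    }
    if (bestd > h)
      break
    cl[[best[1L]]] <- c(cl[[best[1L]]], cl[[best[2L]]])
    cl[[best[2L]]] <- NULL
  }
  memb <- integer(length(x))
  for (k in seq_along(cl))
    memb[cl[[k]]] <- k
  memb
}

# partitions compared as sets of index sets (cluster ids are arbitrary)
same_partition <- function(a, b) {
  key <- function(memb)
    sort(unname(vapply(split(seq_along(memb), memb),
                       function(i) paste(sort(i), collapse = ","),
                       character(1))))
  identical(key(a), key(b))
}

# one-site date table from raw CRAs
site_table <- function(cras, errors = 30, site = "s1", set = "A") {
  as_date_table(data.frame(
    lab_id = paste0("L", seq_along(cras)), site_id = site, set_label = set,
    cra = cras, error = errors, stringsAsFactors = FALSE))
}

# does any interval (start older than end, cal BP) overlap the window?
any_overlap <- function(iv, window) {
  nrow(iv) > 0L && any(iv$start >= window[2L] & iv$end <= window[1L])
}
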