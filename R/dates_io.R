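#' Validate a data frame of radiocarbon determinations
#'
#' Canonical columns: `lab_id`, `site_id`, `set_label`, `cra` (14C years
#' BP), `error` (1-sigma lab error, 14C years), and the optional `delta13c`
#' (per mil), `method` (`AMS`/`conventional`/`unknown`) and `material`
#' (`terrestrial`/`marine`/`unknown`). Missing optional columns are filled
#' with `NA`/`"unknown"`. Rows violating the invariants (`error > 0`,
#' `cra > 0`, non-empty `lab_id`, `site_id`, `set_label`) raise an error
#' naming the offending rows.
#'
#' @param df a data frame.
#' @param column_map optional named character vector mapping canonical field
#'   names to the data frame's column names, e.g.
#'   `c(cra = "C14Age", error = "C14Error")`.
#' @return A `date_table` (a validated data frame).
#' @export
as_date_table <- function(df, column_map = NULL) {
  stopifnot(is.data.frame(df))
  canon <- c("lab_id", "site_id", "set_label", "cra", "error",
             "delta13c", "method", "material")
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), canon)
    if (length(bad))
      stop("unknown field(s) in column_map: ", paste(bad, collapse = ", "))
    missing_src <- setdiff(unname(column_map), names(df))
    if (length(missing_src))
      stop("column_map refers to absent column(s): ",
           paste(missing_src, collapse = ", "))
    for (f in names(column_map))
      df[[f]] <- df[[column_map[[f]]]]
  }
  mandatory <- c("lab_id", "site_id", "set_label", "cra", "error")
  absent <- setdiff(mandatory, names(df))
  if (length(absent))
    stop("unmapped mandatory column(s): ", paste(absent, collapse = ", "))

  out <- data.frame(
    lab_id = as.character(df$lab_id),
    site_id = as.character(df$site_id),
    set_label = as.character(df$set_label),
    cra = suppressWarnings(as.numeric(df$cra)),
    error = suppressWarnings(as.numeric(df$error)),
    stringsAsFactors = FALSE
  )
  out$delta13c <- if ("delta13c" %in% names(df))
    suppressWarnings(as.numeric(df$delta13c)) else NA_real_
  norm_enum <- function(x, levels) {
    x <- tolower(trimws(as.character(x)))
    x[is.na(x) | x == ""] <- "unknown"
    x[!x %in% levels] <- "unknown"
    x
  }
  out$method <- if ("method" %in% names(df)) {
    m <- tolower(trimws(as.character(df$method)))
    m[is.na(m)] <- "unknown"
    m[grepl("^conv", m)] <- "conventional"
    m[m == "ams"] <- "AMS"
    m[!m %in% c("AMS", "conventional")] <- "unknown"
    m
  } else rep("unknown", nrow(out))
  out$material <- if ("material" %in% names(df))
    norm_enum(df$material, c("terrestrial", "marine")) else
    rep("unknown", nrow(out))

  problems <- character(0)
  flag <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      problems <<- c(problems, paste0(what, " in row(s) ",
                                      paste(utils::head(i, 10L), collapse = ", ")))
  }
  flag(is.na(out$cra), "unparseable or missing cra")
  flag(is.na(out$error), "unparseable or missing error")
  flag(!is.na(out$error) & out$error <= 0, "error must be > 0")
  flag(!is.na(out$cra) & out$cra <= 0, "cra must be > 0")
  flag(is.na(out$lab_id) | out$lab_id == "", "empty lab_id")
  flag(is.na(out$site_id) | out$site_id == "", "empty site_id")
  flag(is.na(out$set_label) | out$set_label == "", "empty set_label")
  if (length(problems))
    stop("invalid date table: ", paste(problems, collapse = "; "))

  class(out) <- c("date_table", "data.frame")
  out
}

#' Read a table of radiocarbon determinations
#'
#' @param path delimited text file with a header row.
#' @param column_map see [as_date_table()].
#' @param sep field separator (`","` default, `"\t"` selectable).
#' @return A `date_table`.
#' @export
read_dates <- function(path, column_map = NULL, sep = ",") {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("date table file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  as_date_table(df, column_map)
}

#' Write a date table
#'
#' @param table a `date_table`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_dates <- function(table, path, sep = ",") {
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Inclusion criteria for radiocarbon dates
#'
#' The default criteria retain AMS-dated, non-marine samples whose measured
#' delta-13C does not exceed -24 per mil (samples above that threshold are
#' potentially affected by a marine reservoir effect) and whose CRA lies
#' inside 7,500-2,500 14C years BP. Missing delta-13C is not grounds for
#' exclusion: only measured values above the threshold are dropped (a
#' stricter -26 per mil variant is available through `delta13c_max`). The
#' CRA window is inclusive at both ends; the delta-13C rule is a strict
#' inequality.
#'
#' @param ams_only drop determinations not flagged as AMS (includes
#'   `unknown` methods).
#' @param exclude_marine drop marine-material samples.
#' @param delta13c_max exclude measured `delta13c > delta13c_max` (per mil).
#'   `NA` disables the rule.
#' @param cra_window `c(max, min)` inclusive window in 14C years BP; `NULL`
#'   disables the rule.
#' @return A `filter_criteria` object.
#' @export
filter_criteria <- function(ams_only = TRUE, exclude_marine = TRUE,
                            delta13c_max = -24,
                            cra_window = c(7500, 2500)) {
  if (!is.null(cra_window)) {
    stopifnot(length(cra_window) == 2L, is.numeric(cra_window))
    if (!(cra_window[1L] > cra_window[2L]))
      stop("cra_window must be c(max, min) with max > min")
  }
  structure(list(ams_only = isTRUE(ams_only),
                 exclude_marine = isTRUE(exclude_marine),
                 delta13c_max = delta13c_max,
                 cra_window = cra_window),
            class = "filter_criteria")
}

#' Apply inclusion criteria to a date table
#'
#' Returns rows passing all active criteria, order preserved. The result
#' carries a per-set filter report (see [filter_report()]) counting, for
#' each `set_label`, the input rows, the retained rows, and the rows failing
#' each individual rule (a row failing several rules is counted under each).
#' Filtering is idempotent.
#'
#' @param table a `date_table`.
#' @param criteria a [filter_criteria()].
#' @return The filtered `date_table` with a `"filter_report"` attribute.
#' @export
filter_dates <- function(table, criteria = filter_criteria()) {
  stopifnot(inherits(table, "date_table"), inherits(criteria, "filter_criteria"))
  n <- nrow(table)
  fail_ams <- if (criteria$ams_only) table$method != "AMS" else logical(n)
  fail_marine <- if (criteria$exclude_marine)
    table$material == "marine" else logical(n)
  fail_d13c <- if (!is.null(criteria$delta13c_max) &&
                   !is.na(criteria$delta13c_max))
    !is.na(table$delta13c) & table$delta13c > criteria$delta13c_max else
    logical(n)
  fail_window <- if (!is.null(criteria$cra_window))
    table$cra > criteria$cra_window[1L] | table$cra < criteria$cra_window[2L]
  else logical(n)
  keep <- !(fail_ams | fail_marine | fail_d13c | fail_window)

  labs <- unique(table$set_label)
  report <- lapply(labs, function(l) {
    i <- table$set_label == l
    list(input = sum(i), retained = sum(i & keep),
         dropped_by_rule = list(
           ams = sum(i & fail_ams), marine = sum(i & fail_marine),
           delta13c = sum(i & fail_d13c), cra_window = sum(i & fail_window)))
  })
  names(report) <- labs

  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("date_table", "data.frame")
  attr(out, "filter_report") <- report
  out
}

#' Bind date tables row-wise
#'
#' @param ... `date_table`s (e.g. the regions of a multi-set analysis).
#' @return A single `date_table`.
#' @export
bind_dates <- function(...) {
  parts <- lapply(list(...), function(x) {
    stopifnot(inherits(x, "date_table"))
    as.data.frame(x)
  })
  cols <- Reduce(intersect, lapply(parts, names)) # extras kept if shared
  out <- do.call(rbind, lapply(parts, `[`, cols))
  rownames(out) <- NULL
  class(out) <- c("date_table", "data.frame")
  out
}

#' Retrieve the per-set filter report of a filtered table
#'
#' @param table output of [filter_dates()].
#' @return Named list, one entry per `set_label`, with `input`, `retained`
#'   and `dropped_by_rule` counts.
#' @export
filter_report <- function(table) {
  attr(table, "filter_report")
}
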