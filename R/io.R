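#' Column mapping for delimited record files
#'
#' Describes how CSV columns map onto the required fields. `day` may point at
#' an integer study-day column (passed through unchanged) or a calendar-date
#' column; dates are converted by setting the earliest date to day 1 and
#' counting elapsed days.
#'
#' @param x,y,day,outcome column names (or integer positions) in the file.
#' @param covariates character vector of covariate columns (may be empty).
#' @param date_format `strptime` format for date parsing (default ISO
#'   `"%Y-%m-%d"`); ignored for numeric day columns.
#' @export
column_mapping <- function(x = "x", y = "y", day = "day", outcome = "outcome",
                           covariates = "age", date_format = "%Y-%m-%d") {
  structure(list(x = x, y = y, day = day, outcome = outcome,
                 covariates = covariates, date_format = date_format),
            class = "ed_column_mapping")
}

resolve_col <- function(df, col, what) {
  if (is.numeric(col)) {
    if (col < 1 || col > ncol(df))
      stop("no column at position ", col, " for field '", what, "'", call. = FALSE)
    return(df[[col]])
  }
  if (!col %in% names(df))
    stop("missing column '", col, "' for field '", what, "'", call. = FALSE)
  df[[col]]
}

#' Read case-control records from a delimited file
#'
#' Reads a CSV of individual records, resolves columns through a
#' [column_mapping()], converts calendar dates to integer study days (day 1 =
#' earliest date in the file), validates, and returns a day-sorted
#' [ed_dataset()]. Malformed rows are rejected with errors naming the
#' offending file line (header = line 1).
#'
#' @param path CSV file path.
#' @param mapping a [column_mapping()].
#' @export
read_records <- function(path, mapping = column_mapping()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  x <- resolve_col(df, mapping$x, "x")
  y <- resolve_col(df, mapping$y, "y")
  dayraw <- resolve_col(df, mapping$day, "day")
  outcome <- resolve_col(df, mapping$outcome, "outcome")
  bad <- which(!(outcome %in% c(0, 1, "0", "1")))
  if (length(bad))
    stop("non-binary outcome value(s) at file line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  if (is.numeric(dayraw)) {
    day <- dayraw
  } else {
    dates <- as.Date(as.character(dayraw), format = mapping$date_format)
    bad <- which(is.na(dates))
    if (length(bad))
      stop("unparseable date(s) at file line(s): ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    day <- as.integer(dates - min(dates)) + 1L
  }
  out <- data.frame(x = as.numeric(x), y = as.numeric(y), day = day,
                    outcome = as.integer(as.numeric(outcome)))
  for (cv in mapping$covariates) {
    v <- resolve_col(df, cv, cv)
    nm <- if (is.numeric(cv)) names(df)[cv] else cv
    out[[nm]] <- as.numeric(v)
  }
  cvn <- vapply(mapping$covariates, function(cv)
    if (is.numeric(cv)) names(df)[cv] else cv, character(1))
  ed_dataset(out, covariates = unname(cvn))
}

#' Write records (and optional generative truth) to disk
#'
#' The dataset goes to CSV with the standard columns (`x`, `y`, `day`,
#' `outcome`, covariates); if the dataset carries a synthetic `truth`
#' attribute and `truth_path` is given, the generative description is written
#' as a JSON sidecar. Files are written to a temporary name and renamed, so no
#' partial file survives an error.
#'
#' @param data an [ed_dataset()].
#' @param path output CSV path.
#' @param truth_path optional JSON sidecar path for the generative truth.
#' @export
write_records <- function(data, path, truth_path = NULL) {
  stopifnot(inherits(data, "ed_dataset"))
  atomic_write(path, function(tmp)
    utils::write.csv(as.data.frame(data), tmp, row.names = FALSE))
  truth <- attr(data, "truth")
  if (!is.null(truth_path) && !is.null(truth)) {
    cfg <- truth$config
    cfg$hotspots <- lapply(cfg$hotspots, unclass)
    payload <- list(config = unclass(cfg), p = truth$p)
    atomic_write(truth_path, function(tmp)
      jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA))
  }
  invisible(path)
}

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path, call. = FALSE)
  ok <- TRUE
  invisible(path)
}

#' Export an OR map (or a whole series) to CSV
#'
#' One row per grid point: `window_id`, `x`, `y`, `or`, `rank_pct`, `flag`.
#' Masked points are omitted. For an `ed_stmap`, all windows are stacked.
#'
#' @param x an `ed_ormap` or `ed_stmap`.
#' @param path output CSV path.
#' @export
write_ormap <- function(x, path) {
  df <- ormap_frame(x)
  atomic_write(path, function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE))
  invisible(path)
}

ormap_frame <- function(x) {
  if (inherits(x, "ed_stmap"))
    return(do.call(rbind, lapply(x$maps, ormap_frame)))
  stopifnot(inherits(x, "ed_ormap"))
  keep <- x$grid$active
  data.frame(window_id = x$window_id,
             x = x$grid$points$x[keep], y = x$grid$points$y[keep],
             or = x$or[keep], rank_pct = x$rank_pct[keep],
             flag = x$flag[keep])
}
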