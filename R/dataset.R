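#' Emergency-department case-control dataset
#'
#' Validates and day-sorts individual-level records: planar coordinates,
#' integer study day (day 1 = first record), a binary case/control outcome and
#' numeric covariates. Coordinates are used as given — inputs are expected in
#' a planar projection (or in degrees knowingly treated as planar); no internal
#' rescaling is applied, so any anisotropy between axes is the caller's
#' responsibility.
#'
#' @param data data.frame with columns `x`, `y`, `day`, `outcome` and the
#'   covariate columns named in `covariates`.
#' @param covariates character vector of covariate column names (default
#'   `"age"` when present, otherwise none).
#' @return An object of class `ed_dataset` (a sorted data.frame with a
#'   `covariates` attribute).
#' @examples
#' d <- ed_dataset(data.frame(x = runif(5), y = runif(5), day = c(2, 1, 1, 3, 2),
#'                            outcome = c(0, 1, 0, 0, 1), age = 20:24))
#' d$day  # sorted
#' @export
ed_dataset <- function(data, covariates = intersect("age", names(data))) {
  stopifnot(is.data.frame(data))
  need <- c("x", "y", "day", "outcome", covariates)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(data) == 0L) stop("dataset is empty", call. = FALSE)
  for (cc in c("x", "y", "day", covariates)) {
    if (!is.numeric(data[[cc]]) || anyNA(data[[cc]]) || any(!is.finite(data[[cc]])))
      stop("column '", cc, "' must be finite numeric", call. = FALSE)
  }
  if (!all(data$outcome %in% c(0, 1)))
    stop("outcome must be 0 (control) or 1 (case); offending row(s): ",
         paste(utils::head(which(!data$outcome %in% c(0, 1)), 5), collapse = ", "),
         call. = FALSE)
  day <- as.integer(round(data$day))
  if (any(abs(day - data$day) > 1e-8) || any(day < 1L))
    stop("day must be an integer >= 1 (day 1 = first record)", call. = FALSE)
  data$day <- day
  data$outcome <- as.integer(data$outcome)
  ord <- order(data$day)            # stable sort, preserves within-day order
  out <- data[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, covariates = covariates, class = c("ed_dataset", "data.frame"))
}

#' @export
print.ed_dataset <- function(x, ...) {
  cat("ED case-control dataset: ", nrow(x), " records, days ",
      x$day[1], "-", x$day[nrow(x)], ", ", sum(x$outcome), " cases / ",
      sum(1 - x$outcome), " controls\n", sep = "")
  cat("covariates:", if (length(attr(x, "covariates")))
    paste(attr(x, "covariates"), collapse = ", ") else "(none)", "\n")
  invisible(x)
}

ed_covariates <- function(data) attr(data, "covariates") %||% character()

`%||%` <- function(a, b) if (is.null(a)) b else a

# covariate matrix (n x p, possibly 0 columns)
ed_covmat <- function(data) {
  cv <- ed_covariates(data)
  as.matrix(as.data.frame(data)[, cv, drop = FALSE])
}

# smoothing coordinate matrix for "space" or "time"
ed_coords <- function(data, smooth = c("space", "time")) {
  smooth <- match.arg(smooth)
  if (smooth == "space") cbind(x = data$x, y = data$y)
  else cbind(day = as.numeric(data$day))
}
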