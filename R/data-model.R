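#' Validate a right-censored survival data frame
#'
#' Checks the invariants every downstream function in the package relies on:
#' one row per subject; a strictly positive observation time; an event
#' indicator that is exactly 0 (censored) or 1 (event observed); and numeric,
#' finite covariate columns with unique names. Each violated invariant raises
#' its own error naming the offending rows or columns.
#'
#' @param data A data frame with one row per subject.
#' @param time_col Name of the observation-time column. Default `"time"`.
#' @param event_col Name of the event-indicator column. Default `"event"`.
#' @return The validated data as a tibble with the time and event columns
#'   first, covariate column order preserved. Invisible on success so the
#'   function can be used as a pipeline assertion.
#' @examples
#' d <- tibble::tibble(time = c(2, 5, 1), event = c(1, 0, 1),
#'                     x1 = rnorm(3), x2 = rnorm(3))
#' validate_survival_data(d)
#' @export
validate_survival_data <- function(data, time_col = "time", event_col = "event") {
  if (!is.data.frame(data)) {
    stop("`data` must be a data frame", call. = FALSE)
  }
  dup <- unique(names(data)[duplicated(names(data))])
  if (length(dup) > 0) {
    stop("duplicate covariate name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(c(time_col, event_col), names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }

  time <- data[[time_col]]
  event <- data[[event_col]]
  if (!is.numeric(time)) {
    stop("time column `", time_col, "` must be numeric", call. = FALSE)
  }
  bad_time <- which(!is.finite(time) | time <= 0)
  if (length(bad_time) > 0) {
    stop("non-positive time in row(s): ",
         paste(utils::head(bad_time, 5), collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(event)) {
    stop("event column `", event_col, "` must be numeric", call. = FALSE)
  }
  bad_event <- which(!(event %in% c(0, 1)))
  if (length(bad_event) > 0) {
    stop("event indicator outside {0,1} in row(s): ",
         paste(utils::head(bad_event, 5), collapse = ", "), call. = FALSE)
  }

  cov_names <- setdiff(names(data), c(time_col, event_col))
  if (length(cov_names) < 1) {
    stop("at least one covariate column is required", call. = FALSE)
  }
  for (nm in cov_names) {
    col <- data[[nm]]
    if (!is.numeric(col)) {
      stop("covariate `", nm, "` is not numeric", call. = FALSE)
    }
    bad <- which(!is.finite(col))
    if (length(bad) > 0) {
      stop("non-finite value in covariate `", nm, "`, row(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }

  invisible(data[, c(time_col, event_col, cov_names)])
}

#' Read a censored survival dataset from a CSV file
#'
#' Expects a comma-separated UTF-8 file with a header row. Besides the named
#' time and event columns, every remaining column is treated as a numeric
#' covariate; non-numeric cells, non-positive times and event values outside
#' \{0,1\} are rejected with errors naming the offending row or column.
#'
#' @inheritParams validate_survival_data
#' @param path Path to the CSV file.
#' @return A validated tibble with columns `time_col`, `event_col`, then the
#'   covariates in file order.
#' @seealso [write_survival_csv()] for the inverse operation.
#' @export
read_survival_csv <- function(path, time_col = "time", event_col = "event") {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c(time_col, event_col), names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cov_names <- setdiff(names(data), c(time_col, event_col))
  for (nm in cov_names) {
    if (!is.numeric(data[[nm]])) {
      # re-parse to locate the first offending cell for the error message
      raw <- suppressWarnings(as.numeric(as.character(data[[nm]])))
      bad <- which(is.na(raw) & !is.na(data[[nm]]))
      stop("non-numeric covariate cell in column `", nm, "`, row ",
           if (length(bad) > 0) bad[1] else "?", call. = FALSE)
    }
  }
  out <- validate_survival_data(data, time_col = time_col, event_col = event_col)
  tibble::as_tibble(out)
}

#' Write a survival dataset to CSV
#'
#' Writes the schema read back by [read_survival_csv()]: header row, time and
#' event columns first, covariates after, full double precision so that a
#' write-then-read round trip reproduces the dataset.
#'
#' @inheritParams validate_survival_data
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(data, path, time_col = "time", event_col = "event") {
  data <- validate_survival_data(data, time_col = time_col, event_col = event_col)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

# Split a validated survival data frame into the pieces the estimators use:
# numeric time/event vectors, the covariate matrix and its column names.
surv_parts <- function(data, time_col = "time", event_col = "event") {
  data <- validate_survival_data(data, time_col = time_col, event_col = event_col)
  cov_names <- setdiff(names(data), c(time_col, event_col))
  X <- as.matrix(data[, cov_names, drop = FALSE])
  storage.mode(X) <- "double"
  list(
    time = as.double(data[[time_col]]),
    event = as.integer(data[[event_col]]),
    X = X,
    covariate_names = cov_names,
    n = nrow(X),
    p = ncol(X)
  )
}
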