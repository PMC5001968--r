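#' Hyperparameter sensitivity sweep
#'
#' Re-runs the 5x2 cross-validation harness at each value of a grid over one
#' ensemble hyperparameter — the subspace size `r` (useful range roughly
#' `sqrt(p)/5` to `5 sqrt(p)`, clipped to `[1, p - 1]`) or the variable-subset
#' size `M` (clipped to `[1, r]`) — and records the mean C-index, ready for a
#' sensitivity curve. By default the sweep runs on simulated
#' proportional-hazards data so it needs no external files; pass `data` to
#' sweep on your own dataset.
#'
#' @param data A survival data frame, or `NULL` to simulate one.
#' @param parameter `"r"` or `"M"`.
#' @param grid Numeric vector of hyperparameter values to try.
#' @param time_col,event_col Outcome column names.
#' @param n_trees Ensemble size per fit (default 100; sweeps refit
#'   `10 * length(grid)` forests).
#' @param n_reps CV replications (default 5).
#' @param seed Integer seed (shared across grid values so splits match).
#' @param sim_args Named list of arguments for [simulate_survival_data()]
#'   when `data` is `NULL`.
#' @param ... Further fixed hyperparameters passed to [rrotsf()].
#' @return A tibble of class `rrotsf_sweep` with columns `parameter`,
#'   `value`, `mean_cindex`, `sd_cindex`.
#' @export
run_sensitivity_sweep <- function(data = NULL,
                                  parameter = c("r", "M"),
                                  grid,
                                  time_col = "time",
                                  event_col = "event",
                                  n_trees = 100,
                                  n_reps = 5,
                                  seed = 1L,
                                  sim_args = list(),
                                  ...) {
  parameter <- match.arg(parameter)
  stopifnot(length(grid) >= 1)
  if (is.null(data)) {
    defaults <- list(n = 200, p = 400, n_informative = 10, beta = 1,
                     target_censoring = 0.3, seed = seed)
    data <- do.call(simulate_survival_data, utils::modifyList(defaults, sim_args))
  }
  data <- validate_survival_data(data, time_col = time_col,
                                 event_col = event_col)
  p <- length(setdiff(names(data), c(time_col, event_col)))
  # n/2 rows are available per CV training fold
  grid <- as.integer(round(grid))
  if (parameter == "r") {
    bad <- grid[grid < 1 | grid > p - 1]
    if (length(bad) > 0) {
      stop("r grid value(s) outside [1, p - 1] = [1, ", p - 1, "]: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  } else {
    extra <- list(...)
    r_used <- if (!is.null(extra$r)) extra$r else default_r(p)
    bad <- grid[grid < 1 | grid > r_used]
    if (length(bad) > 0) {
      stop("M grid value(s) outside [1, r] = [1, ", r_used, "]: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  rows <- purrr::map(grid, function(value) {
    args <- c(list(n_trees = n_trees), list(...))
    args[[parameter]] <- value
    lrn <- list(rrotsf = do.call(rrotsf_learner, args))
    cv <- five_by_two_cv(data, lrn, time_col = time_col,
                         event_col = event_col, n_reps = n_reps, seed = seed)
    tibble::tibble(parameter = parameter, value = value,
                   mean_cindex = mean(cv$cindex),
                   sd_cindex = stats::sd(cv$cindex))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("rrotsf_sweep", class(out))
  out
}

#' Sensitivity-sweep curve
#'
#' @param object A [run_sensitivity_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object: mean C-index against the swept hyperparameter,
#'   with a one-standard-deviation ribbon over the CV cells.
#' @export
autoplot.rrotsf_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$mean_cindex)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_cindex - .data$sd_cindex,
      ymax = .data$mean_cindex + .data$sd_cindex), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = object$parameter[1], y = "mean C-index (5x2 CV)") +
    ggplot2::theme_minimal()
}
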