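#' Harrell's concordance index
#'
#' The fraction of valid subject pairs whose predicted risk ordering agrees
#' with their survival ordering. A pair is valid when the ordering of the two
#' survival experiences is determinable under right censoring: the smaller
#' observed time must be an event; pairs with equal observed times are valid
#' only when exactly one of the two is an event (that subject is treated as
#' failing first). For a valid pair in which subject 2 fails before subject 1
#' survives longer, the pair scores 1 when the risk of the earlier failure is
#' higher (`risk2 > risk1`), 0.5 when the two risks are tied, and 0
#' otherwise; the index is the total score over the number of valid pairs.
#' A value of 1 is perfect ranking; 0.5 is random guessing (and is attained
#' exactly when all predictions are tied).
#'
#' @param time Observed survival/censoring times.
#' @param event Event indicators (1 = event observed, 0 = censored).
#' @param risk Predicted risk scores; higher risk must mean shorter predicted
#'   survival (e.g. mortality from [predict_mortality()]).
#' @return The concordance index in `[0, 1]`.
#' @examples
#' concordance_index(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)) # 1
#' @export
concordance_index <- function(time, event, risk) {
  n <- length(time)
  stopifnot(length(event) == n, length(risk) == n)
  if (n < 2) stop("need at least two subjects", call. = FALSE)
  event <- as.integer(event)
  # valid[i, j]: subject i fails strictly before subject j's (possibly
  # censored) time, or at the same observed time with only i an event.
  # Each valid pair appears exactly once with i as the earlier failure.
  dt <- outer(time, time, "<")
  eq <- outer(time, time, "==")
  ev_i <- matrix(event == 1, n, n)
  ev_j <- t(ev_i)
  valid <- (dt & ev_i) | (eq & ev_i & !ev_j)
  n_pairs <- sum(valid)
  if (n_pairs == 0) {
    stop("no valid pairs: all subjects censored or degenerate times",
         call. = FALSE)
  }
  gt <- outer(risk, risk, ">")
  te <- outer(risk, risk, "==")
  s <- sum(valid & gt) + 0.5 * sum(valid & te)
  s / n_pairs
}

#' Model adapters for the cross-validation harness
#'
#' The CV and comparison machinery is model-agnostic: a learner is a list
#' with a `fit(data, time_col, event_col)` function returning any fitted
#' object and a `predict(object, newdata)` function returning one risk score
#' per row (higher = shorter predicted survival).
#'
#' * `rrotsf_learner()` wraps [rrotsf()] with fixed hyperparameters.
#' * `oracle_learner(beta)` scores by a known linear predictor — useful as a
#'   ceiling on simulated data where the generating coefficients are known.
#' * `random_learner()` scores by fresh uniform noise — a floor at C = 0.5.
#'
#' @param ... Hyperparameters passed on to [rrotsf()] (e.g. `n_trees`, `r`,
#'   `M`). Per-fit seeds are supplied by the harness.
#' @return A learner list with elements `fit` and `predict`.
#' @export
rrotsf_learner <- function(...) {
  args <- list(...)
  list(
    fit = function(data, time_col = "time", event_col = "event", seed = 1L) {
      do.call(rrotsf, c(list(data = data, time_col = time_col,
                             event_col = event_col, seed = seed, oob = FALSE),
                        args))
    },
    predict = function(object, newdata) predict_mortality(object, newdata)
  )
}

#' @rdname rrotsf_learner
#' @param beta Numeric coefficient vector, one entry per covariate column.
#' @export
oracle_learner <- function(beta) {
  force(beta)
  list(
    fit = function(data, time_col = "time", event_col = "event", seed = 1L) {
      cov_names <- setdiff(names(data), c(time_col, event_col))
      list(beta = beta, cov_names = cov_names)
    },
    predict = function(object, newdata) {
      X <- as.matrix(newdata[, object$cov_names, drop = FALSE])
      as.vector(X %*% object$beta)
    }
  )
}

#' @rdname rrotsf_learner
#' @export
random_learner <- function() {
  list(
    fit = function(data, time_col = "time", event_col = "event", seed = 1L) {
      list(seed = seed)
    },
    predict = function(object, newdata) {
      stats::runif(nrow(newdata))
    }
  )
}

#' Five replications of two-fold cross-validation
#'
#' The evaluation protocol for comparing survival models: the data are split
#' at random into two halves; each half serves once as the training set and
#' once as the test set, yielding two C-index values; the split is redrawn
#' `n_reps` times (default 5), for 10 values per model. All models see
#' identical splits within a run, so the resulting table supports paired
#' rank-based comparisons.
#'
#' @param data A survival data frame.
#' @param learners A named list of learners (see [rrotsf_learner()]).
#' @param time_col,event_col Outcome column names.
#' @param n_reps Number of replications (default 5).
#' @param seed Integer seed controlling the splits and per-fit learner seeds.
#' @return A tibble with columns `model`, `replication`, `fold`, `cindex` —
#'   one row per model per replication per fold.
#' @export
five_by_two_cv <- function(data, learners,
                           time_col = "time", event_col = "event",
                           n_reps = 5, seed = 1L) {
  data <- validate_survival_data(data, time_col = time_col,
                                 event_col = event_col)
  n <- nrow(data)
  if (n < 20) stop("need at least 20 subjects for 2-fold CV", call. = FALSE)
  if (is.null(names(learners)) || any(names(learners) == "")) {
    stop("`learners` must be a named list", call. = FALSE)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)

  out <- vector("list", n_reps * 2 * length(learners))
  k <- 0
  for (rep in seq_len(n_reps)) {
    set.seed(rep_seeds[rep])
    perm <- sample.int(n, n)
    half1 <- perm[seq_len(n %/% 2)]
    half2 <- perm[(n %/% 2 + 1):n]
    fit_seeds <- sample.int(.Machine$integer.max, 2 * length(learners))
    fs <- 0
    for (fold in 1:2) {
      train_rows <- if (fold == 1) half1 else half2
      test_rows <- if (fold == 1) half2 else half1
      train <- data[train_rows, , drop = FALSE]
      test <- data[test_rows, , drop = FALSE]
      for (mname in names(learners)) {
        fs <- fs + 1
        lrn <- learners[[mname]]
        fit <- lrn$fit(train, time_col = time_col, event_col = event_col,
                       seed = fit_seeds[fs])
        risk <- lrn$predict(fit, test)
        ci <- tryCatch(
          concordance_index(test[[time_col]], test[[event_col]], risk),
          error = function(e) {
            stop("replication ", rep, ", fold ", fold, ": ",
                 conditionMessage(e), call. = FALSE)
          }
        )
        k <- k + 1
        out[[k]] <- tibble::tibble(model = mname, replication = rep,
                                   fold = fold, cindex = ci)
      }
    }
  }
  dplyr::bind_rows(out)
}
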