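#' Friedman rank sum test over model scores
#'
#' Ranks the models within each run (rank 1 = best, i.e. largest C-index;
#' ties receive average ranks) and tests the null hypothesis that all models
#' perform alike with the classical Friedman chi-square statistic
#' \deqn{\chi^2_F = \frac{12N}{K(K+1)} \sum_k \left(\bar R_k -
#' \frac{K+1}{2}\right)^2,}
#' referred to a chi-square distribution with `K - 1` degrees of freedom.
#' With every row constant the statistic is 0 and the p-value 1.
#'
#' @param scores A numeric matrix (or data frame) of scores, one row per run
#'   and one named column per model; larger score = better model.
#' @return A list of class `friedman_ranks`: `ranks` (runs x K matrix),
#'   `mean_ranks`, `statistic`, `p.value`, `n_runs`, `k`.
#' @export
friedman_rank_test <- function(scores) {
  scores <- as.matrix(scores)
  n_runs <- nrow(scores)
  k <- ncol(scores)
  if (n_runs < 2 || k < 2) {
    stop("need at least 2 runs and 2 models", call. = FALSE)
  }
  ranks <- t(apply(scores, 1, function(row) rank(-row)))
  colnames(ranks) <- colnames(scores)
  mean_ranks <- colMeans(ranks)
  statistic <- 12 * n_runs / (k * (k + 1)) * sum((mean_ranks - (k + 1) / 2)^2)
  p.value <- stats::pchisq(statistic, df = k - 1, lower.tail = FALSE)
  structure(
    list(ranks = ranks, mean_ranks = mean_ranks, statistic = statistic,
         p.value = p.value, n_runs = n_runs, k = k),
    class = "friedman_ranks"
  )
}

#' @export
print.friedman_ranks <- function(x, ...) {
  cat("Friedman rank sum test:", x$k, "models,", x$n_runs, "runs\n")
  cat("  chi-square =", format(x$statistic, digits = 5),
      " df =", x$k - 1, " p =", format(x$p.value, digits = 4), "\n")
  cat("  mean ranks:",
      paste(names(x$mean_ranks), format(x$mean_ranks, digits = 3),
            collapse = ", "), "\n")
  invisible(x)
}

#' Nemenyi post-hoc test on mean ranks
#'
#' Pairwise p-values from the studentized-range approximation: for models
#' `a`, `b` with mean-rank difference `d`, the standardized statistic is
#' `d / sqrt(K(K+1)/(6N)) * sqrt(2)` referred to the studentized range
#' distribution with `K` groups and infinite degrees of freedom. Two models
#' whose mean-rank difference exceeds the critical difference
#' `CD = q_alpha sqrt(K(K+1)/(6N))` are declared different at level alpha
#' (see [nemenyi_critical_difference()]).
#'
#' @param ranks A runs x K rank matrix (e.g. `$ranks` from
#'   [friedman_rank_test()]), or a `friedman_ranks` object.
#' @return A symmetric K x K matrix of p-values with unit diagonal.
#' @export
nemenyi_posthoc <- function(ranks) {
  if (inherits(ranks, "friedman_ranks")) ranks <- ranks$ranks
  ranks <- as.matrix(ranks)
  n_runs <- nrow(ranks)
  k <- ncol(ranks)
  if (n_runs < 2 || k < 2) {
    stop("need at least 2 runs and 2 models", call. = FALSE)
  }
  mean_ranks <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n_runs))
  p <- matrix(1, k, k, dimnames = list(colnames(ranks), colnames(ranks)))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      q <- abs(mean_ranks[a] - mean_ranks[b]) / se * sqrt(2)
      pv <- stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
      p[a, b] <- pv
      p[b, a] <- pv
    }
  }
  p
}

#' @rdname nemenyi_posthoc
#' @param k Number of models.
#' @param n_runs Number of runs (rank vectors).
#' @param alpha Significance level (default 0.05).
#' @return `nemenyi_critical_difference()`: the minimum mean-rank difference
#'   significant at `alpha`.
#' @export
nemenyi_critical_difference <- function(k, n_runs, alpha = 0.05) {
  q_alpha <- stats::qtukey(1 - alpha, nmeans = k, df = Inf) / sqrt(2)
  q_alpha * sqrt(k * (k + 1) / (6 * n_runs))
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided p-value for a location difference between two score samples.
#' Uses exact enumeration when both samples have at most 10 observations and
#' the pooled values contain no ties, otherwise the normal approximation with
#' tie-corrected variance (no continuity correction). Used to resolve model
#' pairs the Nemenyi test leaves undecided.
#'
#' @param scores_a,scores_b Numeric score vectors (need not be equal length).
#' @return The two-sided p-value.
#' @export
wilcoxon_pairwise <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) >= 1, length(scores_b) >= 1)
  has_ties <- anyDuplicated(c(scores_a, scores_b)) > 0
  exact <- length(scores_a) <= 10 && length(scores_b) <= 10 && !has_ties
  suppressWarnings(
    stats::wilcox.test(scores_a, scores_b, alternative = "two.sided",
                       exact = exact, correct = FALSE)$p.value
  )
}

#' Rank-based comparison report over a cross-validation table
#'
#' Implements the escalation protocol for comparing survival models over
#' 5x2-CV results, possibly across several datasets: (1) mean C-index per
#' model (and per dataset when a `dataset` column is present); (2) models
#' ranked within every run — a run is one (dataset, replication, fold) cell —
#' with ties averaged; (3) the Friedman omnibus test on the pooled rank
#' matrix; (4) the Nemenyi post-hoc pairwise p-matrix; (5) a two-sample
#' Wilcoxon rank-sum test on the raw C-index samples for every pair the
#' Nemenyi test leaves unresolved at `alpha`. With a single model only the
#' means are reported.
#'
#' @param cv_results A tibble as returned by [five_by_two_cv()] (columns
#'   `model`, `replication`, `fold`, `cindex`, optionally `dataset`); the
#'   model x run grid must be complete.
#' @param alpha Significance level used for the escalation (default 0.05).
#' @return An object of class `rrotsf_comparison`: mean C-index table, rank
#'   matrix, Friedman result, Nemenyi and Wilcoxon p-matrices, and a pairwise
#'   decision table (see [tidy.rrotsf_comparison()]).
#' @export
build_comparison_report <- function(cv_results, alpha = 0.05) {
  needed <- c("model", "replication", "fold", "cindex")
  missing_cols <- setdiff(needed, names(cv_results))
  if (length(missing_cols) > 0) {
    stop("cv_results is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cv_results <- tibble::as_tibble(cv_results)
  if (!"dataset" %in% names(cv_results)) {
    cv_results$dataset <- "data"
  }
  if (any(!is.finite(cv_results$cindex)) ||
      any(cv_results$cindex < 0 | cv_results$cindex > 1)) {
    stop("cindex values must lie in [0, 1]", call. = FALSE)
  }

  models <- unique(cv_results$model)
  k <- length(models)

  wide <- tidyr::pivot_wider(cv_results, names_from = "model",
                             values_from = "cindex")
  score_cols <- as.matrix(wide[, models, drop = FALSE])
  if (anyNA(score_cols)) {
    bad <- wide[!stats::complete.cases(score_cols),
                c("dataset", "replication", "fold")]
    stop("incomplete model x run grid; missing cells:\n",
         paste(utils::capture.output(print(as.data.frame(bad))),
               collapse = "\n"), call. = FALSE)
  }

  mean_ci <- cv_results |>
    dplyr::group_by(.data$dataset, .data$model) |>
    dplyr::summarise(mean_cindex = mean(.data$cindex), .groups = "drop")

  if (k == 1) {
    return(structure(
      list(mean_ci = mean_ci, models = models, ranks = NULL, friedman = NULL,
           nemenyi = NULL, wilcoxon = NULL, decisions = NULL, alpha = alpha,
           note = "single model: rank-based tests skipped"),
      class = "rrotsf_comparison"
    ))
  }

  friedman <- friedman_rank_test(score_cols)
  nemenyi <- nemenyi_posthoc(friedman$ranks)
  wilcoxon <- matrix(NA_real_, k, k, dimnames = list(models, models))
  diag(wilcoxon) <- 1
  decisions <- list()
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      pw <- wilcoxon_pairwise(score_cols[, a], score_cols[, b])
      wilcoxon[a, b] <- pw
      wilcoxon[b, a] <- pw
      p_nem <- nemenyi[a, b]
      resolved_by <- if (p_nem < alpha) "nemenyi" else "wilcoxon"
      p_final <- if (p_nem < alpha) p_nem else pw
      decisions[[length(decisions) + 1]] <- tibble::tibble(
        model_a = models[a], model_b = models[b],
        mean_rank_a = unname(friedman$mean_ranks[a]),
        mean_rank_b = unname(friedman$mean_ranks[b]),
        p_nemenyi = p_nem, p_wilcoxon = pw,
        resolved_by = resolved_by, p_final = p_final,
        significant = p_final < alpha
      )
    }
  }

  structure(
    list(mean_ci = mean_ci, models = models, ranks = friedman$ranks,
         friedman = friedman, nemenyi = nemenyi, wilcoxon = wilcoxon,
         decisions = dplyr::bind_rows(decisions), alpha = alpha, note = NULL),
    class = "rrotsf_comparison"
  )
}

#' @export
print.rrotsf_comparison <- function(x, ...) {
  cat("Model comparison report\n")
  print(tidyr::pivot_wider(x$mean_ci, names_from = "dataset",
                           values_from = "mean_cindex"))
  if (!is.null(x$note)) {
    cat(x$note, "\n")
    return(invisible(x))
  }
  print(x$friedman)
  cat("Pairwise decisions (alpha =", x$alpha, "):\n")
  print(x$decisions[, c("model_a", "model_b", "p_final", "resolved_by",
                        "significant")])
  invisible(x)
}

#' Tidy pairwise decisions from a comparison report
#'
#' @param x An [build_comparison_report()] object.
#' @param ... Unused.
#' @return A tibble with one row per model pair: mean ranks, Nemenyi and
#'   Wilcoxon p-values, which test resolved the pair, and significance at the
#'   report's alpha.
#' @export
tidy.rrotsf_comparison <- function(x, ...) {
  if (is.null(x$decisions)) {
    return(tibble::tibble(model_a = character(0), model_b = character(0),
                          p_final = numeric(0)))
  }
  x$decisions
}

#' One-row summary of a comparison report
#'
#' @param x An [build_comparison_report()] object.
#' @param ... Unused.
#' @return A one-row tibble: number of models and runs, Friedman statistic
#'   and p-value, and the model with the best (lowest) mean rank.
#' @export
glance.rrotsf_comparison <- function(x, ...) {
  if (is.null(x$friedman)) {
    return(tibble::tibble(k = length(x$models), n_runs = NA_integer_,
                          friedman_statistic = NA_real_,
                          friedman_p = NA_real_, best_model = x$models[1]))
  }
  tibble::tibble(
    k = x$friedman$k,
    n_runs = x$friedman$n_runs,
    friedman_statistic = x$friedman$statistic,
    friedman_p = x$friedman$p.value,
    best_model = names(which.min(x$friedman$mean_ranks))
  )
}

#' Rank boxplot for a comparison report
#'
#' One box per model showing the distribution of its within-run ranks across
#' all runs (lower is better).
#'
#' @param object An [build_comparison_report()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rrotsf_comparison <- function(object, ...) {
  if (is.null(object$ranks)) {
    stop("nothing to plot for a single-model report", call. = FALSE)
  }
  long <- tibble::as_tibble(object$ranks) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "model",
                        values_to = "rank")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$rank)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "rank per run (1 = best)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
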