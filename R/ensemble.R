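#' Fit a random rotation survival forest
#'
#' Trains an ensemble of survival trees for right-censored outcomes. Each
#' member is built by (1) drawing a random subspace of `r` of the `p`
#' covariates, (2) drawing a bootstrap sample of the subjects, (3) randomly
#' partitioning the subspace into subsets of size `M` (leftovers form the
#' remainder set RV whose rotation coefficients are zero), (4) rotating each
#' subset by the principal-component loadings of the bootstrap sample, and
#' (5) growing a log-rank survival tree on the rotated bootstrap rows. The
#' combination of random subspace, bagging and blockwise PCA rotation keeps
#' eigendecompositions cheap (`r x r` at most) while injecting the diversity
#' that makes the ensemble accurate on data with `p >> n`.
#'
#' All randomness derives from `seed` through per-member substreams, so the
#' first `k` members of an `n_trees = k + 1` fit coincide with an
#' `n_trees = k` fit at the same seed, and refits are identical.
#'
#' @param data A survival data frame (time, event and numeric covariates; see
#'   [validate_survival_data()]).
#' @param time_col,event_col Column names of the observation time and event
#'   indicator.
#' @param n_trees Ensemble size (default 500).
#' @param r Subspace size; default \eqn{\lceil \sqrt{p} \rceil} via
#'   [default_r()].
#' @param M Variable-subset size for the blockwise PCA (default 2).
#' @param min_node_size,min_events_to_split,max_depth Tree stopping controls,
#'   see [fit_survival_tree()].
#' @param seed Integer master seed.
#' @param oob Compute the out-of-bag concordance index at fit time (default
#'   `TRUE`; set `FALSE` to skip the extra prediction pass, e.g. inside
#'   cross-validation).
#' @return An object of class `rrotsf` with members (rotation spec + tree
#'   pairs), the shared event-time grid, hyperparameters, and — when
#'   `oob = TRUE` — the out-of-bag C-index in `$oob_cindex`.
#' @examples
#' d <- simulate_survival_data(n = 80, p = 30, n_informative = 3, seed = 7)
#' fit <- rrotsf(d, n_trees = 10, seed = 7)
#' fit$oob_cindex
#' @export
rrotsf <- function(data,
                   time_col = "time",
                   event_col = "event",
                   n_trees = 500,
                   r = NULL,
                   M = 2,
                   min_node_size = 15,
                   min_events_to_split = 3,
                   max_depth = Inf,
                   seed = 1L,
                   oob = TRUE) {
  parts <- surv_parts(data, time_col = time_col, event_col = event_col)
  n <- parts$n
  p <- parts$p
  if (is.null(r)) r <- default_r(p)
  r <- as.integer(r)
  if (r < 1 || r > p) {
    stop("r must satisfy 1 <= r <= p", call. = FALSE)
  }
  if (M < 1 || M > r) {
    stop("M must satisfy 1 <= M <= r", call. = FALSE)
  }
  stopifnot(n_trees >= 1)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  member_seeds <- sample.int(.Machine$integer.max, n_trees)

  time_grid <- sort(unique(parts$time[parts$event == 1]))

  members <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    members[[i]] <- tryCatch(
      fit_member(parts, r, M, min_node_size, min_events_to_split, max_depth,
                 member_seeds[i], time_grid, allow_full = (r == p)),
      error = function(e) {
        stop("while fitting ensemble member ", i, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
  }

  model <- structure(
    list(
      members = members,
      time_grid = time_grid,
      params = list(
        n_trees = as.integer(n_trees), r = r, M = as.integer(M),
        min_node_size = as.integer(min_node_size),
        min_events_to_split = as.integer(min_events_to_split),
        max_depth = max_depth
      ),
      covariate_names = parts$covariate_names,
      n = n,
      p = p,
      seed = as.integer(seed),
      member_seeds = member_seeds,
      oob_cindex = NA_real_
    ),
    class = "rrotsf"
  )
  if (isTRUE(oob)) {
    model$oob_cindex <- oob_score(model, data, time_col = time_col,
                                  event_col = event_col)
  }
  model
}

# Build one (rotation spec, survival tree) pair from its private seed.
fit_member <- function(parts, r, M, min_node_size, min_events_to_split,
                       max_depth, member_seed, time_grid, allow_full = FALSE) {
  set.seed(member_seed)
  spec <- new_rotation_spec(parts$p, parts$n, r, M, allow_full = allow_full)
  spec <- fit_block_rotation_X(parts$X, spec)
  boot <- spec$bootstrap_indices
  Zb <- apply_rotation(parts$X[boot, , drop = FALSE], spec)
  tree <- fit_survival_tree(parts$time[boot], parts$event[boot], Zb,
                            min_node_size = min_node_size,
                            min_events_to_split = min_events_to_split,
                            max_depth = max_depth)
  leaf_ids <- as.integer(names(tree$leaf_chf))
  leaf_grid <- do.call(rbind, lapply(tree$leaf_chf, chf_eval, at = time_grid))
  if (is.null(leaf_grid)) leaf_grid <- matrix(0, 0, length(time_grid))
  list(
    spec = spec,
    tree = tree,
    oob_rows = setdiff(seq_len(parts$n), boot),
    leaf_ids = leaf_ids,
    leaf_grid = leaf_grid,          # leaves x grid, CHF values on time_grid
    leaf_mortality = rowSums(leaf_grid)
  )
}

#' @export
print.rrotsf <- function(x, ...) {
  cat("Random rotation survival forest\n")
  cat("  subjects:", x$n, " covariates:", x$p, "\n")
  cat("  trees:", x$params$n_trees, " r:", x$params$r, " M:", x$params$M, "\n")
  if (!is.na(x$oob_cindex)) {
    cat("  out-of-bag C-index:", format(x$oob_cindex, digits = 4), "\n")
  }
  invisible(x)
}

# Extract the covariate matrix a model expects from a matrix or data frame.
model_covariates <- function(model, newdata) {
  if (is.data.frame(newdata)) {
    missing_cols <- setdiff(model$covariate_names, names(newdata))
    if (length(missing_cols) > 0) {
      stop("newdata is missing covariate column(s): ",
           paste(utils::head(missing_cols, 5), collapse = ", "), call. = FALSE)
    }
    X <- as.matrix(newdata[, model$covariate_names, drop = FALSE])
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) != model$p) {
      stop("expected ", model$p, " covariate columns, got ", ncol(X),
           call. = FALSE)
    }
  }
  storage.mode(X) <- "double"
  X
}

# Leaf row-position in member$leaf_grid for every row of X.
member_leaf_pos <- function(member, X) {
  Z <- apply_rotation(X, member$spec)
  ids <- tree_leaf_ids(member$tree, Z)
  match(ids, member$leaf_ids)
}

#' Ensemble cumulative hazard functions
#'
#' For each subject, every member rotates the covariates with its own
#' rotation spec, routes them to a leaf and reads off the leaf's Nelson-Aalen
#' estimate on the shared training event-time grid; the ensemble estimate is
#' the pointwise mean over members, itself nondecreasing.
#'
#' @param model A fitted [rrotsf()] model.
#' @param newdata Data frame containing the training covariate columns, or a
#'   numeric matrix with `p` columns.
#' @return A list of [chf_step()] objects on `model$time_grid`, one per row.
#' @export
predict_ensemble_chf <- function(model, newdata) {
  H <- ensemble_chf_matrix(model, model_covariates(model, newdata))
  lapply(seq_len(nrow(H)), function(i) chf_step(model$time_grid, H[i, ]))
}

# rows x grid matrix of ensemble-mean CHF values.
ensemble_chf_matrix <- function(model, X) {
  H <- matrix(0, nrow(X), length(model$time_grid))
  for (member in model$members) {
    pos <- member_leaf_pos(member, X)
    H <- H + member$leaf_grid[pos, , drop = FALSE]
  }
  H / length(model$members)
}

#' Mortality risk scores
#'
#' The ensemble risk score of a subject is the sum of its ensemble cumulative
#' hazard over all training event-time grid points (the "mortality"
#' convention of survival forests): higher mortality means shorter predicted
#' survival. This is the score fed to [concordance_index()].
#'
#' @inheritParams predict_ensemble_chf
#' @return A numeric vector of nonnegative risk scores, one per row.
#' @export
predict_mortality <- function(model, newdata) {
  X <- model_covariates(model, newdata)
  mort <- numeric(nrow(X))
  for (member in model$members) {
    pos <- member_leaf_pos(member, X)
    mort <- mort + member$leaf_mortality[pos]
  }
  unname(mort / length(model$members))
}

#' Predict method for random rotation survival forests
#'
#' @param object A fitted [rrotsf()] model.
#' @param newdata New covariate data (data frame or matrix).
#' @param type `"mortality"` (default) for a one-column tibble of risk
#'   scores; `"chf"` for a long tibble of the ensemble cumulative hazard with
#'   columns `.row`, `time`, `chf`.
#' @param ... Unused.
#' @return A tibble.
#' @export
predict.rrotsf <- function(object, newdata, type = c("mortality", "chf"), ...) {
  type <- match.arg(type)
  if (type == "mortality") {
    tibble::tibble(mortality = predict_mortality(object, newdata))
  } else {
    H <- ensemble_chf_matrix(object, model_covariates(object, newdata))
    tibble::tibble(
      .row = rep(seq_len(nrow(H)), each = ncol(H)),
      time = rep(object$time_grid, times = nrow(H)),
      chf = as.vector(t(H))
    )
  }
}

#' Out-of-bag concordance index
#'
#' Scores each training subject with only the members whose bootstrap sample
#' excluded it, then computes Harrell's C-index of those out-of-bag mortality
#' scores against the observed outcomes. Subjects that were in-bag for every
#' member are dropped (with a message); with a handful of trees this can
#' leave no scored subject at all, which is an error.
#'
#' @param model A fitted [rrotsf()] model.
#' @param data The training data the model was fitted on.
#' @param time_col,event_col Outcome column names.
#' @return The out-of-bag C-index in `[0, 1]`.
#' @export
oob_score <- function(model, data, time_col = "time", event_col = "event") {
  parts <- surv_parts(data, time_col = time_col, event_col = event_col)
  if (parts$n != model$n || parts$p != model$p) {
    stop("data does not match the model's training dimensions", call. = FALSE)
  }
  mort <- numeric(parts$n)
  cnt <- integer(parts$n)
  for (member in model$members) {
    rows <- member$oob_rows
    if (length(rows) == 0) next
    pos <- member_leaf_pos(member, parts$X[rows, , drop = FALSE])
    mort[rows] <- mort[rows] + member$leaf_mortality[pos]
    cnt[rows] <- cnt[rows] + 1L
  }
  keep <- cnt > 0
  if (!any(keep)) {
    stop("no subject was out-of-bag for any member; increase n_trees",
         call. = FALSE)
  }
  if (any(!keep)) {
    message(sum(!keep), " subject(s) never out-of-bag were dropped from the ",
            "OOB score")
  }
  concordance_index(parts$time[keep], parts$event[keep],
                    mort[keep] / cnt[keep])
}

#' Save / load a fitted forest
#'
#' The model container (rotation matrices, centers, tree tables, hazard
#' grids, hyperparameters and seeds) round-trips exactly: a reloaded model
#' produces bit-identical predictions.
#'
#' @param model A fitted [rrotsf()] model.
#' @param path File path.
#' @return `write_rrotsf()` returns `path` invisibly; `read_rrotsf()` the
#'   model.
#' @export
write_rrotsf <- function(model, path) {
  stopifnot(inherits(model, "rrotsf"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname write_rrotsf
#' @export
read_rrotsf <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rrotsf")) {
    stop("file does not contain an rrotsf model", call. = FALSE)
  }
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-member summary of a fitted forest
#'
#' @param x A fitted [rrotsf()] model.
#' @param ... Unused.
#' @return A tibble with one row per ensemble member: subspace size, number
#'   of tree nodes and leaves, maximum depth and out-of-bag count.
#' @export
tidy.rrotsf <- function(x, ...) {
  purrr::map_dfr(seq_along(x$members), function(i) {
    m <- x$members[[i]]
    tibble::tibble(
      member = i,
      r = length(m$spec$subspace),
      n_blocks = length(m$spec$subsets),
      n_remainder = length(m$spec$remainder),
      n_nodes = nrow(m$tree$nodes),
      n_leaves = length(m$tree$leaf_chf),
      max_depth = max(m$tree$nodes$depth),
      n_oob = length(m$oob_rows)
    )
  })
}

#' One-row summary of a fitted forest
#'
#' @param x A fitted [rrotsf()] model.
#' @param ... Unused.
#' @return A one-row tibble with dimensions, hyperparameters and the
#'   out-of-bag C-index (NA when not computed).
#' @export
glance.rrotsf <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = x$p,
    n_trees = x$params$n_trees, r = x$params$r, M = x$params$M,
    seed = x$seed,
    oob_cindex = x$oob_cindex
  )
}
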