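#' Cumulative hazard step functions
#'
#' Lightweight container for a right-continuous nondecreasing step function:
#' the Nelson-Aalen estimate at a tree leaf or an ensemble average. The
#' function is 0 before the first grid time and constant after the last jump.
#'
#' @param times Strictly increasing positive event times.
#' @param values Nondecreasing nonnegative values, same length as `times`.
#' @return An object of class `chf_step`.
#' @export
chf_step <- function(times, values) {
  stopifnot(length(times) == length(values))
  if (length(times) > 0) {
    stopifnot(all(times > 0), !is.unsorted(times, strictly = TRUE),
              all(values >= 0), !is.unsorted(values))
  }
  structure(list(times = as.double(times), values = as.double(values)),
            class = "chf_step")
}

#' Evaluate a cumulative hazard step function
#'
#' @param chf A [chf_step()] object.
#' @param at Times at which to evaluate (right-continuous lookup).
#' @return Numeric vector of hazard values, 0 before the first jump.
#' @export
chf_eval <- function(chf, at) {
  stopifnot(inherits(chf, "chf_step"))
  if (length(chf$times) == 0) return(rep(0, length(at)))
  c(0, chf$values)[findInterval(at, chf$times) + 1]
}

#' @export
print.chf_step <- function(x, ...) {
  cat("<chf_step> with", length(x$times), "jump(s)")
  if (length(x$times) > 0) {
    cat(sprintf("; H(%g) = %g", max(x$times), max(x$values)))
  }
  cat("\n")
  invisible(x)
}

#' Nelson-Aalen cumulative hazard estimator
#'
#' At each distinct event time `t` the hazard increments by
#' (events at `t`) / (subjects at risk at `t`); the cumulative sum is the
#' Nelson-Aalen estimate. Censoring times add no jump but shrink later risk
#' sets. With no events the estimate is identically zero.
#'
#' @param time Observed times (events or censoring), positive.
#' @param event Event indicators, 1 = event observed, 0 = censored.
#' @return A [chf_step()] object with one jump per distinct event time.
#' @examples
#' nelson_aalen(c(1, 2, 3), c(1, 1, 1)) # increments 1/3, 1/2, 1
#' @export
nelson_aalen <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0) return(chf_step(numeric(0), numeric(0)))
  d <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  y <- vapply(et, function(t) sum(time >= t), numeric(1))
  chf_step(et, cumsum(d / y))
}

#' Two-sample log-rank statistic
#'
#' The standard log-rank chi-square: observed-minus-expected event counts in
#' one group summed over distinct event times, squared, divided by the summed
#' hypergeometric variance. This is the splitting criterion of the survival
#' trees — a larger value means a larger survival difference between the two
#' groups. Returns 0 when the variance sum is 0 (no discriminating event
#' times).
#'
#' @param time Observed times.
#' @param event Event indicators (1 = event).
#' @param membership Logical (or 0/1) vector: `TRUE` for the "left" group.
#'   Both groups must be nonempty.
#' @return Nonnegative scalar; invariant under swapping the group labels.
#' @export
logrank_statistic <- function(time, event, membership) {
  membership <- as.logical(membership)
  stopifnot(length(time) == length(event), length(time) == length(membership))
  if (!any(membership) || all(membership)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (sum(event == 1) < 1) {
    stop("at least one event is required", call. = FALSE)
  }
  et <- sort(unique(time[event == 1]))
  oe <- 0
  v <- 0
  for (t in et) {
    y <- sum(time >= t)
    y1 <- sum(time >= t & membership)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & membership)
    oe <- oe + d1 - y1 * d / y
    if (y > 1) {
      v <- v + d * (y1 / y) * (1 - y1 / y) * (y - d) / (y - 1)
    }
  }
  if (v <= 0) return(0)
  oe^2 / v
}

#' Grow a survival tree in a rotated feature space
#'
#' Greedy recursive partitioning: each node scores every feature at every
#' midpoint between consecutive distinct observed values with
#' [logrank_statistic()] and takes the best (feature, threshold); ties go to
#' the lowest feature index, then the smallest threshold, so refits are
#' deterministic. A node becomes a leaf when any admissible split would leave
#' a child below `min_node_size`, when it holds fewer than
#' `min_events_to_split` events, when `max_depth` is reached, or when the best
#' statistic is 0. Each leaf stores the Nelson-Aalen cumulative hazard of its
#' training rows. The convention `z <= threshold` goes left.
#'
#' @param time,event Survival outcome of the training rows.
#' @param Z Numeric matrix of (rotated) features, one row per subject; must
#'   be finite.
#' @param min_node_size Minimum rows in any node (default 15).
#' @param min_events_to_split Minimum events a node needs to be split
#'   (default 3).
#' @param max_depth Maximum split depth; `Inf` (default) for unlimited.
#' @return An object of class `survival_tree`: a node table plus per-leaf
#'   [chf_step()] estimators and the leaf each training row landed in.
#' @export
fit_survival_tree <- function(time, event, Z,
                              min_node_size = 15,
                              min_events_to_split = 3,
                              max_depth = Inf) {
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  stopifnot(length(time) == nrow(Z), length(event) == nrow(Z))
  if (!all(is.finite(Z))) {
    stop("Z must be finite", call. = FALSE)
  }
  md <- if (is.finite(max_depth)) as.integer(max_depth) else -1L
  grown <- .grow_tree_cpp(as.double(time), as.integer(event), Z,
                          as.integer(min_node_size),
                          as.integer(min_events_to_split), md)
  leaf_ids <- sort(unique(grown$leaf_of_row))
  leaf_chf <- lapply(leaf_ids, function(id) {
    rows <- which(grown$leaf_of_row == id)
    nelson_aalen(time[rows], event[rows])
  })
  names(leaf_chf) <- as.character(leaf_ids)
  structure(
    list(
      nodes = tibble::tibble(
        node = seq_along(grown$feature),
        feature = grown$feature,
        threshold = grown$threshold,
        left = grown$left,
        right = grown$right,
        n = grown$n,
        events = grown$events,
        depth = grown$depth
      ),
      leaf_chf = leaf_chf,
      leaf_of_row = grown$leaf_of_row,
      n_features = ncol(Z)
    ),
    class = "survival_tree"
  )
}

#' @export
print.survival_tree <- function(x, ...) {
  cat("<survival_tree>", nrow(x$nodes), "nodes,",
      length(x$leaf_chf), "leaves\n")
  invisible(x)
}

# Leaf node id (into the node table) for each row of Z.
tree_leaf_ids <- function(tree, Z) {
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  if (ncol(Z) != tree$n_features) {
    stop("expected ", tree$n_features, " feature columns, got ", ncol(Z),
         call. = FALSE)
  }
  .route_tree_cpp(tree$nodes$feature, tree$nodes$threshold,
                  tree$nodes$left, tree$nodes$right, Z)
}

#' Predict the leaf cumulative hazard for a rotated feature vector
#'
#' Routes `z` down the tree (values equal to a threshold go left) and returns
#' the Nelson-Aalen estimator of the leaf it reaches.
#'
#' @param tree A fitted [fit_survival_tree()] object.
#' @param z A numeric vector with one entry per rotated feature, or a matrix
#'   of such rows.
#' @return A [chf_step()] object, or a list of them when `z` is a matrix with
#'   more than one row.
#' @export
predict_tree_chf <- function(tree, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (!all(is.finite(z))) {
    stop("z must be finite", call. = FALSE)
  }
  ids <- tree_leaf_ids(tree, z)
  out <- lapply(as.character(ids), function(id) tree$leaf_chf[[id]])
  if (length(out) == 1) out[[1]] else out
}
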