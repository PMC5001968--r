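#' Default subspace size
#'
#' The number of covariates each ensemble member works on defaults to
#' \eqn{r = \lceil \sqrt{p} \rceil}, the usual random-subspace heuristic that
#' keeps the per-member PCA cheap even for tens of thousands of covariates.
#'
#' @param p Total number of covariates (>= 1).
#' @return The integer \eqn{\lceil \sqrt{p} \rceil}.
#' @examples
#' default_r(22283) # 150
#' @export
default_r <- function(p) {
  stopifnot(length(p) == 1, p >= 1)
  as.integer(ceiling(sqrt(p)))
}

#' Draw a random covariate subspace
#'
#' Selects `r` distinct covariate indices uniformly without replacement from
#' `1:p`, recording their order (the order defines the layout of the rotation
#' matrix). Uses the current R random stream; seed it for reproducibility.
#'
#' @param p Total number of covariates.
#' @param r Subspace size; must satisfy `r < p` unless `allow_full = TRUE`
#'   (a degenerate mode used to reduce the method to plain PCA rotation).
#' @param allow_full Allow `r == p`.
#' @return An integer vector of `r` distinct indices.
#' @export
select_subspace <- function(p, r, allow_full = FALSE) {
  stopifnot(p >= 1, r >= 1)
  if (r > p || (r == p && !allow_full)) {
    stop("subspace size r must satisfy 1 <= r < p (r = ", r, ", p = ", p, ")",
         call. = FALSE)
  }
  sample.int(p, r, replace = FALSE)
}

#' Partition a subspace into equal-size variable subsets
#'
#' Randomly splits the `r` subspace positions into `k = floor(r / M)` disjoint
#' subsets of exactly `M` positions each; the `r mod M` leftover positions
#' form the remainder set RV, whose rotation coefficients are later fixed at
#' zero to inject extra randomness.
#'
#' @param subspace Integer vector of covariate indices (as from
#'   [select_subspace()]); only its length matters here.
#' @param M Subset size, `1 <= M <= length(subspace)`.
#' @return A list with `subsets` (list of `k` integer vectors of positions
#'   into the subspace, each of length `M`) and `remainder` (integer vector of
#'   the leftover positions, possibly empty).
#' @export
partition_variables <- function(subspace, M) {
  r <- length(subspace)
  stopifnot(r >= 1)
  if (M < 1 || M > r) {
    stop("subset size M must satisfy 1 <= M <= r (M = ", M, ", r = ", r, ")",
         call. = FALSE)
  }
  k <- r %/% M
  perm <- sample.int(r, r, replace = FALSE)
  used <- perm[seq_len(k * M)]
  subsets <- split(used, rep(seq_len(k), each = M))
  names(subsets) <- NULL
  remainder <- if (k * M < r) perm[(k * M + 1):r] else integer(0)
  list(subsets = subsets, remainder = remainder)
}

# Internal constructor: draw everything random for one ensemble member, in
# step order (subspace, then bootstrap, then partition), leaving the loadings
# unfitted.
new_rotation_spec <- function(p, n, r, M, allow_full = FALSE) {
  subspace <- select_subspace(p, r, allow_full = allow_full)
  bootstrap_indices <- sample.int(n, n, replace = TRUE)
  part <- partition_variables(subspace, M)
  structure(
    list(
      p = as.integer(p),
      subspace = as.integer(subspace),
      subsets = part$subsets,
      remainder = as.integer(part$remainder),
      bootstrap_indices = as.integer(bootstrap_indices),
      block_loadings = NULL,
      center = NULL,
      rotation = NULL
    ),
    class = "rotation_spec"
  )
}

#' Fit blockwise PCA loadings and assemble the rotation matrix
#'
#' For each variable subset \eqn{V_j}, computes the principal-component
#' loading matrix of the bootstrap sample restricted to those columns after
#' mean-centering. All components are retained (no truncation), so each block
#' loading is a square orthonormal matrix and the rotation is
#' variance-preserving within blocks. The loadings are assembled into the
#' `r x r` rotation matrix laid out in subspace order, with rows and columns
#' belonging to the remainder set RV set exactly to zero.
#'
#' Eigenvector signs are fixed deterministically (largest-magnitude entry
#' positive) so repeated fits are identical. A block whose columns all have
#' zero variance in the bootstrap sample keeps identity loadings rather than
#' aborting (constant covariates are never split on downstream).
#'
#' @param data A survival data frame (see [validate_survival_data()]).
#' @param spec A partially built rotation spec holding `subspace`, `subsets`,
#'   `remainder` and `bootstrap_indices`.
#' @param time_col,event_col Column names of time and event.
#' @return The completed spec with `block_loadings`, `center` and `rotation`
#'   filled in.
#' @export
fit_block_rotation <- function(data, spec, time_col = "time", event_col = "event") {
  parts <- surv_parts(data, time_col = time_col, event_col = event_col)
  fit_block_rotation_X(parts$X, spec)
}

# Matrix-level work-horse so the ensemble can skip repeated validation.
fit_block_rotation_X <- function(X, spec) {
  if (ncol(X) != spec$p) {
    stop("covariate count mismatch: spec expects p = ", spec$p,
         ", data has ", ncol(X), call. = FALSE)
  }
  boot <- spec$bootstrap_indices
  if (length(unique(boot)) < 2) {
    stop("bootstrap sample has fewer than 2 distinct rows", call. = FALSE)
  }
  Xb <- X[boot, spec$subspace, drop = FALSE]
  center <- colMeans(Xb)
  Xc <- sweep(Xb, 2, center)

  r <- length(spec$subspace)
  rotation <- matrix(0, r, r)
  loadings <- vector("list", length(spec$subsets))
  for (j in seq_along(spec$subsets)) {
    pos <- spec$subsets[[j]]
    block <- Xc[, pos, drop = FALSE]
    cv <- crossprod(block) / (nrow(block) - 1)
    if (all(abs(cv) < .Machine$double.eps * 100)) {
      L <- diag(length(pos)) # zero-variance block: keep axes as they are
    } else {
      eig <- eigen(cv, symmetric = TRUE)
      L <- eig$vectors
      L <- fix_eigen_signs(L)
    }
    loadings[[j]] <- L
    rotation[pos, pos] <- L
  }
  # remainder positions stay identically zero
  spec$block_loadings <- loadings
  spec$center <- center
  spec$rotation <- rotation
  spec
}

# Deterministic sign convention: make the largest-magnitude entry of each
# eigenvector positive (first such entry on exact ties).
fix_eigen_signs <- function(L) {
  for (j in seq_len(ncol(L))) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  L
}

#' Apply a fitted rotation to new data
#'
#' Selects the spec's subspace columns (in subspace order), subtracts the
#' centers stored at fitting time, and multiplies by the assembled rotation
#' matrix. Output columns at remainder (RV) positions are exactly zero.
#'
#' @param X Numeric matrix (or data frame) with the full `p` covariate
#'   columns in training schema order.
#' @param spec A completed rotation spec.
#' @return A numeric matrix with `length(spec$subspace)` columns of rotated
#'   features.
#' @export
apply_rotation <- function(X, spec) {
  if (is.null(spec$rotation)) {
    stop("rotation spec has not been fitted; call fit_block_rotation() first",
         call. = FALSE)
  }
  X <- as.matrix(X)
  if (ncol(X) != spec$p) {
    stop("covariate count mismatch: spec expects p = ", spec$p,
         ", data has ", ncol(X), call. = FALSE)
  }
  Xs <- X[, spec$subspace, drop = FALSE]
  Xs <- sweep(Xs, 2, spec$center)
  Xs %*% spec$rotation
}
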