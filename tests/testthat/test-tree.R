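test_that("Nelson-Aalen matches hand-computed increments", {
  chf <- nelson_aalen(c(1, 2, 3), c(1, 1, 1))
  expect_equal(chf$times, c(1, 2, 3))
  expect_equal(chf$values, c(1 / 3, 1 / 3 + 1 / 2, 1 / 3 + 1 / 2 + 1))

  # all censored -> identically zero
  flat <- nelson_aalen(c(1, 2, 3), c(0, 0, 0))
  expect_length(flat$times, 0)
  expect_equal(chf_eval(flat, c(0.5, 10)), c(0, 0))

  # duplicating every subject leaves the estimate unchanged
  t1 <- c(0.5, 1, 1, 2.5, 4); e1 <- c(1, 0, 1, 1, 0)
  a <- nelson_aalen(t1, e1)
  b <- nelson_aalen(rep(t1, 2), rep(e1, 2))
  expect_equal(a, b)
})

test_that("Nelson-Aalen agrees with the survival package to 1e-10", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:25, 1)
    time <- round(stats::rexp(n) + 0.05, 2) # rounding forces ties
    event <- stats::rbinom(n, 1, 0.7)
    chf <- nelson_aalen(time, event)
    sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                            stype = 2, ctype = 1)
    ours <- chf_eval(chf, sf$time)
    expect_lt(max(abs(ours - sf$cumhaz)), 1e-10)
  }
})

test_that("log-rank statistic matches hand computation and brute force", {
  # 4 subjects, all events, first two in the left group:
  # O-E = 7/6, Var = 17/36, statistic = (7/6)^2 / (17/36) = 49/17
  stat <- logrank_statistic(c(1, 2, 3, 4), c(1, 1, 1, 1),
                            c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(stat, 49 / 17)

  # identical interleaved groups show no survival difference
  t2 <- rep(c(1, 2, 3, 5), each = 2); e2 <- rep(c(1, 0, 1, 1), each = 2)
  g2 <- rep(c(TRUE, FALSE), 4)
  expect_equal(logrank_statistic(t2, e2, g2), 0)

  set.seed(55)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    time <- round(stats::rexp(n), 2) + 0.01
    event <- stats::rbinom(n, 1, 0.7)
    grp <- c(TRUE, FALSE, stats::runif(n - 2) > 0.5)
    if (sum(event) == 0) event[1] <- 1L
    expect_equal(logrank_statistic(time, event, grp),
                 logrank_bruteforce(time, event, grp))
  }
})

test_that("log-rank statistic has the expected invariances", {
  set.seed(66)
  time <- stats::rexp(20) + 0.01
  event <- stats::rbinom(20, 1, 0.8)
  grp <- rep(c(TRUE, FALSE), 10)
  s <- logrank_statistic(time, event, grp)
  # relabeling left/right
  expect_equal(logrank_statistic(time, event, !grp), s)
  # strictly increasing time transform
  expect_equal(logrank_statistic(exp(time), event, grp), s)

  # complete separation scores higher than interleaving (n = 20)
  tt <- 1:20; ee <- rep(1L, 20)
  sep <- logrank_statistic(tt, ee, c(rep(TRUE, 10), rep(FALSE, 10)))
  inter <- logrank_statistic(tt, ee, rep(c(TRUE, FALSE), 10))
  expect_gt(sep, inter)

  expect_error(logrank_statistic(time, event, rep(TRUE, 20)), "nonempty")
})

test_that("tree stumps and forced stops reduce to the root Nelson-Aalen", {
  set.seed(77)
  n <- 40
  time <- stats::rexp(n) + 0.01
  event <- stats::rbinom(n, 1, 0.8)
  Z <- matrix(stats::rnorm(n * 3), n, 3)

  stump <- fit_survival_tree(time, event, Z, max_depth = 0)
  expect_equal(nrow(stump$nodes), 1)
  expect_equal(stump$leaf_chf[["1"]], nelson_aalen(time, event))
  expect_equal(predict_tree_chf(stump, c(9, 9, 9)), nelson_aalen(time, event))

  forced <- fit_survival_tree(time, event, Z, min_node_size = n)
  expect_equal(nrow(forced$nodes), 1)
})

test_that("a perfectly separating feature is chosen at the root", {
  set.seed(88)
  n <- 40
  x <- c(rep(0, 20), rep(1, 20))
  time <- ifelse(x == 0, stats::runif(n, 0.1, 1), stats::runif(n, 5, 10))
  event <- rep(1L, n)
  Z <- cbind(stats::rnorm(n), x, stats::rnorm(n))

  tree <- fit_survival_tree(time, event, Z, min_node_size = 10, max_depth = 1)
  expect_equal(tree$nodes$feature[1], 2)
  expect_equal(tree$nodes$threshold[1], 0.5)

  left_chf <- tree$leaf_chf[[as.character(tree$nodes$left[1])]]
  right_chf <- tree$leaf_chf[[as.character(tree$nodes$right[1])]]
  grid <- sort(unique(time))
  # early-failure group (x = 0, goes left) has the larger hazard everywhere
  expect_true(all(chf_eval(left_chf, grid) >= chf_eval(right_chf, grid)))
})

test_that("the compiled split search equals an exhaustive R-level search", {
  set.seed(99)
  for (i in 1:5) {
    n <- 30
    time <- round(stats::rexp(n), 1) + 0.1
    event <- stats::rbinom(n, 1, 0.8)
    Z <- matrix(round(stats::rnorm(n * 2), 1), n, 2)
    tree <- fit_survival_tree(time, event, Z, min_node_size = 5,
                              max_depth = 1)
    if (is.na(tree$nodes$feature[1])) next

    best <- list(stat = 0, feature = NA, threshold = NA)
    for (f in 1:2) {
      vals <- sort(unique(Z[, f]))
      if (length(vals) < 2) next
      for (cut in (vals[-1] + vals[-length(vals)]) / 2) {
        left <- Z[, f] <= cut
        if (sum(left) < 5 || sum(!left) < 5) next
        s <- logrank_statistic(time, event, left)
        if (s > best$stat) best <- list(stat = s, feature = f, threshold = cut)
      }
    }
    expect_equal(tree$nodes$feature[1], best$feature)
    expect_equal(tree$nodes$threshold[1], best$threshold)
  }
})

test_that("trees partition their rows, are deterministic, and route back", {
  set.seed(111)
  n <- 60
  time <- stats::rexp(n) + 0.01
  event <- stats::rbinom(n, 1, 0.7)
  Z <- matrix(stats::rnorm(n * 4), n, 4)
  t1 <- fit_survival_tree(time, event, Z, min_node_size = 8)
  t2 <- fit_survival_tree(time, event, Z, min_node_size = 8)
  expect_identical(t1, t2)

  # every training row reaches exactly one leaf, and routing reproduces the
  # leaf recorded at fit time
  leaf_nodes <- as.integer(names(t1$leaf_chf))
  expect_setequal(unique(t1$leaf_of_row), leaf_nodes)
  routed <- rrotsf:::tree_leaf_ids(t1, Z)
  expect_identical(routed, t1$leaf_of_row)
  expect_equal(sum(t1$nodes$n[t1$nodes$node %in% leaf_nodes]), n)

  # each leaf CHF is a nonnegative nondecreasing step function
  for (chf in t1$leaf_chf) {
    expect_true(all(chf$values >= 0))
    expect_true(!is.unsorted(chf$values))
  }

  # exact-threshold values go left
  stub <- fit_survival_tree(c(1, 2, 3, 4), c(1, 1, 1, 1),
                            matrix(c(0, 0, 1, 1), 4), min_node_size = 1,
                            min_events_to_split = 1)
  expect_equal(stub$nodes$threshold[1], 0.5)
  id_left <- rrotsf:::tree_leaf_ids(stub, matrix(0.5, 1, 1))
  expect_equal(id_left, stub$nodes$left[1])

  expect_error(predict_tree_chf(t1, c(1, NA, 0, 0)), "finite")
})
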