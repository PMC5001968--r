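# Shared fixtures and independent oracles for the test suite.

# Small random censored dataset as a plain tibble (no signal structure).
random_censored_data <- function(n, p = 3, censor_frac = 0.3, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    time = stats::rexp(n) + 0.01,
    event = as.integer(stats::runif(n) > censor_frac),
    !!!stats::setNames(
      lapply(seq_len(p), function(j) stats::rnorm(n)),
      paste0("x", seq_len(p))
    )
  )
}

# Independent O(n^2) concordance oracle: explicit double loop over ordered
# pairs, written against the pair rules directly (no vectorization shared
# with the package implementation).
cindex_bruteforce <- function(time, event, risk) {
  n <- length(time)
  s <- 0
  npairs <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      # determine which subject demonstrably fails first, if any
      if (time[i] < time[j] && event[i] == 1) {
        early <- i; late <- j
      } else if (time[j] < time[i] && event[j] == 1) {
        early <- j; late <- i
      } else if (time[i] == time[j] && event[i] + event[j] == 1) {
        early <- if (event[i] == 1) i else j
        late <- if (event[i] == 1) j else i
      } else {
        next
      }
      npairs <- npairs + 1
      if (risk[early] > risk[late]) {
        s <- s + 1
      } else if (risk[early] == risk[late]) {
        s <- s + 0.5
      }
    }
  }
  if (npairs == 0) stop("no valid pairs")
  s / npairs
}

# Independent log-rank oracle: accumulate O-E and hypergeometric variance
# over each distinct event time, one risk set at a time.
logrank_bruteforce <- function(time, event, membership) {
  membership <- as.logical(membership)
  oe <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    y <- sum(at_risk)
    y1 <- sum(at_risk & membership)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & membership)
    oe <- oe + (d1 - d * y1 / y)
    if (y > 1) v <- v + d * (y1 / y) * (1 - y1 / y) * (y - d) / (y - 1)
  }
  if (v <= 0) return(0)
  oe^2 / v
}

# A dataset whose first covariate alone drives the failure times through a
# smooth monotone gradient (so risk is rankable both between and within
# regions of x1).
separable_data <- function(n = 60, p = 5, seed = 1) {
  set.seed(seed)
  x1 <- stats::runif(n, -1, 1)
  time <- exp(-2 * x1 + stats::rnorm(n, sd = 0.2))
  tibble::tibble(
    time = time,
    event = rep(1L, n),
    x1 = x1,
    !!!stats::setNames(
      lapply(seq_len(p - 1), function(j) stats::rnorm(n)),
      paste0("x", 1 + seq_len(p - 1))
    )
  )
}
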