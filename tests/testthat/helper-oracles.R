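# Independent oracles used across the suite. These deliberately avoid the
# production code paths: segment statistics are recomputed from scratch,
# the Mann-Kendall null is enumerated, and geodesic checks call geosphere
# directly on analytically known nearest points.

make_series <- function(values, start = as.Date("1990-01-01"), by = 16,
                        site_id = "s") {
  tibble::tibble(site_id = site_id,
                 date = start + by * (seq_along(values) - 1),
                 value = as.numeric(values))
}

# exhaustive O(n^2) single-changepoint scan; each candidate's two segment
# costs are recomputed directly from the raw values
oracle_cpt <- function(x, metric = "mean", min_seg = NULL,
                       var_floor = 1e-8) {
  if (is.null(min_seg)) min_seg <- if (metric == "mean") 1L else 2L
  n <- length(x)
  seg_cost <- function(xk) {
    if (metric == "mean") {
      sum((xk - mean(xk))^2)
    } else {
      length(xk) * log(max(sum((xk - mean(xk))^2) / length(xk), var_floor))
    }
  }
  best_tau <- NA_integer_
  best_cost <- Inf
  for (n1 in seq.int(min_seg, n - min_seg)) {
    cost <- seg_cost(x[1:n1]) + seg_cost(x[(n1 + 1):n])
    if (cost < best_cost) {        # strict: keeps the smallest tau on ties
      best_cost <- cost
      best_tau <- n1 - 1L
    }
  }
  list(tau = best_tau, cost = best_cost)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, ifelse(p >= i, p + 1L, p))
  }))
}

mk_S <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) s <- s + sum(sign(x[(i + 1):n] - x[i]))
  s
}

# exact two-sided p-value of the Mann-Kendall S under the permutation null
# (all orderings equally likely; values must be distinct)
mk_exact_p <- function(x) {
  stopifnot(!anyNA(x), length(unique(x)) == length(x))
  P <- all_perms(length(x))
  Svals <- apply(P, 1, function(idx) mk_S(x[idx]))
  mean(abs(Svals) >= abs(mk_S(x)))
}
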