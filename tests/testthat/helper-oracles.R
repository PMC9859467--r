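# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# Mode of the first 10 readings by explicit counting; ties -> largest value.
oracle_features <- function(readings) {
  f10 <- readings[1:10]
  best_v <- -Inf
  best_n <- 0L
  for (v in unique(f10)) {
    n <- 0L
    for (x in f10) if (x == v) n <- n + 1L
    if (n > best_n || (n == best_n && v > best_v)) {
      best_v <- v
      best_n <- n
    }
  }
  s20 <- 0
  for (x in readings[1:20]) s20 <- s20 + x
  s30 <- 0
  mx <- readings[1]
  mn <- readings[1]
  for (x in readings[1:30]) {
    s30 <- s30 + x
    if (x > mx) mx <- x
    if (x < mn) mn <- x
  }
  list(mode10 = best_v, max30 = mx, min30 = mn,
       avg20 = s20 / 20, avg30 = s30 / 30,
       max_minus_avg20 = mx - s20 / 20,
       max_minus_avg30 = mx - s30 / 30)
}

# Ordinary least squares through the normal equations.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(intercept = beta[1], slope = beta[2])
}

random_trace <- function(n = 40, max_count = 1023) {
  sensor_trace(sample(0:max_count, n, replace = TRUE),
               trial_id = "random")
}
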