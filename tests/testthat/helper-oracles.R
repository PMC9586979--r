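# Independent oracles used to freeze expected values; each is a deliberately
# naive implementation kept separate from the code paths it checks.

# direct-summation mean and sample SD
oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}
oracle_sd <- function(x) {
  m <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}

# closed-form normal equations for simple OLS
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# sort-and-interpolate median
oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# brute-force Moore-neighborhood mean over unmasked, in-bounds cells
oracle_neighborhood <- function(values, mask, row, col) {
  acc <- c(); used <- 0
  for (dr in -1:1) {
    for (dc in -1:1) {
      r <- row + dr; c <- col + dc
      if (r >= 1 && r <= nrow(values) && c >= 1 && c <= ncol(values) &&
          !mask[r, c]) {
        acc <- c(acc, values[r, c]); used <- used + 1
      }
    }
  }
  list(mean = sum(acc) / used, used = used)
}
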