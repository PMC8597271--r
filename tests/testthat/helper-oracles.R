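# Independent oracles used to pin expected values.

# weighted least squares by explicit normal equations
wls_normal_equations <- function(x, y, w) {
  X <- cbind(1, x)
  A <- t(X) %*% (w * X)
  b <- t(X) %*% (w * y)
  as.numeric(solve(A, b)) # (intercept, slope)
}

# iterative extreme-trimming linearity oracle on level means with given
# per-level weights; returns retained indices and final fit
linearity_trim_oracle <- function(expected, means, weights, delta) {
  retained <- rep(TRUE, length(expected))
  repeat {
    k <- which(retained)
    cf <- wls_normal_equations(expected[k], means[k], weights[k])
    fitted <- cf[1] + cf[2] * expected[k]
    dev <- 100 * (means[k] - fitted) / fitted
    fails <- abs(dev) > delta
    if (!any(fails)) {
      return(list(retained = k, coef = cf, dev = dev))
    }
    stopifnot(fails[1] || fails[length(fails)]) # oracle assumes extreme failure
    drop <- if (fails[1] && fails[length(fails)]) {
      if (abs(dev[1]) >= abs(dev[length(dev)])) k[1] else k[length(k)]
    } else if (fails[1]) k[1] else k[length(k)]
    retained[drop] <- FALSE
  }
}

# a numeric vector with exactly the requested sample mean and SD
vector_with_stats <- function(n, mean, sd, seed = 1) {
  z <- withr::with_seed(seed, stats::rnorm(n))
  mean + sd * (z - base::mean(z)) / stats::sd(z)
}

# exact 4PL forward map (mirrors the model definition independently)
oracle_4pl <- function(x, a, d, c50, b) a + (d - a) / (1 + (c50 / x)^b)

quiet_truth <- function(...) {
  sim_truth(cv_components = c(lot = 0, operator = 0, day = 0, run = 0, rep = 0),
            blank_floor_sd = 0, ...)
}
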