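# Independent oracles, deliberately sharing no code with the implementation.

# Exponential-decay fit by grid search over tau with (A, A*B) solved
# linearly at each tau, then a 1-D polish.
brute_force_tau <- function(lag, r) {
  sse_for <- function(tau) {
    x <- exp(-lag / tau)
    sum(stats::resid(stats::lm(r ~ x))^2)
  }
  grid <- exp(seq(log(5), log(5000), length.out = 400))
  sses <- vapply(grid, sse_for, numeric(1))
  i <- which.min(sses)
  opt <- stats::optimize(sse_for, c(grid[max(1, i - 1)],
                                    grid[min(length(grid), i + 1)]))
  tau <- opt$minimum
  cf <- stats::coef(stats::lm(r ~ exp(-lag / tau)))
  list(tau = tau, A = unname(cf[2]), B = unname(cf[1] / cf[2]))
}

# Fisher-averaged PWD correlation by direct summation over explicit loops.
oracle_discriminability <- function(train_vals, test_vals, labels_train,
                                    labels_test) {
  conds <- sort(unique(labels_train))
  pairs <- utils::combn(length(conds), 2)
  zs <- c()
  for (p in seq_len(ncol(pairs))) {
    a <- c()
    b <- c()
    for (n in seq_len(nrow(train_vals))) {
      m1a <- mean(train_vals[n, labels_train == conds[pairs[1, p]]])
      m1b <- mean(train_vals[n, labels_train == conds[pairs[2, p]]])
      m2a <- mean(test_vals[n, labels_test == conds[pairs[1, p]]])
      m2b <- mean(test_vals[n, labels_test == conds[pairs[2, p]]])
      a <- c(a, m1a - m1b)
      b <- c(b, m2a - m2b)
    }
    if (stats::sd(a) > 0 && stats::sd(b) > 0) {
      zs <- c(zs, atanh(min(max(stats::cor(a, b), -1 + 1e-12), 1 - 1e-12)))
    }
  }
  tanh(mean(zs))
}
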