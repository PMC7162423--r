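# Independent oracles used across the suite. These deliberately avoid the
# package's own fitting paths.

# Coarse grid search over (lambda_r, lambda_d) with a closed-form linear
# solve for A0, followed by local refinement with optim. Brute-force
# reference for the rise-and-decay time-activity fit.
oracle_tac_fit <- function(t, y) {
  sse_of <- function(lr, ld) {
    f <- (1 - exp(-lr * t)) * exp(-ld * t)
    a0 <- max(0, sum(f * y) / sum(f * f))
    sum((a0 * f - y)^2)
  }
  grid <- expand.grid(lr = exp(seq(log(0.02), log(10), length.out = 40)),
                      ld = seq(0, 1, length.out = 40))
  sse <- mapply(sse_of, grid$lr, grid$ld)
  best <- grid[which.min(sse), ]
  ref <- stats::optim(c(best$lr, best$ld),
                      function(p) sse_of(max(p[1], 1e-8), max(p[2], 0)),
                      method = "Nelder-Mead")
  lr <- max(ref$par[1], 1e-8); ld <- max(ref$par[2], 0)
  f <- (1 - exp(-lr * t)) * exp(-ld * t)
  c(A0 = max(0, sum(f * y) / sum(f * f)), lambda_r = lr, lambda_d = ld)
}

# Hand product-limit Kaplan-Meier estimator (no survival package).
oracle_km <- function(time, event) {
  o <- order(time)
  time <- time[o]; event <- event[o]
  ut <- unique(time[event == 1])
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (tt in ut) {
    at_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / at_risk)
    out <- rbind(out, data.frame(time = tt, surv = s))
  }
  out
}

# Hand normal-equations solution of a simple linear regression.
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
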