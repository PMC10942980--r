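# Independent EM-REML oracle for the random-intercept model
#   y = X beta + Z alpha + e,  alpha ~ N(0, s2b I_q),  e ~ N(0, s2e I_n).
# EM updates (P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1):
#   s2b <- s2b + (s2b^2 / q) * (y' P Z Z' P y - tr(P Z Z'))
#   s2e <- s2e + (s2e^2 / n) * (y' P P y     - tr(P))
# whose fixed point solves the REML score equations; beta by GLS at the
# converged variances. Dense linear algebra only: a deliberately independent
# implementation path from lme4.
em_reml <- function(y, X, group, max_iter = 50000, tol = 1e-13) {
  group <- factor(group)
  Z <- stats::model.matrix(~ group - 1)
  n <- length(y)
  q <- ncol(Z)
  A <- Z %*% t(Z)
  s2b <- 1
  s2e <- 1
  for (it in seq_len(max_iter)) {
    V <- s2b * A + s2e * diag(n)
    Vi <- solve(V)
    ViX <- Vi %*% X
    P <- Vi - ViX %*% solve(t(X) %*% ViX, t(ViX))
    Py <- P %*% y
    s2b_new <- s2b + (s2b^2 / q) *
      (as.numeric(t(Py) %*% A %*% Py) - sum(diag(P %*% A)))
    s2e_new <- s2e + (s2e^2 / n) *
      (as.numeric(t(Py) %*% Py) - sum(diag(P)))
    s2b_new <- max(s2b_new, 1e-12)
    s2e_new <- max(s2e_new, 1e-12)
    done <- abs(s2b_new - s2b) < tol * (s2b + 1e-12) &&
      abs(s2e_new - s2e) < tol * (s2e + 1e-12)
    s2b <- s2b_new
    s2e <- s2e_new
    if (done) break
  }
  V <- s2b * A + s2e * diag(n)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  list(beta = as.numeric(beta), s2b = s2b, s2e = s2e, iterations = it)
}

# Printed 3-group fixture used by the mixed-model oracle tests.
lmm_fixture <- function() {
  data.frame(
    participant_id = rep(c("A", "B", "C"), each = 4),
    x1 = c(1.3710, -0.5647, 0.3631, 0.6329, 0.4043, -0.1061, 1.5115,
           -0.0947, 2.0184, -0.0627, 1.3049, 2.2866),
    x2 = c(-1.3889, -0.2788, -0.1333, 0.6360, -0.2843, -2.6565, -2.4405,
           1.3201, -0.3066, -1.7813, -0.1719, 1.2147),
    y = c(1.6629, -1.2990, -0.6211, -1.4930, 0.9268, 0.9683, 2.5620,
          0.0581, 3.1531, 1.4642, 2.3347, 1.3562))
}
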