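# Shared fixtures, built once per test run. Everything is generated in code;
# the default 22-frame / 60.5-min schedule and the default class kinetics
# are the reference conditions used across test files.

sch_fx <- default_frame_schedule()
grid_fx <- seq(0, 3630.5, by = 0.5) # fine grid covering the scan
ip_fx <- input_function_params()
templates_fx <- make_class_templates(schedule = sch_fx)
cr_fx <- templates_fx$raw_tacs$gray_nonspecific        # frame-level reference
cr_fine_fx <- templates_fx$fine_tacs$gray_nonspecific  # fine-grid reference
blood_fine_fx <- whole_blood(ip_fx, grid_fx)
blood_fx <- frame_average(blood_fine_fx, sch_fx)
basis_fx <- make_basis(cr_fx, sch_fx)

# largest bp_nd change induced by moving one theta3 grid step at fixed k2
grid_step_bp_tol <- function(basis, bp_true) {
  ratio <- basis$theta3_grid[2] / basis$theta3_grid[1]
  (1 + bp_true) * (ratio - 1)
}

# independent convolution oracle: trapezoid sum of f(s) * exp(-theta (t-s)),
# f taken piecewise linear on its grid and resampled to a 0.02-s step;
# theta in 1/min, times in seconds
conv_oracle <- function(grid_s, values, theta, eval_s, dt_s = 0.02) {
  fine <- seq(0, max(eval_s), by = dt_s)
  f <- approx(grid_s, values, xout = fine, rule = 2)$y
  dt_min <- dt_s / 60
  vapply(eval_s, function(t) {
    k <- which.min(abs(fine - t))
    w <- rep(1, k)
    w[c(1, k)] <- 0.5
    sum(w * f[1:k] * exp(-theta * (t - fine[1:k]) / 60)) * dt_min
  }, numeric(1))
}

# brute-force NNLS oracle: try every support subset, solve unconstrained LS
# on it, keep the feasible solution with smallest RSS
nnls_bruteforce <- function(A, y) {
  p <- ncol(A)
  best <- list(rss = Inf, x = rep(0, p))
  for (code in 0:(2^p - 1)) {
    S <- which(bitwAnd(code, 2^(0:(p - 1))) > 0)
    x <- rep(0, p)
    if (length(S) > 0) {
      cf <- qr.coef(qr(A[, S, drop = FALSE]), y)
      cf[is.na(cf)] <- 0
      if (any(cf < -1e-12)) next
      x[S] <- cf
    }
    rss <- sum((y - A %*% x)^2)
    if (rss < best$rss - 1e-12) best <- list(rss = rss, x = x)
  }
  best$x
}

# Wilks lambda oracle from residual SSCP determinant ratio
wilks_oracle <- function(Y, group, age) {
  full <- stats::lm(Y ~ group + age)
  red <- stats::lm(Y ~ age)
  E <- crossprod(stats::residuals(full))
  H <- crossprod(stats::residuals(red)) - E
  det(E) / det(E + H)
}
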