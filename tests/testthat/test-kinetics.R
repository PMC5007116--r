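test_that("plasma input is zero before bolus arrival and decays late", {
  cp <- plasma_input(ip_fx, c(0, 10, 20, 29.9))
  expect_equal(cp$values, rep(0, 4)) # delay = 0.5 min
  cp2 <- plasma_input(ip_fx, c(5 * 60 + 30, 60 * 60 + 30))
  expect_lt(cp2$values[2], cp2$values[1]) # tail at 60 min below 5 min
  expect_error(plasma_input(ip_fx, c(10, 5)), "increasing")
  expect_error(input_function_params(lam1 = 0.1, lam2 = 0.2), "lam1 > lam2")
  expect_error(input_function_params(A2 = -1), "non-negative")
})

test_that("plasma peak location matches a dense-grid evaluation oracle", {
  t_dense <- seq(0, 300, by = 0.1)
  # independent re-evaluation of the tri-exponential bolus form
  tau <- t_dense / 60 - ip_fx$delay
  v <- with(ip_fx, (A1 * tau - A2 - A3) * exp(-lam1 * tau) +
              A2 * exp(-lam2 * tau) + A3 * exp(-lam3 * tau))
  v[tau <= 0] <- 0
  cp <- plasma_input(ip_fx, t_dense)
  expect_equal(cp$times[which.max(cp$values)],
               t_dense[which.max(v)], tolerance = 1e-12)
})

test_that("two-tissue model reduces to closed forms in limit cases", {
  p0 <- tissue_kinetic_params(K1 = 0, k2t = 0.1)
  cp <- plasma_input(ip_fx, grid_fx)
  expect_equal(two_tissue_tac(cp, p0, sch_fx$frame_mid)$values, rep(0, 22))

  # k3 = k4 = 0: one-tissue K1 * (Cp (x) exp(-k2t t)), independent
  # trapezoid-sum convolution oracle
  p1 <- tissue_kinetic_params(K1 = 0.3, k2t = 0.15)
  ct <- two_tissue_tac(cp, p1, sch_fx$frame_mid)
  oracle <- 0.3 * conv_oracle(grid_fx, cp$values, 0.15, sch_fx$frame_mid)
  keep <- oracle > 1e-3 * max(oracle)
  expect_lt(max(abs(ct$values[keep] - oracle[keep]) / oracle[keep]), 1e-6)

  expect_error(tissue_kinetic_params(K1 = -1, k2t = 0.1), ">= 0")
  expect_error(tissue_kinetic_params(K1 = 1, k2t = 0.1, vb = 1), "vb")
})

test_that("two-tissue solution matches a fine-step ODE oracle", {
  skip_if_not_installed("deSolve")
  p <- tissue_kinetic_params(K1 = 0.30, k2t = 0.15, k3 = 0.15, k4 = 0.30,
                             vb = 0.05)
  cp <- plasma_input(ip_fx, grid_fx)
  ct <- two_tissue_tac(cp, p, sch_fx$frame_mid, cb = cp)
  # integrate in minutes: rate constants are per minute
  cpf <- approxfun(cp$times / 60, cp$values, rule = 2)
  # fixed-step RK4 with steps aligned to the input's 0.5-s kinks
  h <- 0.5 / 60 / 4
  de <- deSolve::ode(
    c(C1 = 0, C2 = 0), seq(0, 60.5, by = h),
    function(t, y, parms) {
      cpv <- cpf(t)
      list(c(p$K1 * cpv - (p$k2t + p$k3) * y[1] + p$k4 * y[2],
             p$k3 * y[1] - p$k4 * y[2]))
    }, NULL, method = "rk4")
  tot <- approx(de[, 1] * 60,
                (1 - p$vb) * (de[, 2] + de[, 3]) + p$vb * cpf(de[, 1]),
                xout = sch_fx$frame_mid)$y
  keep <- tot > 1e-2 * max(tot) # frames after bolus arrival
  expect_lt(max(abs(ct$values[keep] - tot[keep]) / tot[keep]), 1e-4)
})

test_that("SRTM forward model honours its identity and blood limits", {
  # r1 = 1, bp = 0, vb = 0: output IS the reference, bit for bit
  out <- srtm_forward(cr_fx, srtm_params(1, 0.15, 0))
  expect_identical(out$values, cr_fx$values)

  # vb -> 1: pure blood voxel
  out_b <- srtm_forward(cr_fx, srtm_params(1, 0.15, 0.5, vb = 1 - 1e-12),
                        cb = blood_fx)
  expect_equal(out_b$values, blood_fx$values, tolerance = 1e-9)

  expect_error(srtm_forward(cr_fx, srtm_params(1, 0.15, 0, vb = 0.05)),
               "blood")
  bad_cb <- tac(cr_fx$times + 1, cr_fx$values)
  expect_error(srtm_forward(cr_fx, srtm_params(1, 0.15, 0), cb = bad_cb),
               "grid")
})

test_that("SRTM convolution term matches an independent fine-grid oracle", {
  p <- srtm_params(1.0, 0.15, 0.5)
  out <- srtm_forward(cr_fine_fx, p)
  at <- sch_fx$frame_mid
  conv <- conv_oracle(grid_fx, cr_fine_fx$values, p$theta3, at)
  cr_at <- approx(grid_fx, cr_fine_fx$values, xout = at)$y
  o <- p$r1 * cr_at + (p$k2 - p$r1 * p$theta3) * conv
  v <- approx(grid_fx, out$values, xout = at)$y
  keep <- abs(o) > 1e-3 * max(abs(o))
  expect_lt(max(abs(v[keep] - o[keep]) / abs(o[keep])), 1e-5)
})

test_that("frame averaging is exact for constants and linear curves", {
  const <- frame_average(function(t) rep(3.5, length(t)), sch_fx)
  expect_equal(const$values, rep(3.5, 22))
  lin <- frame_average(function(t) 0.01 * t, sch_fx)
  expect_equal(lin$values, 0.01 * sch_fx$frame_mid, tolerance = 1e-12)
})

test_that("frame averaging matches a 0.01-s Riemann oracle on a bolus", {
  f <- function(t) {
    tau <- t / 60
    (300 * tau) * exp(-4 * tau) + 1.5 * exp(-0.25 * tau) +
      0.8 * exp(-0.012 * tau)
  }
  got <- frame_average(f, sch_fx)
  oracle <- vapply(seq_len(22), function(i) {
    tt <- seq(sch_fx$frame_start[i],
              sch_fx$frame_start[i] + sch_fx$frame_duration[i], by = 0.01)
    mean(f(tt[-1] / 2 + tt[-length(tt)] / 2)) # midpoint Riemann sum
  }, numeric(1))
  expect_lt(max(abs(got$values - oracle) / oracle), 1e-6)
})

test_that("frame averaging commutes with curve scaling", {
  x <- tac(grid_fx, pmax(sin(grid_fx / 500), 0) + 0.1)
  a <- frame_average(x, sch_fx)
  b <- frame_average(tac(grid_fx, 7 * x$values), sch_fx)
  expect_equal(b$values, 7 * a$values, tolerance = 1e-12)
  short <- tac(c(0, 100), c(1, 1))
  expect_error(frame_average(short, sch_fx), "cover")
})

test_that("noise model is reproducible and matches its stated SD", {
  expect_identical(add_noise(cr_fx, sch_fx, 0, 1)$values, cr_fx$values)
  n1 <- add_noise(cr_fx, sch_fx, 0.3, 99)
  n2 <- add_noise(cr_fx, sch_fx, 0.3, 99)
  expect_identical(n1$values, n2$values)
  expect_false(identical(add_noise(cr_fx, sch_fx, 0.3, 100)$values,
                         n1$values))
  expect_error(add_noise(cr_fx, sch_fx, -0.1, 1), "non-negative")

  # Monte-Carlo check of the SD formula on a single late frame
  one <- frame_schedule(0, 300)
  val <- tac(150, 2.0)
  draws <- vapply(1:10000, function(s) {
    add_noise(val, one, 0.5, s)$values - 2.0
  }, numeric(1))
  sd_formula <- 0.5 * sqrt(2.0 / (300 * 2^(-(150 / 60) / 20.4)))
  expect_lt(abs(sd(draws) - sd_formula) / sd_formula, 0.03)
})

test_that("stochastic ops leave the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(add_noise(cr_fx, sch_fx, 0.3, 42))
  invisible(sample_cohort(cohort_spec(), 42))
  expect_identical(.Random.seed, before)
})

test_that("two-tissue output stays non-negative for non-negative inputs", {
  cp <- plasma_input(ip_fx, grid_fx)
  set.seed(7)
  for (i in 1:20) {
    p <- tissue_kinetic_params(K1 = runif(1, 0.05, 0.5),
                               k2t = runif(1, 0.02, 0.3),
                               k3 = runif(1, 0, 0.2),
                               k4 = runif(1, 0.05, 0.4),
                               vb = runif(1, 0, 0.2))
    ct <- two_tissue_tac(cp, p, sch_fx$frame_mid, cb = cp)
    expect_gte(min(ct$values), -1e-10)
  }
})
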