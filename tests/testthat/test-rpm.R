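test_that("basis curves behave like the convolution they encode", {
  expect_true(all(basis_fx$basis_curves >= 0))
  expect_true(all(diff(basis_fx$theta3_grid) > 0))
  # log spacing: constant ratio
  r <- basis_fx$theta3_grid[-1] / basis_fx$theta3_grid[-64]
  expect_lt(max(r) - min(r), 1e-12)

  # large theta3: B(t) ~ Cr(t) / theta3 at late frames
  big <- make_basis(cr_fx, sch_fx, theta3_min = 6, theta3_max = 12,
                    n_basis = 2)
  late <- 19:22
  expect_lt(max(abs(big$basis_curves[1, late] -
                      cr_fx$values[late] / 6) /
                  (cr_fx$values[late] / 6)), 0.05)

  # small theta3: independent trapezoid-sum convolution oracle
  th <- 0.006
  crg <- approx(c(0, cr_fx$times), c(0, cr_fx$values), xout = grid_fx,
                rule = 2)$y
  conv <- conv_oracle(grid_fx, crg, th, grid_fx)
  oracle <- frame_average(tac(grid_fx, conv), sch_fx)$values
  got <- basis_fx$basis_curves[1, ]
  expect_lt(max(abs(got - oracle) / pmax(abs(oracle), 1e-6)), 1e-5)

  expect_error(make_basis(cr_fx, sch_fx, theta3_min = -1), "positive")
  expect_error(make_basis(cr_fx, sch_fx, n_basis = 1), "n_basis")
})

test_that("fitting the reference against itself returns the identity", {
  f <- fit_srtm_vb(cr_fx, basis_fx, blood_fx)
  expect_equal(f$r1, 1, tolerance = 1e-6)
  expect_equal(f$bp_nd, 0, tolerance = 1e-6)
  expect_equal(f$vb, 0, tolerance = 1e-6)
})

test_that("noiseless SRTM targets are recovered within grid tolerance", {
  p <- srtm_params(1.0, 0.15, 0.5, vb = 0.05)
  target <- srtm_frame_tac(cr_fine_fx, p, sch_fx, cb = blood_fine_fx)
  f <- fit_srtm_vb(target, basis_fx, blood_fx, rescale_vb = TRUE)
  expect_lt(abs(f$bp_nd - 0.5), grid_step_bp_tol(basis_fx, 0.5))
  expect_lt(abs(f$vb - 0.05), 0.005)

  # default (unscaled) convention shrinks bp by vb * (1 + bp)
  f0 <- fit_srtm_vb(target, basis_fx, blood_fx)
  expect_lt(abs(f0$bp_nd - (0.5 - 0.05 * 1.5)),
            grid_step_bp_tol(basis_fx, 0.5))
})

test_that("a two-tissue target with no specific binding fits bp ~ 0", {
  cp <- plasma_input(ip_fx, grid_fx)
  # same delivery, efflux, and blood fraction as the reference class
  p <- tissue_kinetic_params(K1 = 0.30, k2t = 0.15, vb = 0.05)
  target <- frame_average(two_tissue_tac(cp, p, grid_fx, cb = cp), sch_fx)
  f <- fit_srtm_vb(target, basis_fx, blood_fx)
  expect_lt(abs(f$bp_nd), 0.02)
})

test_that("degenerate and boundary fits are flagged", {
  zero <- tac(sch_fx$frame_mid, rep(0, 22))
  f <- fit_srtm_vb(zero, basis_fx, blood_fx)
  expect_equal(f$status, "degenerate")
  expect_true(is.na(f$bp_nd))

  # very fast washout forces theta3 to the upper grid edge
  narrow <- make_basis(cr_fx, sch_fx, theta3_min = 0.006, theta3_max = 0.02,
                       n_basis = 8)
  p <- srtm_params(1.0, 0.15, 0.2)
  target <- srtm_frame_tac(cr_fine_fx, p, sch_fx)
  fb <- fit_srtm_vb(target, narrow, blood_fx)
  expect_equal(fb$status, "boundary")
})

test_that("fits are scale invariant", {
  p <- srtm_params(0.9, 0.12, 0.3, vb = 0.04)
  target <- srtm_frame_tac(cr_fine_fx, p, sch_fx, cb = blood_fine_fx)
  f1 <- fit_srtm_vb(target, basis_fx, blood_fx)
  c <- 3.7
  basis_s <- make_basis(tac(cr_fx$times, c * cr_fx$values), sch_fx)
  f2 <- fit_srtm_vb(tac(target$times, c * target$values), basis_s,
                    tac(blood_fx$times, c * blood_fx$values))
  expect_equal(f2$bp_nd, f1$bp_nd, tolerance = 1e-8)
  expect_equal(f2$r1, f1$r1, tolerance = 1e-8)
  expect_equal(f2$k2, f1$k2, tolerance = 1e-8)
  expect_equal(f2$vb, f1$vb, tolerance = 1e-8)
})

test_that("refining the theta3 grid never increases the minimal RSS", {
  set.seed(21)
  coarse <- make_basis(cr_fx, sch_fx, n_basis = 16)
  fine <- make_basis(cr_fx, sch_fx, n_basis = 31) # superset of the 16
  expect_true(all(sapply(coarse$theta3_grid, function(th) {
    min(abs(fine$theta3_grid - th)) < 1e-12
  })))
  for (i in 1:10) {
    p <- srtm_params(runif(1, 0.7, 1.2), runif(1, 0.08, 0.25),
                     runif(1, 0, 0.8))
    target <- srtm_frame_tac(cr_fine_fx, p, sch_fx)
    target <- add_noise(target, sch_fx, 0.2, 300 + i)
    rc <- fit_srtm_vb(target, coarse, blood_fx)$rss
    rf <- fit_srtm_vb(target, fine, blood_fx)$rss
    expect_lte(rf, rc + 1e-12)
  }
})

test_that("disabling the vascular term gives the plain SRTM fit", {
  p <- srtm_params(1.0, 0.15, 0.4)
  target <- add_noise(srtm_frame_tac(cr_fine_fx, p, sch_fx), sch_fx,
                      0.1, 17)
  f_novasc <- fit_srtm_vb(target, basis_fx, blood_fx, vascular = FALSE)
  f_plain <- fit_srtm_vb(target, basis_fx)
  expect_identical(f_novasc$bp_nd, f_plain$bp_nd)
  expect_identical(f_novasc$rss, f_plain$rss)
  expect_identical(f_novasc$vb, 0)
})

test_that("ROI-level bp recovery stays unbiased across noise levels", {
  tol0 <- 0.02 + grid_step_bp_tol(basis_fx, 0.5)
  for (bp in c(0, 0.15, 0.5)) {
    target <- srtm_frame_tac(cr_fine_fx,
                             srtm_params(1, 0.15, bp, vb = 0), sch_fx)
    for (alpha in c(0, 0.1, 0.3)) {
      nrep <- if (alpha == 0) 1 else 100
      est <- vapply(seq_len(nrep), function(k) {
        y <- add_noise(target, sch_fx, alpha, 5000 + 100 * k)
        fit_srtm_vb(y, basis_fx, blood_fx)$bp_nd
      }, numeric(1))
      bias <- abs(mean(est) - bp)
      if (alpha == 0) expect_lt(bias, tol0) else expect_lt(bias, 0.05)
    }
  }
})

test_that("parametric maps recover phantom truth voxelwise", {
  ph <- make_phantom(phantom_spec(alpha = 0, seed = 5))
  sv <- extract_reference(ph, templates_fx)
  pm <- parametric_map(ph, sv$reference_tac, blood_fx)
  err <- abs(pm$bp_nd[ph$class_map == 1L] - 0.5)
  expect_lte(median(err), 0.02)
  expect_true(all(pm$vb[ph$class_map == 4L] >= 0.9))
  expect_true(all(is.na(pm$bp_nd[ph$class_map == 0L])))

  one <- array(0, dim = dim(ph$class_map))
  one[16, 16, 8] <- 1
  pm1 <- parametric_map(ph$image, sv$reference_tac, blood_fx, mask = one,
                        schedule = sch_fx)
  expect_equal(sum(!is.na(pm1$bp_nd)), 1)
})
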