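#' Per-frame fit weights
#'
#' Default weights are proportional to frame duration times the physical
#' decay factor, `duration * 2^(-t / 20.4 min)` — a standard surrogate for
#' inverse noise variance of decay-corrected, reconstructed PET frames.
#'
#' @param schedule A [frame_schedule()].
#' @param type `"duration_decay"` (default) or `"uniform"`.
#' @param half_life_min Isotope half-life in minutes (C-11 default).
#' @return Numeric weight vector, scaled to mean 1.
#' @export
frame_weights <- function(schedule, type = c("duration_decay", "uniform"),
                          half_life_min = 20.4) {
  type <- match.arg(type)
  n <- n_frames(schedule)
  w <- if (type == "uniform") {
    rep(1, n)
  } else {
    (schedule$frame_duration / 60) *
      2^(-(schedule$frame_mid / 60) / half_life_min)
  }
  w / mean(w)
}

#' Build the SRTM basis set
#'
#' Basis functions \eqn{B_j(t) = (C_r \otimes e^{-\theta_3^{(j)} t})(t)} for
#' a logarithmically spaced grid of washout rates `theta3`, each computed by
#' exact piecewise-linear convolution of the reference curve on a fine
#' internal grid and then frame-averaged. Convolutions are in minutes, so
#' `k2 * B` has the units of the reference curve.
#'
#' @param reference Reference-tissue [tac()] at the frame mid-times.
#' @param schedule A [frame_schedule()].
#' @param theta3_min,theta3_max Positive grid bounds (1/min). The default
#'   range 0.006-0.6 brackets `k2 / (1 + BP_ND)` for plausible
#'   first-generation TSPO-tracer kinetics.
#' @param n_basis Number of grid points (>= 2), default 64.
#' @param dt_s Internal convolution grid step (seconds).
#' @return An object of class `basis_set`: `theta3_grid`, `basis_curves`
#'   (n_basis x n_frames), `reference_tac`, `schedule`.
#' @export
make_basis <- function(reference, schedule, theta3_min = 0.006,
                       theta3_max = 0.6, n_basis = 64L, dt_s = 0.5) {
  stopifnot(inherits(reference, "tac"), inherits(schedule, "frame_schedule"))
  if (theta3_min <= 0 || theta3_max <= 0) {
    stop("theta3 bounds must be positive")
  }
  if (theta3_min >= theta3_max) stop("theta3_min must be < theta3_max")
  if (n_basis < 2) stop("n_basis must be >= 2")
  if (length(reference$times) != n_frames(schedule)) {
    stop("reference must be sampled at the schedule's frame mid-times")
  }
  theta3 <- exp(seq(log(theta3_min), log(theta3_max), length.out = n_basis))
  grid <- fine_grid(scan_end(schedule), dt_s)
  ref_fine <- tac_interp(reference, grid)
  B <- matrix(0, nrow = n_basis, ncol = n_frames(schedule))
  for (j in seq_len(n_basis)) {
    conv <- conv_exp(ref_fine, dt_s / 60, theta3[j])
    B[j, ] <- frame_average(tac(grid, conv), schedule)$values
  }
  structure(
    list(theta3_grid = theta3, basis_curves = B,
         reference_tac = reference, schedule = schedule),
    class = "basis_set"
  )
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> %d theta3 values in [%.4g, %.4g]/min, %d frames\n",
              length(x$theta3_grid), min(x$theta3_grid), max(x$theta3_grid),
              ncol(x$basis_curves)))
  invisible(x)
}

# Core weighted basis-function solve for a matrix of target TACs.
# Y: n_frames x n_targets. Returns per-target parameter vectors.
rpm_solve <- function(Y, basis, blood = NULL, weights = NULL,
                      vascular = !is.null(blood), rescale_vb = FALSE) {
  nf <- ncol(basis$basis_curves)
  stopifnot(nrow(Y) == nf)
  if (is.null(weights)) weights <- frame_weights(basis$schedule)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (vascular) {
    stopifnot(inherits(blood, "tac"))
    if (length(blood$values) != nf) {
      stop("blood curve must be on the basis frame grid")
    }
  }
  sw <- sqrt(weights)
  Yw <- Y * sw
  cr <- basis$reference_tac$values
  nb <- length(basis$theta3_grid)
  nt <- ncol(Y)
  p <- if (vascular) 3L else 2L

  rss <- matrix(NA_real_, nb, nt)
  coefs <- array(NA_real_, dim = c(nb, p, nt))
  for (j in seq_len(nb)) {
    X <- if (vascular) {
      cbind(cr, basis$basis_curves[j, ], blood$values)
    } else {
      cbind(cr, basis$basis_curves[j, ])
    }
    Xw <- X * sw
    qrx <- qr(Xw)
    cf <- qr.coef(qrx, Yw)
    cf[is.na(cf)] <- 0
    res <- Yw - Xw %*% cf
    rss[j, ] <- colSums(res^2)
    coefs[j, , ] <- cf
  }
  best <- apply(rss, 2, which.min) # ties: smallest theta3 index
  idx <- cbind(best, seq_len(nt))
  th1 <- coefs[cbind(best, 1L, seq_len(nt))]
  th2 <- coefs[cbind(best, 2L, seq_len(nt))]
  thv <- if (vascular) coefs[cbind(best, 3L, seq_len(nt))] else rep(0, nt)
  theta3 <- basis$theta3_grid[best]
  vb <- pmin(pmax(thv, 0), 1 - 1e-12)
  if (rescale_vb) {
    th1 <- th1 / (1 - vb)
    th2 <- th2 / (1 - vb)
  }
  k2 <- th2 + th1 * theta3
  list(
    r1 = th1, k2 = k2, theta3 = theta3,
    bp_nd = k2 / theta3 - 1,
    vb = vb,
    rss = rss[idx], theta3_index = best,
    boundary = best == 1L | best == nb,
    rss_all = rss
  )
}

#' Fit one TAC with the vascular-corrected basis-function SRTM (RPM-Vb)
#'
#' For every `theta3` on the basis grid, solves the weighted linear model
#' \deqn{C_T \approx \theta_1 C_r + \theta_2 B_{\theta_3} + \theta_v C_b}
#' and keeps the `theta3` with minimal weighted residual sum of squares
#' (ties broken towards the smallest grid value). Reported parameters are
#' `r1 = theta1`, `k2 = theta2 + theta1 * theta3`,
#' `bp_nd = k2 / theta3 - 1`, and `vb = theta_v` clamped to `[0, 1)`.
#' With `vascular = FALSE` the blood column is dropped and the fit is the
#' plain basis-function SRTM.
#'
#' By default the tissue parameters are taken from `theta1`, `theta2`
#' directly, so when the data truly follow
#' `(1 - vb) * SRTM + vb * blood` the reported `bp_nd` is shrunk by
#' `vb * (1 + bp_nd)`; `rescale_vb = TRUE` divides `theta1`, `theta2` by
#' `(1 - vb)` first, undoing that shrinkage.
#'
#' @param target Target [tac()] on the basis frame grid.
#' @param basis A [make_basis()] object.
#' @param blood Whole-blood [tac()] on the same grid (required when
#'   `vascular = TRUE`).
#' @param weights Per-frame weights; default [frame_weights()] of the basis
#'   schedule.
#' @param vascular Include the vascular term (default `TRUE` when `blood`
#'   is given).
#' @param rescale_vb Rescale tissue parameters by `1 / (1 - vb)` (default
#'   `FALSE`).
#' @return An object of class `fit_result` with fields `r1`, `k2`,
#'   `theta3`, `bp_nd`, `vb`, `rss`, `theta3_index`, and `status` (one of
#'   `"ok"`, `"boundary"`, `"degenerate"`). An all-zero target is
#'   degenerate and returns `NA` parameters.
#' @export
fit_srtm_vb <- function(target, basis, blood = NULL, weights = NULL,
                        vascular = !is.null(blood), rescale_vb = FALSE) {
  stopifnot(inherits(target, "tac"), inherits(basis, "basis_set"))
  if (length(target$values) != ncol(basis$basis_curves)) {
    stop("target must be on the basis frame grid")
  }
  if (all(target$values == 0)) {
    return(structure(list(r1 = NA_real_, k2 = NA_real_, theta3 = NA_real_,
                          bp_nd = NA_real_, vb = NA_real_, rss = 0,
                          theta3_index = NA_integer_, status = "degenerate"),
                     class = "fit_result"))
  }
  s <- rpm_solve(matrix(target$values, ncol = 1), basis, blood, weights,
                 vascular, rescale_vb)
  structure(
    list(r1 = s$r1, k2 = s$k2, theta3 = s$theta3, bp_nd = s$bp_nd,
         vb = s$vb, rss = s$rss, theta3_index = s$theta3_index,
         status = if (s$boundary) "boundary" else "ok"),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> bp_nd = %.4f, r1 = %.4f, k2 = %.4f/min, vb = %.4f (%s)\n",
    x$bp_nd, x$r1, x$k2, x$vb, x$status))
  invisible(x)
}

#' Voxelwise RPM-Vb parametric maps
#'
#' Applies [fit_srtm_vb()] to every in-mask voxel of a dynamic image and
#' assembles BP_ND, R1, k2 and Vb parametric maps (out-of-mask voxels are
#' `NA`), plus an integer status map (0 ok, 1 theta3 at a grid boundary,
#' 2 degenerate all-zero voxel).
#'
#' @param image 4D array (x, y, z, frame) or a [make_phantom()] object.
#' @param reference Reference [tac()] (e.g. from [extract_reference()]).
#' @param blood Whole-blood [tac()] on the frame grid, or `NULL` to fit
#'   without the vascular term.
#' @param mask 3D brain mask (defaults to the phantom's own mask).
#' @param schedule A [frame_schedule()] (defaults to the phantom's).
#' @param weights Per-frame weights; default [frame_weights()].
#' @param theta3_min,theta3_max,n_basis Basis-grid settings, see
#'   [make_basis()].
#' @param rescale_vb See [fit_srtm_vb()].
#' @return An object of class `parametric_maps`: 3D arrays `bp_nd`, `r1`,
#'   `k2`, `vb`, `rss`, integer `status`, plus the `basis` used.
#' @export
parametric_map <- function(image, reference, blood = NULL, mask = NULL,
                           schedule = NULL, weights = NULL,
                           theta3_min = 0.006, theta3_max = 0.6,
                           n_basis = 64L, rescale_vb = FALSE) {
  if (inherits(image, "dynamic_phantom")) {
    if (is.null(mask)) mask <- image$mask
    if (is.null(schedule)) schedule <- image$schedule
    image <- image$image
  }
  if (is.null(mask) || is.null(schedule)) {
    stop("mask and schedule are required for a raw array input")
  }
  stopifnot(inherits(reference, "tac"))
  if (dim(image)[4] != n_frames(schedule)) {
    stop("image frame count does not match the schedule")
  }
  basis <- make_basis(reference, schedule, theta3_min, theta3_max, n_basis)
  masked <- apply_anatomical_mask(image, mask)
  Y <- t(masked$tacs)
  nonzero <- colSums(Y != 0) > 0
  s <- rpm_solve(Y[, nonzero, drop = FALSE], basis, blood, weights,
                 vascular = !is.null(blood), rescale_vb = rescale_vb)

  d3 <- dim(mask)
  nv <- prod(d3)
  put <- function(vals) {
    v <- rep(NA_real_, nv)
    full <- rep(NA_real_, masked$n)
    full[nonzero] <- vals
    v[masked$voxels] <- full
    array(v, dim = d3)
  }
  status <- rep(NA_integer_, nv)
  st <- rep(2L, masked$n)
  st[nonzero] <- ifelse(s$boundary, 1L, 0L)
  status[masked$voxels] <- st

  structure(
    list(bp_nd = put(s$bp_nd), r1 = put(s$r1), k2 = put(s$k2),
         vb = put(s$vb), rss = put(s$rss),
         status = array(status, dim = d3), basis = basis),
    class = "parametric_maps"
  )
}

#' @export
print.parametric_maps <- function(x, ...) {
  ok <- sum(x$status == 0L, na.rm = TRUE)
  cat(sprintf("<parametric_maps> %s voxels fitted ok; median BP_ND = %.3f\n",
              format(ok, big.mark = ","),
              stats::median(x$bp_nd, na.rm = TRUE)))
  invisible(x)
}
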