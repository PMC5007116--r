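#' Tri-exponential bolus input function parameters
#'
#' Parameters of the standard tri-exponential arterial input model
#' \deqn{C_p(\tau) = (A_1 \tau - A_2 - A_3) e^{-\lambda_1 \tau} +
#'   A_2 e^{-\lambda_2 \tau} + A_3 e^{-\lambda_3 \tau}, \quad \tau = t - delay}
#' which rises from zero at bolus arrival, peaks within a minute, and decays
#' with two slower exponentials. Rates are per minute, amplitudes in kBq/mL
#' (A1 in kBq/mL/min).
#'
#' @param A1,A2,A3 Amplitudes; `A2`, `A3` must be non-negative.
#' @param lam1,lam2,lam3 Decay rates (1/min), strictly ordered
#'   `lam1 > lam2 > lam3 > 0`.
#' @param delay Bolus arrival time (minutes).
#' @return An object of class `input_function_params`.
#' @export
input_function_params <- function(A1 = 300, A2 = 1.5, A3 = 0.8,
                                  lam1 = 4, lam2 = 0.25, lam3 = 0.012,
                                  delay = 0.5) {
  if (!(lam1 > lam2 && lam2 > lam3 && lam3 > 0)) {
    stop("input function rates must satisfy lam1 > lam2 > lam3 > 0")
  }
  if (A2 < 0 || A3 < 0) stop("A2 and A3 must be non-negative")
  structure(list(A1 = A1, A2 = A2, A3 = A3,
                 lam1 = lam1, lam2 = lam2, lam3 = lam3, delay = delay),
            class = "input_function_params")
}

#' Evaluate the plasma input function
#'
#' @param params An [input_function_params()].
#' @param t Sorted, non-negative time points (seconds).
#' @return A [tac()] of plasma activity concentration (kBq/mL); zero before
#'   bolus arrival, clipped at zero from below.
#' @export
plasma_input <- function(params, t) {
  stopifnot(inherits(params, "input_function_params"))
  t <- as.numeric(t)
  if (any(t < 0)) stop("t must be non-negative")
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  tau <- t / 60 - params$delay # minutes since bolus arrival
  v <- with(params,
            (A1 * tau - A2 - A3) * exp(-lam1 * tau) +
              A2 * exp(-lam2 * tau) + A3 * exp(-lam3 * tau))
  v[tau <= 0] <- 0
  tac(t, pmax(v, 0))
}

#' Whole-blood curve
#'
#' The simulator takes the whole-blood activity equal to the plasma input
#' (no metabolite or plasma-to-whole-blood partitioning is modelled); kept as
#' a named entry point so a distinct blood model can be slotted in.
#'
#' @inheritParams plasma_input
#' @return A [tac()].
#' @export
whole_blood <- function(params, t) plasma_input(params, t)

#' Two-tissue compartment model parameters
#'
#' Standard 2TC rate constants: `K1` (mL/cm3/min) plasma-to-tissue delivery,
#' `k2t` (1/min) tissue-to-plasma efflux, `k3`/`k4` (1/min) exchange with the
#' specifically bound compartment, `vb` fractional blood volume. Specific
#' binding enters through `k3/k4` (BP_ND = k3/k4).
#'
#' @param K1,k2t,k3,k4 Non-negative rate constants.
#' @param vb Fractional blood volume in `[0, 1)`.
#' @return An object of class `tissue_kinetic_params`.
#' @export
tissue_kinetic_params <- function(K1, k2t, k3 = 0, k4 = 0, vb = 0) {
  if (any(c(K1, k2t, k3, k4) < 0)) stop("rate constants must be >= 0")
  if (vb < 0 || vb >= 1) stop("vb must lie in [0, 1)")
  if (k3 > 0 && k4 == 0) stop("k3 > 0 requires k4 > 0 (reversible binding)")
  structure(list(K1 = K1, k2t = k2t, k3 = k3, k4 = k4, vb = vb),
            class = "tissue_kinetic_params")
}

# True binding potential of a 2TC parameter set.
bpnd_2tc <- function(params) {
  if (params$k4 == 0) 0 else params$k3 / params$k4
}

#' Simplified reference tissue model parameters
#'
#' SRTM parameters: `r1` = R1, the target/reference delivery ratio; `k2`
#' (1/min) the target efflux rate; `bp_nd` the non-displaceable binding
#' potential; `vb` a fractional blood volume for the vascular-corrected
#' variant. The washout rate `theta3 = k2 / (1 + bp_nd)` is stored for
#' convenience and kept consistent by construction.
#'
#' @param r1 Delivery ratio (unitless).
#' @param k2 Efflux rate (1/min), must give `theta3 > 0`.
#' @param bp_nd Binding potential (unitless, > -1).
#' @param vb Fractional blood volume in `[0, 1)`.
#' @return An object of class `srtm_params`.
#' @export
srtm_params <- function(r1, k2, bp_nd, vb = 0) {
  if (bp_nd <= -1) stop("bp_nd must be > -1")
  theta3 <- k2 / (1 + bp_nd)
  if (theta3 <= 0) stop("theta3 = k2/(1 + bp_nd) must be positive")
  if (vb < 0 || vb >= 1) stop("vb must lie in [0, 1)")
  structure(list(r1 = r1, k2 = k2, theta3 = theta3, bp_nd = bp_nd, vb = vb),
            class = "srtm_params")
}

# Exact convolution of a piecewise-linear curve with exp(-theta * t).
# `values` sampled on a uniform grid with step `dt` (minutes); `theta` in
# 1/min. Returns the convolution in kBq/mL * min at the same grid points.
# Exactness for piecewise-linear inputs makes the result independent of any
# quadrature rule.
conv_exp <- function(values, dt, theta) {
  n <- length(values)
  out <- numeric(n)
  if (n < 2) return(out)
  if (theta * dt < 1e-12) {
    # theta ~ 0: running trapezoid integral
    return(c(0, cumsum((values[-n] + values[-1]) / 2 * dt)))
  }
  E <- exp(-theta * dt)
  # int_0^dt (f0 + (f1-f0) u/dt) e^{-theta (dt-u)} du
  I0 <- (1 - E) / theta
  I1 <- (dt - I0) / theta
  w1 <- I1 / dt           # weight of f1
  w0 <- I0 - w1           # weight of f0
  # recursion out[i+1] = E * out[i] + w0 f[i] + w1 f[i+1], run in C
  z <- w0 * values[-n] + w1 * values[-1]
  c(0, stats::filter(z, E, method = "recursive"))
}

# Uniform internal grid (seconds) over [0, t_end]; default step 0.5 s.
fine_grid <- function(t_end, dt_s = 0.5) {
  seq(0, t_end + dt_s, by = dt_s)
}

#' Two-tissue compartment forward model
#'
#' Solves the 2TC system
#' \deqn{dC_1/dt = K_1 C_p - (k_{2t} + k_3) C_1 + k_4 C_2, \quad
#'       dC_2/dt = k_3 C_1 - k_4 C_2}
#' analytically via the bi-exponential impulse response (eigen-decomposition
#' of the 2x2 rate matrix) and returns
#' \eqn{C_T = (1 - v_b)(C_1 + C_2) + v_b C_b}. Convolutions use an exact
#' piecewise-linear scheme on a fine internal grid.
#'
#' @param cp Plasma input [tac()], defined on a grid at least as fine as the
#'   internal grid wants to resolve (typically a fine-grid evaluation of
#'   [plasma_input()]).
#' @param params A [tissue_kinetic_params()].
#' @param t Output time points (seconds).
#' @param cb Whole-blood [tac()]; defaults to `cp`.
#' @param dt_s Internal grid step (seconds).
#' @return A [tac()] of tissue activity at `t`.
#' @export
two_tissue_tac <- function(cp, params, t, cb = cp, dt_s = 0.5) {
  stopifnot(inherits(cp, "tac"), inherits(params, "tissue_kinetic_params"))
  t <- as.numeric(t)
  grid <- fine_grid(max(t), dt_s)
  cpg <- tac_interp(cp, grid)
  dt_min <- dt_s / 60

  tissue <- numeric(length(grid))
  if (params$K1 > 0) {
    s <- params$k2t + params$k3 + params$k4
    disc <- sqrt(max(s^2 - 4 * params$k2t * params$k4, 0))
    a1 <- (s - disc) / 2
    a2 <- (s + disc) / 2
    if (disc > 1e-10) {
      # h(t) = K1/(a2-a1) [ (k3+k4-a1) e^{-a1 t} + (a2-k3-k4) e^{-a2 t} ]
      c1 <- params$K1 * (params$k3 + params$k4 - a1) / (a2 - a1)
      c2 <- params$K1 * (a2 - params$k3 - params$k4) / (a2 - a1)
      tissue <- c1 * conv_exp(cpg, dt_min, a1) + c2 * conv_exp(cpg, dt_min, a2)
    } else {
      # repeated eigenvalue: h(t) = K1 e^{-a t} (1 + (k3 + k4 - a) t)
      a <- (a1 + a2) / 2
      base <- conv_exp(cpg, dt_min, a)
      # t-weighted term via derivative trick: conv with t e^{-at} =
      # -d/da conv with e^{-at}; use a small central difference in a
      da <- max(1e-6, a * 1e-6)
      tconv <- (conv_exp(cpg, dt_min, a - da) -
                  conv_exp(cpg, dt_min, a + da)) / (2 * da)
      tissue <- params$K1 * (base + (params$k3 + params$k4 - a) * tconv)
    }
  }
  cbg <- tac_interp(cb, grid)
  ctg <- (1 - params$vb) * tissue + params$vb * cbg
  tac(t, stats::approx(grid, ctg, xout = t, rule = 2)$y)
}

#' Simplified reference tissue model forward curve
#'
#' \deqn{C_T(t) = (1 - v_b)\left[ R_1 C_r(t) +
#'   (k_2 - R_1 \theta_3)(C_r \otimes e^{-\theta_3 t})(t) \right] + v_b C_b(t)}
#' with \eqn{\theta_3 = k_2 / (1 + BP_{ND})}. With `r1 = 1`, `bp_nd = 0` and
#' `vb = 0` the output reproduces the reference curve bit-for-bit.
#'
#' @param cr Reference-tissue [tac()].
#' @param params An [srtm_params()].
#' @param cb Whole-blood [tac()] on the same time grid as `cr`; required when
#'   `vb > 0`.
#' @param dt_s Internal convolution grid step (seconds).
#' @return A [tac()] on the time grid of `cr`.
#' @export
srtm_forward <- function(cr, params, cb = NULL, dt_s = 0.5) {
  stopifnot(inherits(cr, "tac"), inherits(params, "srtm_params"))
  if (params$vb > 0 && is.null(cb)) stop("vb > 0 requires a blood curve cb")
  if (!is.null(cb)) {
    stopifnot(inherits(cb, "tac"))
    if (length(cb$times) != length(cr$times) ||
        max(abs(cb$times - cr$times)) > 1e-9) {
      stop("cr and cb must share the same time grid")
    }
  }
  coef <- params$k2 - params$r1 * params$theta3
  conv_t <- if (coef != 0) {
    conv_on_grid(cr, params$theta3, dt_s)
  } else {
    numeric(length(cr$times))
  }
  vals <- (1 - params$vb) * (params$r1 * cr$values + coef * conv_t)
  if (params$vb > 0) vals <- vals + params$vb * cb$values
  tac(cr$times, vals)
}

#' SRTM forward curve averaged over acquisition frames
#'
#' Evaluates the SRTM model of [srtm_forward()] on a fine uniform grid and
#' averages it over the acquisition frames — the curve a scanner would
#' record for a region following those kinetics. This is the generator to
#' pair with frame-averaged reference data and the frame-averaged basis of
#' [make_basis()].
#'
#' @param cr Reference-tissue [tac()] (ideally on a fine grid; any grid is
#'   interpolated).
#' @param params An [srtm_params()].
#' @param schedule A [frame_schedule()].
#' @param cb Whole-blood [tac()]; required when `vb > 0`.
#' @param dt_s Internal grid step (seconds).
#' @return A [tac()] at the frame mid-times.
#' @export
srtm_frame_tac <- function(cr, params, schedule, cb = NULL, dt_s = 0.5) {
  stopifnot(inherits(cr, "tac"), inherits(params, "srtm_params"),
            inherits(schedule, "frame_schedule"))
  if (params$vb > 0 && is.null(cb)) stop("vb > 0 requires a blood curve cb")
  grid <- fine_grid(scan_end(schedule), dt_s)
  crg <- tac_interp(cr, grid)
  coef <- params$k2 - params$r1 * params$theta3
  vals <- params$r1 * crg
  if (coef != 0) {
    vals <- vals + coef * conv_exp(crg, dt_s / 60, params$theta3)
  }
  vals <- (1 - params$vb) * vals
  if (params$vb > 0) vals <- vals + params$vb * tac_interp(cb, grid)
  frame_average(tac(grid, vals), schedule)
}

# Convolution of a TAC with exp(-theta t) (theta in 1/min), evaluated back at
# the TAC's own times. Computed on a fine uniform grid with the exact
# piecewise-linear scheme.
conv_on_grid <- function(x, theta, dt_s = 0.5) {
  grid <- fine_grid(max(x$times), dt_s)
  conv <- conv_exp(tac_interp(x, grid), dt_s / 60, theta)
  stats::approx(grid, conv, xout = x$times, rule = 2)$y
}

#' Average a continuous-time curve over acquisition frames
#'
#' Each frame's value is the mean of the curve over the frame interval. A
#' function input is integrated adaptively; a [tac()] input is treated as
#' piecewise linear and integrated exactly.
#'
#' @param curve Either a function of time in seconds, or a [tac()] covering
#'   the full scan span.
#' @param schedule A [frame_schedule()].
#' @return A [tac()] at the frame mid-times.
#' @export
frame_average <- function(curve, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  a <- schedule$frame_start
  b <- a + schedule$frame_duration
  if (is.function(curve)) {
    vals <- vapply(seq_along(a), function(i) {
      stats::integrate(curve, a[i], b[i], rel.tol = 1e-10,
                       abs.tol = 1e-12, subdivisions = 500L)$value /
        (b[i] - a[i])
    }, numeric(1))
  } else if (inherits(curve, "tac")) {
    if (max(curve$times) < max(b) - 1e-6 || curve$times[1] > min(a) + 1e-6) {
      stop("TAC does not cover the frame schedule span")
    }
    vals <- vapply(seq_along(a), function(i) {
      pl_integral(curve, a[i], b[i]) / (b[i] - a[i])
    }, numeric(1))
  } else {
    stop("curve must be a function(t_seconds) or a tac")
  }
  tac(schedule$frame_mid, vals)
}

# Exact integral of the piecewise-linear interpolant of a TAC over [a, b].
pl_integral <- function(x, a, b) {
  knots <- x$times[x$times > a & x$times < b]
  ts <- c(a, knots, b)
  vs <- tac_interp(x, ts)
  sum(diff(ts) * (utils::head(vs, -1) + utils::tail(vs, -1)) / 2)
}

# Per-frame noise SD of the count-statistics surrogate model; frame
# durations enter in their native seconds.
noise_sd <- function(values, schedule, alpha, half_life_min = 20.4) {
  t_min <- schedule$frame_mid / 60
  decay <- 2^(-t_min / half_life_min)
  alpha * sqrt(pmax(values, 0) / (schedule$frame_duration * decay))
}

#' Add count-statistics surrogate noise to a frame-averaged TAC
#'
#' Adds independent zero-mean Gaussian noise per frame with standard
#' deviation
#' \deqn{\sigma_j = \alpha \sqrt{ \max(C_j, 0) / (\Delta t_j \, d(t_j)) },
#'   \quad d(t) = 2^{-t / T_{1/2}}}
#' where \eqn{\Delta t_j} is the frame duration in seconds and
#' \eqn{T_{1/2} = 20.4} min is the C-11 half-life. The simulated TACs are
#' decay-corrected, so physical decay enters only through this variance
#' model: late, short frames are noisiest.
#'
#' @param x A [tac()] at the mid-times of `schedule`.
#' @param schedule A [frame_schedule()].
#' @param alpha Non-negative noise level (unitless); `alpha = 0` returns the
#'   input unchanged.
#' @param seed Integer seed; the same seed gives identical output and the
#'   caller's RNG state is left untouched.
#' @return A noisy [tac()].
#' @export
add_noise <- function(x, schedule, alpha, seed) {
  stopifnot(inherits(x, "tac"), inherits(schedule, "frame_schedule"))
  if (alpha < 0) stop("alpha must be non-negative")
  if (length(x$times) != n_frames(schedule)) {
    stop("TAC length must equal the number of frames")
  }
  if (alpha == 0) return(x)
  sd <- noise_sd(x$values, schedule, alpha)
  eps <- with_seed(seed, stats::rnorm(length(sd), 0, sd))
  tac(x$times, x$values + eps)
}

# Run code under a fixed seed, restoring the global RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
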