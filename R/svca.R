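#' Supervised cluster analysis configuration
#'
#' Controls how reference-tissue voxels are selected after the per-voxel
#' class decomposition. `top_fraction` keeps the given fraction of in-mask
#' voxels with the highest gray-without-specific-binding weight;
#' `weight_threshold` keeps voxels whose class-2 weight exceeds `threshold`.
#'
#' @param selection_mode `"top_fraction"` (default) or `"weight_threshold"`.
#' @param threshold Fraction in (0, 1] (for `top_fraction`) or a weight
#'   cut-off (for `weight_threshold`). Default 0.10.
#' @param min_voxels Minimum number of selected voxels (default 50).
#' @return An object of class `svca_config`.
#' @export
svca_config <- function(selection_mode = c("top_fraction", "weight_threshold"),
                        threshold = 0.10, min_voxels = 50L) {
  selection_mode <- match.arg(selection_mode)
  if (selection_mode == "top_fraction" && (threshold <= 0 || threshold > 1)) {
    stop("top_fraction threshold must lie in (0, 1]")
  }
  if (threshold <= 0) stop("threshold must be positive")
  if (min_voxels < 1) stop("min_voxels must be >= 1")
  structure(list(normalization = "unit_auc",
                 selection_mode = selection_mode,
                 threshold = threshold,
                 min_voxels = as.integer(min_voxels)),
            class = "svca_config")
}

#' Restrict a dynamic image to an anatomical mask
#'
#' @param image 4D array (x, y, z, frame).
#' @param mask 3D array (logical or numeric) of the same spatial shape;
#'   voxels with `mask > 0` are retained.
#' @return List with `tacs` (n_voxels x n_frames matrix), `voxels` (linear
#'   indices into the volume) and `n` (voxel count).
#' @export
apply_anatomical_mask <- function(image, mask) {
  d <- dim(image)
  if (length(d) != 4) stop("image must be a 4D array (x, y, z, frame)")
  if (!all(dim(mask) == d[1:3])) {
    stop("mask shape must match the image's spatial shape")
  }
  sel <- which(mask > 0)
  if (length(sel) == 0) stop("mask is empty")
  m <- matrix(image, nrow = prod(d[1:3]), ncol = d[4])
  list(tacs = m[sel, , drop = FALSE], voxels = sel, n = length(sel))
}

# Trapezoid quadrature weights on a set of sample times.
trapezoid_weights <- function(times) {
  n <- length(times)
  if (n < 2) return(rep(0, n))
  dt <- diff(times)
  c(dt[1] / 2, (dt[-(n - 1)] + dt[-1]) / 2, dt[n - 1] / 2)
}

#' Normalize a TAC to unit area under the curve
#'
#' Divides by the trapezoid AUC over the frame mid-times, so that the
#' decomposition into class templates depends only on curve shape. A voxel
#' with non-positive AUC cannot be normalized and is reported as an error
#' (such voxels are excluded from clustering by [extract_reference()]).
#'
#' @param x A [tac()] at the mid-times of `schedule`.
#' @param schedule A [frame_schedule()] (used only to validate the grid).
#' @return A unit-AUC [tac()].
#' @export
normalize_tac <- function(x, schedule) {
  stopifnot(inherits(x, "tac"), inherits(schedule, "frame_schedule"))
  if (length(x$times) != n_frames(schedule)) {
    stop("TAC length must equal the number of frames")
  }
  auc <- tac_auc(x)
  if (auc <= 0) stop("TAC has non-positive AUC; cannot normalize")
  tac(x$times, x$values / auc)
}

#' Non-negative decomposition of a TAC into the four class templates
#'
#' Solves \eqn{\min_{w \ge 0} \| y - \sum_i w_i T_i \|^2} for the four
#' kinetic-class templates by non-negative least squares.
#'
#' @param x A (normalized) [tac()] on the template frame grid.
#' @param templates A [make_class_templates()] object.
#' @return List with `weights` (length 4, named by class) and `residual`
#'   (Euclidean residual norm).
#' @export
nnls_weights <- function(x, templates) {
  stopifnot(inherits(x, "tac"), inherits(templates, "kinetic_class_templates"))
  A <- t(templates$matrix)
  if (length(x$values) != nrow(A)) {
    stop("TAC and templates must share the frame grid")
  }
  fit <- pracma::lsqnonneg(A, x$values)
  w <- as.numeric(fit$x)
  names(w) <- rownames(templates$matrix)
  list(weights = w, residual = sqrt(sum((x$values - A %*% w)^2)))
}

#' Extract the reference-tissue input curve (SVCA4)
#'
#' The supervised-cluster reference extraction: every in-mask voxel TAC is
#' normalized to unit AUC and decomposed by non-negative least squares into
#' the four kinetic-class templates; voxels are ranked by their
#' gray-without-specific-binding (class 2) weight; the selected voxels'
#' RAW (unnormalized) TACs are averaged, weighted by their class-2 weights,
#' to give the reference input curve.
#'
#' @param image 4D array (x, y, z, frame) or a [make_phantom()] object.
#' @param templates A [make_class_templates()] object.
#' @param mask 3D brain mask (ignored when `image` is a phantom, whose own
#'   mask is used, unless explicitly supplied).
#' @param config An [svca_config()].
#' @param schedule A [frame_schedule()]; taken from the phantom if omitted.
#' @return An object of class `svca_result`: `reference_tac`, `weight_maps`
#'   (4D array x, y, z, class; `NA` outside the mask), `selected_mask`
#'   (logical 3D array), `selected_voxel_count`, `excluded_voxel_count`
#'   (voxels with non-positive AUC), `config`.
#' @export
extract_reference <- function(image, templates, mask = NULL,
                              config = svca_config(), schedule = NULL) {
  stopifnot(inherits(templates, "kinetic_class_templates"),
            inherits(config, "svca_config"))
  if (inherits(image, "dynamic_phantom")) {
    if (is.null(mask)) mask <- image$mask
    if (is.null(schedule)) schedule <- image$schedule
    image <- image$image
  }
  if (is.null(schedule)) schedule <- templates$schedule
  if (is.null(mask)) stop("a brain mask is required")
  masked <- apply_anatomical_mask(image, mask)
  if (masked$n < config$min_voxels) {
    stop("mask contains fewer than min_voxels = ", config$min_voxels,
         " voxels")
  }
  Y <- masked$tacs
  qw <- trapezoid_weights(schedule$frame_mid)
  auc <- as.numeric(Y %*% qw)
  ok <- auc > 0

  A <- t(templates$matrix)
  W <- matrix(NA_real_, nrow = masked$n, ncol = 4)
  for (i in which(ok)) {
    W[i, ] <- as.numeric(pracma::lsqnonneg(A, Y[i, ] / auc[i])$x)
  }

  w2 <- W[, 2]
  w2[!ok] <- -Inf
  n_ok <- sum(ok)
  if (config$selection_mode == "top_fraction") {
    k <- max(config$min_voxels, ceiling(config$threshold * masked$n))
    k <- min(k, n_ok)
    sel <- order(w2, decreasing = TRUE)[seq_len(k)]
    sel <- sel[w2[sel] > 0]
  } else {
    sel <- which(ok & W[, 2] >= config$threshold)
  }
  if (length(sel) < config$min_voxels) {
    stop("only ", length(sel), " voxels selected (< min_voxels = ",
         config$min_voxels, ") with ", config$selection_mode,
         " threshold = ", config$threshold)
  }
  ref_vals <- as.numeric(t(Y[sel, , drop = FALSE]) %*% w2[sel] / sum(w2[sel]))

  d3 <- dim(mask)
  weight_maps <- array(NA_real_, dim = c(d3, 4))
  nv <- prod(d3)
  for (c in 1:4) {
    v <- rep(NA_real_, nv)
    v[masked$voxels] <- W[, c]
    weight_maps[, , , c] <- array(v, dim = d3)
  }
  sel_vec <- rep(FALSE, nv)
  sel_vec[masked$voxels[sel]] <- TRUE

  structure(
    list(reference_tac = tac(schedule$frame_mid, ref_vals),
         weight_maps = weight_maps,
         selected_mask = array(sel_vec, dim = d3),
         selected_voxel_count = length(sel),
         excluded_voxel_count = masked$n - n_ok,
         config = config),
    class = "svca_result"
  )
}

#' @export
print.svca_result <- function(x, ...) {
  cat(sprintf(
    "<svca_result> reference from %d voxels (%s = %g); %d excluded\n",
    x$selected_voxel_count, x$config$selection_mode, x$config$threshold,
    x$excluded_voxel_count))
  invisible(x)
}
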