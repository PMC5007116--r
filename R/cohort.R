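#' Default two-tissue kinetics for the four SVCA classes
#'
#' Plausible first-generation TSPO-tracer kinetics for the four supervised
#' cluster classes, in the fixed order gray matter with specific binding,
#' gray matter without specific binding, white matter, blood. The two gray
#' classes share delivery and efflux so that the specific class has R1 = 1
#' and k2 = 0.15/min relative to the reference class, with BP_ND = k3/k4 =
#' 0.5; white matter has slower delivery and washout; the blood class is
#' pure blood (vb = 1).
#'
#' @return Named list of four [tissue_kinetic_params()].
#' @export
default_class_kinetics <- function() {
  list(
    gray_specific    = tissue_kinetic_params(K1 = 0.30, k2t = 0.15,
                                             k3 = 0.15, k4 = 0.30, vb = 0.05),
    gray_nonspecific = tissue_kinetic_params(K1 = 0.30, k2t = 0.15, vb = 0.05),
    white_matter     = tissue_kinetic_params(K1 = 0.15, k2t = 0.08, vb = 0.03),
    blood            = tissue_kinetic_params(K1 = 0, k2t = 0, vb = 1 - 1e-9)
  )
}

svca_class_names <- c("gray_specific", "gray_nonspecific",
                      "white_matter", "blood")

#' Build the four kinetic-class templates
#'
#' Generates the noiseless frame-averaged time-activity curve of each class
#' from its two-tissue kinetics (the blood class is the whole-blood curve),
#' then normalizes every template to unit trapezoid area under the curve so
#' that the supervised decomposition compares curve shapes, not amplitudes.
#'
#' @param input_params An [input_function_params()].
#' @param class_kinetics List of four [tissue_kinetic_params()] in the class
#'   order gray-specific, gray-nonspecific, white-matter, blood. The
#'   specific class must have `k3 > 0`, the non-specific gray class
#'   `k3 = 0`, and the blood class must be (numerically) pure blood.
#' @param schedule A [frame_schedule()].
#' @param dt_s Internal simulation grid step (seconds).
#' @return An object of class `kinetic_class_templates`: normalized class
#'   TACs, the unnormalized (raw) class TACs, and the 4 x n_frames template
#'   matrix.
#' @export
make_class_templates <- function(input_params = input_function_params(),
                                 class_kinetics = default_class_kinetics(),
                                 schedule = default_frame_schedule(),
                                 dt_s = 0.5) {
  stopifnot(length(class_kinetics) == 4)
  if (class_kinetics[[1]]$k3 <= 0) {
    stop("class 1 (gray with specific binding) must have k3 > 0")
  }
  if (class_kinetics[[2]]$k3 != 0) {
    stop("class 2 (gray without specific binding) must have k3 = 0")
  }
  if (class_kinetics[[4]]$vb < 1 - 1e-6) {
    stop("class 4 (blood) must have vb ~ 1")
  }
  grid <- fine_grid(scan_end(schedule), dt_s)
  cp <- plasma_input(input_params, grid)
  cb <- whole_blood(input_params, grid)

  fine <- lapply(class_kinetics, function(p) {
    two_tissue_tac(cp, p, grid, cb = cb, dt_s = dt_s)
  })
  names(fine) <- svca_class_names
  raw <- lapply(fine, frame_average, schedule = schedule)
  norm <- lapply(raw, function(x) {
    auc <- tac_auc(x)
    if (auc <= 0) stop("class template has non-positive AUC")
    tac(x$times, x$values / auc)
  })
  mat <- do.call(rbind, lapply(norm, function(x) x$values))
  rownames(mat) <- svca_class_names
  if (qr(mat)$rank < 4) {
    stop("class templates are degenerate (template matrix rank < 4); ",
         "check that the class kinetics are distinct")
  }
  structure(
    list(class_tacs = norm, raw_tacs = raw, fine_tacs = fine, matrix = mat,
         normalization = "unit_auc", schedule = schedule),
    class = "kinetic_class_templates"
  )
}

#' @export
print.kinetic_class_templates <- function(x, ...) {
  cat(sprintf("<kinetic_class_templates> 4 classes x %d frames (%s)\n",
              ncol(x$matrix), x$normalization))
  invisible(x)
}

#' Specification of a synthetic dynamic phantom
#'
#' @param shape Integer vector of 3 voxel dimensions.
#' @param voxel_size Voxel edge lengths in mm (default 2 mm isotropic).
#' @param class_map Integer array of `shape` with values 0 (background) or
#'   1-4 (the SVCA classes); `NULL` builds [default_class_map()].
#' @param alpha Noise level passed to [add_noise()].
#' @param seed Integer seed for the phantom noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 16), voxel_size = c(2, 2, 2),
                         class_map = NULL, alpha = 0.3, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape <= 0)) {
    stop("shape must be 3 positive integers")
  }
  if (is.null(class_map)) class_map <- default_class_map(shape)
  if (!all(dim(class_map) == shape)) stop("class_map must have dim = shape")
  if (!all(class_map %in% 0:4)) stop("class_map values must be in 0..4")
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(shape = shape, voxel_size = voxel_size,
                 class_map = class_map, alpha = alpha,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom class map
#'
#' An ellipsoidal "brain" (semi-axes 45% of each dimension) containing a
#' white-matter core, a gray-matter shell, a lateral gray region with
#' specific binding, and scattered blood voxels, against a zero background.
#'
#' @param shape Integer vector of 3 voxel dimensions.
#' @return Integer array: 0 background, 1 gray-specific, 2 gray-nonspecific,
#'   3 white matter, 4 blood.
#' @export
default_class_map <- function(shape = c(32, 32, 16)) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  ax <- 0.45 * nx; ay <- 0.45 * ny; az <- 0.45 * nz
  idx <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  r2 <- ((idx$i - cx) / ax)^2 + ((idx$j - cy) / ay)^2 + ((idx$k - cz) / az)^2
  core <- ((idx$i - cx) / (0.55 * ax))^2 + ((idx$j - cy) / (0.55 * ay))^2 +
    ((idx$k - cz) / (0.55 * az))^2
  cls <- integer(nrow(idx))
  inside <- r2 <= 1
  cls[inside] <- 2L                       # gray shell
  cls[inside & core <= 1] <- 3L           # white-matter core
  specific <- inside & core > 1 & idx$i > cx + 0.18 * nx
  cls[specific] <- 1L
  # deterministic sprinkling of blood voxels (~3% of the brain)
  sprinkle <- (idx$i * 7L + idx$j * 13L + idx$k * 29L) %% 31L == 0L
  cls[inside & sprinkle] <- 4L
  array(cls, dim = shape)
}

#' Generate a 4D dynamic phantom with ground truth
#'
#' Every in-brain voxel receives the noiseless frame-averaged TAC of its
#' kinetic class plus per-frame Gaussian noise from the count-statistics
#' surrogate model ([add_noise()]); background voxels are zero. Returned
#' alongside are the true class map and the true BP_ND map (`k3/k4` for the
#' specific class, 0 for the other tissue classes, `NA` for blood), so that
#' reference extraction and parametric mapping can be validated.
#'
#' @param spec A [phantom_spec()].
#' @param class_kinetics Four [tissue_kinetic_params()] (class order as in
#'   [make_class_templates()]).
#' @param input_params An [input_function_params()].
#' @param schedule A [frame_schedule()].
#' @param dt_s Internal simulation grid step (seconds).
#' @return A list of class `dynamic_phantom`: `image` (4D array x,y,z,frame),
#'   `class_map`, `bp_true`, `mask` (brain mask), `class_tacs` (noiseless
#'   per-class frame TACs), `schedule`, `spec`.
#' @export
make_phantom <- function(spec = phantom_spec(),
                         class_kinetics = default_class_kinetics(),
                         input_params = input_function_params(),
                         schedule = default_frame_schedule(),
                         dt_s = 0.5) {
  stopifnot(inherits(spec, "phantom_spec"))
  templates <- make_class_templates(input_params, class_kinetics,
                                    schedule, dt_s)
  raw <- templates$raw_tacs
  nf <- n_frames(schedule)
  nv <- prod(spec$shape)
  cls <- as.integer(spec$class_map)

  img <- matrix(0, nrow = nv, ncol = nf)
  for (c in 1:4) {
    sel <- which(cls == c)
    if (length(sel)) {
      img[sel, ] <- matrix(raw[[c]]$values, nrow = length(sel), ncol = nf,
                           byrow = TRUE)
    }
  }
  if (spec$alpha > 0) {
    noise <- with_seed(spec$seed, {
      out <- matrix(0, nrow = nv, ncol = nf)
      for (c in 1:4) {
        sel <- which(cls == c)
        if (length(sel)) {
          sd <- noise_sd(raw[[c]]$values, schedule, spec$alpha)
          out[sel, ] <- matrix(stats::rnorm(length(sel) * nf, 0,
                                            rep(sd, each = length(sel))),
                               nrow = length(sel))
        }
      }
      out
    })
    img <- img + noise
  }

  bp1 <- bpnd_2tc(class_kinetics[[1]])
  bp_true <- rep(NA_real_, nv)
  bp_true[cls == 1L] <- bp1
  bp_true[cls %in% c(2L, 3L)] <- 0
  structure(
    list(image = array(img, dim = c(spec$shape, nf)),
         class_map = spec$class_map,
         bp_true = array(bp_true, dim = spec$shape),
         mask = array(cls > 0L, dim = spec$shape),
         class_tacs = raw, templates = templates,
         schedule = schedule, spec = spec),
    class = "dynamic_phantom"
  )
}

#' Cohort specification emulating a two-group TSPO PET study
#'
#' Defaults reproduce the demographics and per-ROI BP_ND summary statistics
#' of a 17-control / 19-patient recent-onset psychosis cohort: age 26 +/- 4
#' years (range 20-34) in both groups, gender margins 14/3 and 16/3,
#' injected dose 433 +/- 23 vs 407 +/- 73 MBq, specific activity 96 +/- 28
#' vs 74 +/- 19 GBq/umol, injected mass 1.7 +/- 0.6 vs 2.1 +/- 0.6 ug, and
#' the six-ROI BP_ND means/SDs (total gray 0.14 +/- 0.09 vs 0.17 +/- 0.09,
#' etc.). Regional BP_ND values within a subject are correlated through a
#' shared subject factor (default correlation 0.8), reflecting the large
#' intersubject variability of global TSPO expression.
#'
#' @param n_control,n_patient Group sizes.
#' @param roi_means,roi_sds 2 x 6 matrices (rows control, patient; columns
#'   the ROIs) of BP_ND means and SDs.
#' @param roi_correlation Common inter-ROI correlation of subject BP_ND.
#' @param age_mean,age_sd,age_range Age distribution (years), shared by both
#'   groups; draws are clipped to `age_range`.
#' @param males Integer vector: number of males per group.
#' @param dose_mean,dose_sd Injected dose (MBq) per group.
#' @param sa_mean,sa_sd Specific activity (GBq/umol) per group.
#' @param mass_mean,mass_sd Injected mass (ug) per group.
#' @param nicotine_users,cannabis_users Counts of users per group.
#' @param panss_mean,panss_sd PANSS total score distribution (patients only).
#' @param truncate_bp Set `TRUE` to clip negative BP_ND draws at 0
#'   (off by default: reference-tissue estimates can be slightly negative).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 17L, n_patient = 19L,
                        roi_means = default_roi_means(),
                        roi_sds = default_roi_sds(),
                        roi_correlation = 0.8,
                        age_mean = 26, age_sd = 4, age_range = c(20, 34),
                        males = c(14L, 16L),
                        dose_mean = c(433, 407), dose_sd = c(23, 73),
                        sa_mean = c(96, 74), sa_sd = c(28, 19),
                        mass_mean = c(1.7, 2.1), mass_sd = c(0.6, 0.6),
                        nicotine_users = c(5L, 13L),
                        cannabis_users = c(0L, 4L),
                        panss_mean = 53, panss_sd = 10,
                        truncate_bp = FALSE) {
  if (n_control <= 0 || n_patient <= 0) stop("group sizes must be positive")
  if (any(roi_sds < 0)) stop("ROI SDs must be non-negative")
  if (roi_correlation < 0 || roi_correlation > 1) {
    stop("roi_correlation must lie in [0, 1]")
  }
  if (any(males > c(n_control, n_patient))) {
    stop("male counts cannot exceed group sizes")
  }
  structure(
    list(n = c(control = as.integer(n_control),
               patient = as.integer(n_patient)),
         roi_means = roi_means, roi_sds = roi_sds,
         roi_correlation = roi_correlation,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         males = males, dose_mean = dose_mean, dose_sd = dose_sd,
         sa_mean = sa_mean, sa_sd = sa_sd,
         mass_mean = mass_mean, mass_sd = mass_sd,
         nicotine_users = nicotine_users, cannabis_users = cannabis_users,
         panss_mean = panss_mean, panss_sd = panss_sd,
         truncate_bp = truncate_bp),
    class = "cohort_spec"
  )
}

roi_names <- c("total_gray", "frontal", "temporal", "parietal",
               "striatum", "thalamus")

#' @rdname cohort_spec
#' @export
default_roi_means <- function() {
  m <- rbind(control = c(0.14, 0.12, 0.08, 0.15, 0.09, 0.20),
             patient = c(0.17, 0.12, 0.12, 0.15, 0.10, 0.23))
  colnames(m) <- roi_names
  m
}

#' @rdname cohort_spec
#' @export
default_roi_sds <- function() {
  m <- rbind(control = c(0.09, 0.09, 0.09, 0.07, 0.10, 0.12),
             patient = c(0.09, 0.07, 0.08, 0.07, 0.10, 0.12))
  colnames(m) <- roi_names
  m
}

#' Sample a synthetic cohort
#'
#' Draws subject records from a [cohort_spec()]: per-ROI BP_ND from the
#' group's normal distributions with a shared subject factor inducing the
#' configured inter-ROI correlation, ages clipped to the configured range,
#' gender and substance-use flags as fixed per-group counts (permuted), and
#' PANSS totals for patients only.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per subject: `subject_id`, `group`, `age`,
#'   `gender`, `injected_dose`, `specific_activity`, `injected_mass`,
#'   `nicotine`, `cannabis`, `panss_total`, and one `bp_<roi>` column per
#'   ROI.
#' @export
sample_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  rho <- spec$roi_correlation
  n_roi <- ncol(spec$roi_means)
  with_seed(seed, {
    groups <- c("control", "patient")
    rows <- lapply(1:2, function(g) {
      n <- spec$n[g]
      age <- pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd),
                       spec$age_range[1]), spec$age_range[2])
      gender <- sample(rep(c("M", "F"),
                           c(spec$males[g], n - spec$males[g])))
      nicotine <- sample(rep(c(TRUE, FALSE),
                             c(spec$nicotine_users[g],
                               n - spec$nicotine_users[g])))
      cannabis <- sample(rep(c(TRUE, FALSE),
                             c(spec$cannabis_users[g],
                               n - spec$cannabis_users[g])))
      z <- stats::rnorm(n)
      e <- matrix(stats::rnorm(n * n_roi), n, n_roi)
      bp <- matrix(spec$roi_means[g, ], n, n_roi, byrow = TRUE) +
        matrix(spec$roi_sds[g, ], n, n_roi, byrow = TRUE) *
        (sqrt(rho) * z + sqrt(1 - rho) * e)
      if (spec$truncate_bp) bp <- pmax(bp, 0)
      colnames(bp) <- paste0("bp_", colnames(spec$roi_means))
      d <- tibble::tibble(
        group = groups[g],
        age = age,
        gender = gender,
        injected_dose = stats::rnorm(n, spec$dose_mean[g], spec$dose_sd[g]),
        specific_activity = stats::rnorm(n, spec$sa_mean[g], spec$sa_sd[g]),
        injected_mass = stats::rnorm(n, spec$mass_mean[g], spec$mass_sd[g]),
        nicotine = nicotine,
        cannabis = cannabis,
        panss_total = if (groups[g] == "patient") {
          stats::rnorm(n, spec$panss_mean, spec$panss_sd)
        } else {
          NA_real_
        }
      )
      cbind(d, tibble::as_tibble(bp))
    })
    out <- tibble::as_tibble(do.call(rbind, rows))
    out <- cbind(tibble::tibble(subject_id = sprintf("S%03d", seq_len(nrow(out)))),
                 out)
    tibble::as_tibble(out)
  })
}

#' Write / read a subject table as TSV
#'
#' @param subjects A subject tibble from [sample_cohort()].
#' @param path TSV path.
#' @return `write_subject_table` returns `path` invisibly;
#'   `read_subject_table` returns a tibble.
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_subject_table
#' @export
read_subject_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      na.strings = "",
                                      stringsAsFactors = FALSE))
}
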