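#' Pipeline configuration
#'
#' Bundles every stage's settings for a seeded end-to-end run: cohort
#' emulation, the phantom used for supervised-cluster reference extraction,
#' SVCA selection, the basis grid of the RPM-Vb fit, ROI-TAC noise, and the
#' statistics options.
#'
#' @param seed Integer master seed (mandatory; every stage's randomness is
#'   derived from it).
#' @param cohort A [cohort_spec()].
#' @param phantom A [phantom_spec()] for the reference-extraction stage
#'   (default a 24 x 24 x 12 phantom at the cohort noise level).
#' @param svca An [svca_config()].
#' @param input_params An [input_function_params()].
#' @param class_kinetics Four [tissue_kinetic_params()].
#' @param schedule A [frame_schedule()].
#' @param tac_noise Noise level `alpha` for the per-subject ROI TACs
#'   (ROI-averaged curves are much less noisy than single voxels;
#'   default 0.1).
#' @param r1_true,vb_true Delivery ratio and blood-volume fraction used when
#'   synthesizing subject ROI TACs.
#' @param theta3_min,theta3_max,n_basis Basis-grid settings ([make_basis()]).
#' @param outdir Output directory, or `NULL` to keep everything in memory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            cohort = cohort_spec(),
                            phantom = NULL,
                            svca = svca_config(),
                            input_params = input_function_params(),
                            class_kinetics = default_class_kinetics(),
                            schedule = default_frame_schedule(),
                            tac_noise = 0.1,
                            r1_true = 1.0, vb_true = 0.05,
                            theta3_min = 0.006, theta3_max = 0.6,
                            n_basis = 64L,
                            outdir = NULL) {
  if (missing(seed)) stop("a seed is mandatory for a pipeline run")
  seed <- as.integer(seed)
  if (is.null(phantom)) {
    phantom <- phantom_spec(shape = c(24, 24, 12), alpha = 0.3,
                            seed = seed + 1L)
  }
  structure(
    list(seed = seed, cohort = cohort, phantom = phantom, svca = svca,
         input_params = input_params, class_kinetics = class_kinetics,
         schedule = schedule, tac_noise = tac_noise,
         r1_true = r1_true, vb_true = vb_true,
         theta3_min = theta3_min, theta3_max = theta3_max,
         n_basis = as.integer(n_basis), outdir = outdir),
    class = "pipeline_config"
  )
}

# Polynomial rolling hash over the deparsed config; cheap provenance
# fingerprint (not cryptographic).
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Dense frame-averaging operator: n_frames x n_grid matrix A such that
# A %*% f gives the exact trapezoid frame means of a piecewise-linear curve
# sampled on `grid` (which must contain every frame boundary).
frame_average_matrix <- function(schedule, grid) {
  nf <- n_frames(schedule)
  A <- matrix(0, nf, length(grid))
  for (i in seq_len(nf)) {
    a <- schedule$frame_start[i]
    b <- a + schedule$frame_duration[i]
    sel <- which(grid >= a - 1e-9 & grid <= b + 1e-9)
    g <- grid[sel]
    w <- trapezoid_weights(g)
    A[i, sel] <- w / (b - a)
  }
  A
}

# Vectorized SRTM frame-TAC generation for a vector of BP values sharing
# r1, k2_ref and vb: returns an n_frames x length(bp) matrix.
srtm_frame_tac_matrix <- function(crg, cbg, dt_min, A, bp, k2, r1, vb) {
  vapply(bp, function(b) {
    theta3 <- k2 / (1 + b)
    coef <- k2 - r1 * theta3
    v <- r1 * crg
    if (coef != 0) v <- v + coef * conv_exp(crg, dt_min, theta3)
    as.numeric(A %*% ((1 - vb) * v + vb * cbg))
  }, numeric(nrow(A)))
}

#' Synthesize and fit per-subject ROI time-activity curves
#'
#' For every subject and ROI, generates the SRTM forward curve implied by
#' the subject's BP_ND (delivery ratio `r1_true`, reference efflux from the
#' gray-reference class, blood fraction `vb_true`), adds count-statistics
#' noise, and fits it with the vascular-corrected basis-function SRTM
#' against the supplied reference curve.
#'
#' @param subjects Subject tibble from [sample_cohort()] with `bp_<roi>`
#'   columns.
#' @param cr_true Noiseless reference-class [tac()] on a fine grid, used as
#'   the generator's reference input (e.g. `templates$fine_tacs[[2]]`).
#' @param reference Reference [tac()] used for fitting (e.g. the
#'   SVCA-extracted curve).
#' @param blood Whole-blood [tac()] at the frame mid-times (used in the
#'   fit's vascular column).
#' @param blood_fine Fine-grid whole-blood [tac()] for the generator;
#'   defaults to `blood`.
#' @param schedule A [frame_schedule()].
#' @param rois Character vector of ROI names (default all six).
#' @param k2_ref Reference-region efflux rate (1/min) of the generator.
#' @param r1_true,vb_true Generator delivery ratio and blood fraction.
#' @param tac_noise Noise level alpha for [add_noise()].
#' @param seed Integer seed.
#' @param theta3_min,theta3_max,n_basis Basis-grid settings.
#' @return The subject tibble with added `fit_bp_<roi>`, `fit_r1_<roi>`,
#'   `fit_vb_<roi>` columns.
#' @export
fit_cohort_tacs <- function(subjects, cr_true, reference, blood, schedule,
                            blood_fine = blood,
                            rois = roi_names, k2_ref = 0.15,
                            r1_true = 1.0, vb_true = 0.05,
                            tac_noise = 0.1, seed = 1L,
                            theta3_min = 0.006, theta3_max = 0.6,
                            n_basis = 64L) {
  basis <- make_basis(reference, schedule, theta3_min, theta3_max, n_basis)
  n <- nrow(subjects)
  grid <- fine_grid(scan_end(schedule))
  crg <- tac_interp(cr_true, grid)
  cbg <- tac_interp(blood_fine, grid)
  A <- frame_average_matrix(schedule, grid)
  for (roi in rois) {
    bp_col <- paste0("bp_", roi)
    if (!bp_col %in% names(subjects)) stop("missing column ", bp_col)
    Y <- srtm_frame_tac_matrix(crg, cbg, 0.5 / 60, A,
                               pmax(subjects[[bp_col]], -0.9),
                               k2 = r1_true * k2_ref, r1 = r1_true,
                               vb = vb_true)
    for (i in seq_len(n)) {
      Y[, i] <- add_noise(tac(schedule$frame_mid, Y[, i]), schedule,
                          tac_noise,
                          seed + 1000L * match(roi, rois) + i)$values
    }
    s <- rpm_solve(Y, basis, blood)
    subjects[[paste0("fit_bp_", roi)]] <- s$bp_nd
    subjects[[paste0("fit_r1_", roi)]] <- s$r1
    subjects[[paste0("fit_vb_", roi)]] <- s$vb
  }
  subjects
}

#' Group-comparison statistics battery
#'
#' For each ROI: the one-way group ANOVA, the age-adjusted ANCOVA group
#' test, and Levene's test for homogeneity of variances; plus the Wilks
#' MANOVA over the five regional ROIs with age covariate, and the gender
#' chi-square. Bonferroni adjustment (m = 5) is applied to the regional
#' group tests; total gray matter is the primary outcome and reported
#' unadjusted.
#'
#' @param subjects Subject tibble with `group`, `age`, `gender` and
#'   `<value_prefix><roi>` columns.
#' @param rois ROI names to test.
#' @param value_prefix Column prefix of the outcome values (default
#'   `"fit_bp_"`; use `"bp_"` to test the simulated truth directly).
#' @return A tibble: `test`, `roi`, `statistic`, `df1`, `df2`, `p`,
#'   `p_bonferroni`.
#' @export
stats_battery <- function(subjects, rois = roi_names,
                          value_prefix = "fit_bp_") {
  grp <- factor(subjects$group)
  rows <- list()
  regional <- setdiff(rois, "total_gray")
  m_adj <- length(regional)
  for (roi in rois) {
    v <- subjects[[paste0(value_prefix, roi)]]
    by_group <- split(v, grp)
    a <- anova_oneway(by_group)
    ac <- ancova_group(v, grp, subjects$age)
    lv <- levene_test(by_group)
    adj <- function(p) {
      if (roi %in% regional) bonferroni_adjust(p, m_adj) else p
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      test = c("anova_group", "ancova_group_age", "levene"),
      roi = roi,
      statistic = c(a$statistic, ac$statistic, lv$statistic),
      df1 = c(a$df[1], ac$df[1], lv$df[1]),
      df2 = c(a$df[2], ac$df[2], lv$df[2]),
      p = c(a$p_value, ac$p_value, lv$p_value),
      p_bonferroni = c(adj(a$p_value), adj(ac$p_value), NA_real_)
    )
  }
  if (all(regional %in% rois) && length(regional) >= 2) {
    M <- as.matrix(subjects[paste0(value_prefix, regional)])
    # degenerate (e.g. noise-free constant) cohorts have a singular
    # within-group covariance; the MANOVA row is then omitted
    mv <- tryCatch(manova_rois(M, grp, subjects$age), error = function(e) NULL)
    if (!is.null(mv)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        test = "manova_wilks", roi = "regional",
        statistic = mv$statistic, df1 = mv$df[1], df2 = mv$df[2],
        p = mv$p_value, p_bonferroni = NA_real_)
    }
  }
  tab <- table(grp, factor(subjects$gender, levels = c("M", "F")))
  if (all(dim(tab) == c(2, 2)) && all(rowSums(tab) > 0) &&
      all(colSums(tab) > 0)) {
    ch <- chi2_2x2(tab)
    rows[[length(rows) + 1]] <- tibble::tibble(
      test = "chi2_gender", roi = "all",
      statistic = ch$statistic, df1 = ch$df, df2 = NA_real_,
      p = ch$p_value, p_bonferroni = NA_real_)
  }
  do.call(rbind, rows)
}

#' Run the full seeded pipeline
#'
#' Stages, in order: simulate (cohort + dynamic phantom), extract-reference
#' (SVCA4 on the phantom), fit (per-subject ROI TACs against the extracted
#' reference with RPM-Vb), roi (fitted BP_ND per subject and ROI), stats
#' (the group-comparison battery). With `outdir` set, all artifacts are
#' written (subject table and report as TSV, reference TAC as TSV, phantom
#' and weight maps as NIfTI + JSON timing) and listed in the manifest.
#' The run is a pure function of (config, seed): rerunning reproduces
#' identical numeric outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `subjects` (with fitted
#'   values), `report` (stats tibble), `reference` ([extract_reference()]
#'   result), `phantom`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  files <- character(0)

  # -- simulate ---------------------------------------------------------
  subjects <- sample_cohort(config$cohort, config$seed)
  templates <- make_class_templates(config$input_params,
                                    config$class_kinetics, config$schedule)
  phantom <- make_phantom(config$phantom, config$class_kinetics,
                          config$input_params, config$schedule)

  # -- extract-reference ------------------------------------------------
  svca <- extract_reference(phantom, templates, config = config$svca)

  # -- fit + roi --------------------------------------------------------
  cr_true <- templates$fine_tacs$gray_nonspecific
  blood_fine <- whole_blood(config$input_params,
                            fine_grid(scan_end(config$schedule)))
  blood <- frame_average(blood_fine, config$schedule)
  subjects <- fit_cohort_tacs(
    subjects, cr_true, svca$reference_tac, blood, config$schedule,
    blood_fine = blood_fine,
    k2_ref = config$class_kinetics[[2]]$k2t,
    r1_true = config$r1_true, vb_true = config$vb_true,
    tac_noise = config$tac_noise, seed = config$seed + 2L,
    theta3_min = config$theta3_min, theta3_max = config$theta3_max,
    n_basis = config$n_basis)

  # -- stats ------------------------------------------------------------
  report <- stats_battery(subjects)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$outdir, f)
    write_subject_table(subjects, p("subjects.tsv"))
    write_tac_tsv(svca$reference_tac, config$schedule,
                  p("reference_tac.tsv"))
    utils::write.table(report, p("report.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE, na = "")
    write_dynamic(phantom$image, config$schedule, p("phantom.nii.gz"),
                  voxel_size = config$phantom$voxel_size)
    write_map(svca$selected_mask * 1, p("svca_selected_mask.nii.gz"),
              voxel_size = config$phantom$voxel_size)
    files <- c("subjects.tsv", "reference_tac.tsv", "report.tsv",
               "phantom.nii.gz", "phantom.json",
               "svca_selected_mask.nii.gz")
    manifest <- list(
      config_hash = config_hash(config),
      seed = config$seed,
      version = as.character(utils::packageVersion("rpmpet")),
      files = files,
      started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  } else {
    manifest <- list(config_hash = config_hash(config), seed = config$seed,
                     version = as.character(utils::packageVersion("rpmpet")),
                     files = files)
  }

  structure(list(subjects = subjects, report = report, reference = svca,
                 phantom = phantom, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects, %d report rows, seed %d\n",
              nrow(x$subjects), nrow(x$report), x$manifest$seed))
  invisible(x)
}

#' Null calibration of the ROI-level pipeline
#'
#' Repeatedly simulates cohorts with EQUAL group means (patients set to the
#' control distribution), synthesizes and fits each subject's total-gray
#' TAC, tests the group difference of the fitted BP_ND, and reports the
#' fraction of replicates rejecting at `sig_level`. With the pipeline
#' well calibrated this should sit near the nominal level.
#'
#' @param n_reps Number of replicates.
#' @param seed Integer master seed.
#' @param sig_level Test level (default 0.05).
#' @param tac_noise Noise level of the simulated ROI TACs.
#' @param cohort Base [cohort_spec()]; its patient rows are overwritten
#'   with the control rows to enforce the null.
#' @return List with `rejection_rate`, `n_reps`, `p_values`.
#' @export
pipeline_null_calibration <- function(n_reps = 1000, seed = 1L,
                                      sig_level = 0.05, tac_noise = 0.1,
                                      cohort = cohort_spec()) {
  cohort$roi_means["patient", ] <- cohort$roi_means["control", ]
  cohort$roi_sds["patient", ] <- cohort$roi_sds["control", ]
  schedule <- default_frame_schedule()
  templates <- make_class_templates(schedule = schedule)
  cr_true <- templates$fine_tacs$gray_nonspecific
  cr_frames <- templates$raw_tacs$gray_nonspecific
  blood_fine <- whole_blood(input_function_params(),
                            fine_grid(scan_end(schedule)))
  blood <- frame_average(blood_fine, schedule)
  basis <- make_basis(cr_frames, schedule)
  k2_ref <- 0.15
  grid <- fine_grid(scan_end(schedule))
  crg <- tac_interp(cr_true, grid)
  cbg <- tac_interp(blood_fine, grid)
  A <- frame_average_matrix(schedule, grid)

  pvals <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    subjects <- sample_cohort(cohort, seed + r)
    n <- nrow(subjects)
    Y <- srtm_frame_tac_matrix(crg, cbg, 0.5 / 60, A,
                               pmax(subjects$bp_total_gray, -0.9),
                               k2 = k2_ref, r1 = 1, vb = 0.05)
    for (i in seq_len(n)) {
      Y[, i] <- add_noise(tac(schedule$frame_mid, Y[, i]), schedule,
                          tac_noise, seed + r * 1000L + i)$values
    }
    s <- rpm_solve(Y, basis, blood)
    pvals[r] <- anova_oneway(split(s$bp_nd, subjects$group))$p_value
  }
  list(rejection_rate = mean(pvals < sig_level), n_reps = n_reps,
       p_values = pvals)
}
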