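#' Composite ROI definition
#'
#' Regions of interest are volume-weighted composites of labelled
#' subregions (e.g. the frontal cortex as the volume-weighted average of
#' anterior cingulate, gyrus rectus, orbitofrontal, precentral, and
#' superior/middle/inferior frontal cortex).
#'
#' @param name ROI name, one of `total_gray`, `frontal`, `temporal`,
#'   `parietal`, `striatum`, `thalamus`.
#' @param labels Integer vector of subregion labels in the label volume.
#' @param volumes Positive subregion volumes (same length as `labels`);
#'   defaults to the subregion voxel counts taken from the label volume at
#'   aggregation time.
#' @return An object of class `roi_definition`.
#' @export
roi_definition <- function(name, labels, volumes = NULL) {
  name <- match.arg(name, roi_names)
  labels <- as.integer(labels)
  if (anyDuplicated(labels)) stop("subregion labels must be unique")
  if (!is.null(volumes)) {
    if (length(volumes) != length(labels)) {
      stop("volumes must match labels in length")
    }
    if (any(volumes <= 0)) stop("subregion volumes must be positive")
  }
  structure(list(name = name, labels = labels, volumes = volumes),
            class = "roi_definition")
}

#' Volume-weighted ROI mean of a parametric map
#'
#' \deqn{\bar v = \sum_s \bar v_s \, V_s / \sum_s V_s}
#' where \eqn{\bar v_s} is the mean map value over subregion `s` (NaN/NA
#' voxels excluded, and their volume share removed from \eqn{V_s}) and
#' \eqn{V_s} its volume.
#'
#' @param map 3D array (e.g. a BP_ND map).
#' @param roi A [roi_definition()].
#' @param labels Integer label volume aligned with `map`.
#' @return The ROI mean (single number).
#' @export
composite_roi_mean <- function(map, roi, labels) {
  stopifnot(inherits(roi, "roi_definition"))
  if (!all(dim(map) == dim(labels))) {
    stop("map and label volume must have the same shape")
  }
  vols <- roi$volumes
  means <- numeric(length(roi$labels))
  eff_vols <- numeric(length(roi$labels))
  for (i in seq_along(roi$labels)) {
    lab <- roi$labels[i]
    vox <- map[labels == lab]
    if (length(vox) == 0) {
      stop("subregion label ", lab, " absent from the label volume")
    }
    good <- is.finite(vox)
    if (!any(good)) stop("subregion label ", lab, " contains only NA voxels")
    means[i] <- mean(vox[good])
    v <- if (is.null(vols)) length(vox) else vols[i]
    eff_vols[i] <- v * mean(good) # drop the NA voxels' volume share
  }
  sum(means * eff_vols) / sum(eff_vols)
}
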