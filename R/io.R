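#' Write a dynamic 4D volume with its frame-timing sidecar
#'
#' Volumes go to NIfTI-1 (optionally gzipped by extension) with an isotropic
#' voxel size recorded in the header; frame timing goes to a JSON sidecar
#' with `frame_start_s` / `frame_duration_s` arrays.
#'
#' @param image 4D array (x, y, z, frame).
#' @param schedule A [frame_schedule()] with one entry per frame.
#' @param path NIfTI output path (`.nii` or `.nii.gz`).
#' @param timing_path JSON sidecar path; default replaces the NIfTI
#'   extension with `.json`.
#' @param voxel_size Voxel edge lengths in mm (default 2 mm isotropic).
#' @param datatype NIfTI storage type; `"double"` (default) round-trips
#'   synthetic data exactly, `"float"` halves the file size.
#' @return `path`, invisibly.
#' @export
write_dynamic <- function(image, schedule, path, timing_path = NULL,
                          voxel_size = c(2, 2, 2), datatype = "double") {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(dim(image)) != 4) stop("image must be 4D (x, y, z, frame)")
  if (dim(image)[4] != n_frames(schedule)) {
    stop("image has ", dim(image)[4], " frames but the schedule has ",
         n_frames(schedule))
  }
  if (is.null(timing_path)) timing_path <- nifti_sidecar_path(path)
  img <- RNifti::asNifti(image)
  RNifti::pixdim(img) <- c(voxel_size, 1) # 4th dim: frame axis
  RNifti::writeNifti(img, path, datatype = datatype)
  write_frame_schedule(schedule, timing_path)
  invisible(path)
}

#' Read a dynamic 4D volume and its frame-timing sidecar
#'
#' @param path NIfTI path of a 4D volume.
#' @param timing_path JSON sidecar path; default derived from `path`.
#' @return List with `image` (4D array), `schedule` ([frame_schedule()]),
#'   `voxel_size` (mm).
#' @export
read_dynamic <- function(path, timing_path = NULL) {
  if (is.null(timing_path)) timing_path <- nifti_sidecar_path(path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) {
    stop("expected a 4D dynamic volume, got ", length(d), "D")
  }
  schedule <- read_frame_schedule(timing_path)
  if (d[4] != n_frames(schedule)) {
    stop("timing sidecar has ", n_frames(schedule),
         " frames but the image has ", d[4])
  }
  list(image = array(as.numeric(img), dim = d), schedule = schedule,
       voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write / read a 3D map as NIfTI
#'
#' @param map 3D array (`NA` allowed; stored as NaN).
#' @param path NIfTI path.
#' @param voxel_size Voxel edge lengths in mm.
#' @return `write_map` returns `path` invisibly; `read_map` a 3D array.
#' @export
write_map <- function(map, path, voxel_size = c(2, 2, 2)) {
  if (length(dim(map)) != 3) stop("map must be 3D")
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3) stop("expected a 3D volume")
  array(as.numeric(img), dim = dim(img))
}

nifti_sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}
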