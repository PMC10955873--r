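# Persistence: a single-file, versioned container for every pipeline stage
# (sequence, frames, system matrices, reconstructions, perfusion maps) using
# R's native serialization with a documented group schema, plus NIfTI export
# for volumes and parameter maps.

.container_version <- "1.0"
.container_groups <- c("acquisition", "measurement", "calibration", "fields",
                       "reconstruction", "perfusion")

#' Write a pipeline container
#'
#' Stores named objects under the documented groups (`acquisition`,
#' `measurement`, `calibration`, `fields`, `reconstruction`, `perfusion`) in
#' one versioned file. Round-trips are lossless (bit-for-bit for integer
#' data, exact for doubles).
#'
#' @param path output file path.
#' @param ... named objects, each name one of the documented groups.
#' @return `path`, invisibly.
#' @seealso [read_container()]
#' @export
write_container <- function(path, ...) {
  objects <- list(...)
  if (length(objects) && (is.null(names(objects)) || any(names(objects) == "")))
    stop("all container entries must be named", call. = FALSE)
  bad <- setdiff(names(objects), .container_groups)
  if (length(bad))
    stop("unknown container group(s): ", paste(bad, collapse = ", "),
         "; valid groups: ", paste(.container_groups, collapse = ", "),
         call. = FALSE)
  payload <- list(format = "mpiscan-container",
                  version = .container_version,
                  created = format(Sys.time(), tz = "UTC"),
                  groups = objects)
  saveRDS(payload, path)
  invisible(path)
}

#' Read a pipeline container
#'
#' @param path file path.
#' @param require optional character vector of groups that must be present;
#'   a missing group raises a clear error.
#' @return The named list of stored groups.
#' @export
read_container <- function(path, require = NULL) {
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$format, "mpiscan-container"))
    stop("not an mpiscan container: ", path, call. = FALSE)
  if (numeric_version(payload$version) > numeric_version(.container_version))
    stop("container version ", payload$version,
         " is newer than supported (", .container_version, ")", call. = FALSE)
  missing <- setdiff(require, names(payload$groups))
  if (length(missing))
    stop("container ", path, " is missing required group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  payload$groups
}

#' Export a voxel volume as NIfTI
#'
#' @param c_vec concentration vector (or 3D array).
#' @param grid a [recon_grid()] giving dims and voxel spacing.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(c_vec, grid, path) {
  a <- array(c_vec, grid$dims)
  sp <- function(ax) if (length(ax) > 1) diff(ax[1:2]) else 1
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(sp(grid$x), sp(grid$y), sp(grid$z))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a frames-by-voxels series as 4D NIfTI
#'
#' @param series a [time_series_volume()] with a grid.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series_nifti <- function(series, path) {
  if (is.null(series$grid)) stop("series carries no grid", call. = FALSE)
  g <- series$grid
  a <- array(t(series$data), c(g$dims, nrow(series$data)))
  sp <- function(ax) if (length(ax) > 1) diff(ax[1:2]) else 1
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(sp(g$x), sp(g$y), sp(g$z), series$frame_period)
  RNifti::writeNifti(img, path)
  invisible(path)
}
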