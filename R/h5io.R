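#' Read a plume movie from HDF5
#'
#' Loads a 3-D concentration stack stored in the on-disk layout `[t, y, x]`
#' with attributes `fps`, `px_per_cm`, `origin_x_cm`, `origin_y_cm`.
#' Attributes missing from the file fall back to the function arguments.
#' Negative voxels (PLIF noise floor) are clipped to 0; the clip count is
#' reported via a message and the `"n_clipped"` attribute of the result.
#'
#' @param path Path to an HDF5 file.
#' @param dataset_name Name of the 3-D dataset inside the file.
#' @param fps,px_per_cm,origin Fallback calibration used when the file
#'   carries no corresponding attribute.
#' @return A [dynamic_plume()] with attribute `n_clipped`.
#' @seealso [write_plume_movie()]
#' @export
load_plume_movie <- function(path, dataset_name, fps = 15, px_per_cm = 1,
                             origin = c(0, 0)) {
  if (!file.exists(path)) {
    stop("plume file not found: ", path, call. = FALSE)
  }
  contents <- rhdf5::h5ls(path)
  datasets <- contents$name[contents$otype == "H5I_DATASET"]
  ds <- sub("^/", "", dataset_name)
  if (!ds %in% datasets) {
    stop("dataset not found: `", dataset_name, "`; available datasets: ",
         paste(datasets, collapse = ", "), call. = FALSE)
  }
  raw <- rhdf5::h5read(path, ds, read.attributes = TRUE)
  at <- attributes(raw)
  if (length(dim(raw)) != 3L) {
    stop("dataset `", dataset_name, "` is not a 3-D stack (rank ",
         length(dim(raw)), ")", call. = FALSE)
  }
  n_neg <- sum(raw < 0)
  if (n_neg > 0) {
    raw[raw < 0] <- 0
    message("load_plume_movie: clipped ", n_neg, " negative voxel(s) to 0")
  }
  # On-disk [t, y, x] maps to an R array with dims (t, y, x) reversed by
  # rhdf5's column-major read, i.e. raw has dims (x, y, t) already.
  movie <- dynamic_plume(
    unclass(array(as.numeric(raw), dim(raw))),
    fps = as.numeric(at[["fps"]] %||% fps),
    px_per_cm = as.numeric(at[["px_per_cm"]] %||% px_per_cm),
    origin = c(as.numeric(at[["origin_x_cm"]] %||% origin[1]),
               as.numeric(at[["origin_y_cm"]] %||% origin[2])))
  attr(movie, "n_clipped") <- n_neg
  movie
}

#' Write a plume movie to HDF5
#'
#' Writes the movie in the layout read back by [load_plume_movie()]: one 3-D
#' dataset (on-disk `[t, y, x]`) with calibration attributes `fps`,
#' `px_per_cm`, `origin_x_cm`, `origin_y_cm`.
#'
#' @param movie A [dynamic_plume()].
#' @param path Output file path (overwritten if present).
#' @param dataset_name Dataset name (default `"plume"`).
#' @return `path`, invisibly.
#' @export
write_plume_movie <- function(movie, path, dataset_name = "plume") {
  stopifnot(inherits(movie, "dynamic_plume"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  # R array (x, y, t) is written column-major, which HDF5 records as [t, y, x]
  rhdf5::h5write(movie$frames, path, dataset_name)
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  did <- rhdf5::H5Dopen(fid, dataset_name)
  on.exit(rhdf5::H5Dclose(did), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(movie$fps, did, "fps")
  rhdf5::h5writeAttribute(movie$px_per_cm, did, "px_per_cm")
  rhdf5::h5writeAttribute(movie$origin[1], did, "origin_x_cm")
  rhdf5::h5writeAttribute(movie$origin[2], did, "origin_y_cm")
  invisible(path)
}
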