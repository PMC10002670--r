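#' Labeled reference-atlas volume
#'
#' An `atlas_volume` is a 3D grid of non-negative integer region IDs plus its
#' voxel size. ID 0 is reserved for background (outside the brain) and is never
#' mapped to a region. Spatial convention: voxel `(i, j, k)` (0-based) has its
#' center at continuous coordinate `(i, j, k)` in voxel units, so the volume
#' spans `[-0.5, n - 0.5)` along each axis.
#'
#' @param labels 3D array of non-negative integers (region IDs). Numeric input
#'   is accepted only when every value is integral.
#' @param voxel_size_um positive scalar, physical voxel size in micrometers.
#' @param ml_axis which axis (1, 2 or 3) runs medio-laterally; used by
#'   [make_hemisphere_mask()]. Raw volumes carry no orientation, so this is
#'   explicit configuration rather than inference.
#' @return An object of class `atlas_volume` with fields `labels`, `shape`,
#'   `voxel_size_um`, `background_id` (always 0) and `ml_axis`.
#' @export
atlas_volume <- function(labels, voxel_size_um = 1, ml_axis = 1L) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  if (is.double(labels)) {
    if (any(!is.finite(labels)) || any(labels != round(labels))) {
      stop("volume format error: label values must be integral", call. = FALSE)
    }
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels)) {
    stop("volume format error: label values must be integer", call. = FALSE)
  }
  if (any(labels < 0L)) {
    stop("label IDs must be non-negative", call. = FALSE)
  }
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      voxel_size_um <= 0) {
    stop("`voxel_size_um` must be a positive scalar", call. = FALSE)
  }
  ml_axis <- as.integer(ml_axis)
  stopifnot(ml_axis %in% 1:3)
  structure(
    list(
      labels = labels,
      shape = dim(labels),
      voxel_size_um = as.numeric(voxel_size_um),
      background_id = 0L,
      ml_axis = ml_axis
    ),
    class = "atlas_volume"
  )
}

#' @export
print.atlas_volume <- function(x, ...) {
  cat(sprintf(
    "<atlas_volume> %d x %d x %d voxels @ %g um, %d region IDs\n",
    x$shape[1], x$shape[2], x$shape[3], x$voxel_size_um,
    length(region_ids(x))
  ))
  invisible(x)
}

#' Nonzero region IDs present in a volume
#' @param volume an [atlas_volume()].
#' @return sorted integer vector of distinct nonzero labels.
#' @export
region_ids <- function(volume) {
  stopifnot(inherits(volume, "atlas_volume"))
  ids <- sort(unique(as.vector(volume$labels)))
  ids[ids != 0L]
}

#' Read / write a labeled volume (raw int32 + JSON sidecar)
#'
#' The on-disk format is a raw little-endian int32 dump in R array order
#' (first axis fastest) with a JSON sidecar `<path>.json` holding
#' `shape`, `voxel_size_um` and `axis_order`. IDs round-trip bit-exactly.
#'
#' @param path file path of the raw payload (sidecar is `<path>.json`).
#' @param voxel_size_um optional override; defaults to the sidecar value.
#' @param ml_axis medio-lateral axis, see [atlas_volume()].
#' @return [read_label_volume()] returns an `atlas_volume`;
#'   [write_label_volume()] returns `path` invisibly.
#' @export
read_label_volume <- function(path, voxel_size_um = NULL, ml_axis = 1L) {
  if (!file.exists(path)) {
    stop(sprintf("volume file not found: %s", path), call. = FALSE)
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop(sprintf("missing JSON sidecar: %s", sidecar), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$shape) || length(meta$shape) != 3L) {
    stop("volume format error: sidecar must carry a length-3 `shape`",
         call. = FALSE)
  }
  shape <- as.integer(meta$shape)
  n <- prod(shape)
  raw <- readBin(path, what = "integer", n = n + 1L, size = 4L,
                 endian = "little")
  if (length(raw) != n) {
    stop("volume format error: payload size disagrees with sidecar shape",
         call. = FALSE)
  }
  vs <- if (!is.null(voxel_size_um)) voxel_size_um
        else if (!is.null(meta$voxel_size_um)) meta$voxel_size_um else 1
  atlas_volume(array(raw, dim = shape), voxel_size_um = vs, ml_axis = ml_axis)
}

#' @rdname read_label_volume
#' @param volume an [atlas_volume()] to serialize.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "atlas_volume"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(volume$labels), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(shape = volume$shape, voxel_size_um = volume$voxel_size_um,
         axis_order = "xyz"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
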