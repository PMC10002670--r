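#' Linear anchoring of a section plane in atlas space
#'
#' The linear registration of a section image is nine numbers: `o`, the atlas
#' coordinate (voxel units) of the image's top-left corner; `u`, the vector
#' spanning the image width; and `v`, the vector spanning the image height.
#' `u` and `v` must be nonzero and non-parallel.
#'
#' @param o,u,v numeric length-3 vectors in atlas voxel units.
#' @return object of class `linear_anchoring`.
#' @export
linear_anchoring <- function(o, u, v) {
  o <- as.numeric(o); u <- as.numeric(u); v <- as.numeric(v)
  if (length(o) != 3L || length(u) != 3L || length(v) != 3L) {
    stop("o, u, v must each have length 3", call. = FALSE)
  }
  if (any(!is.finite(c(o, u, v)))) {
    stop("anchoring values must be finite", call. = FALSE)
  }
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  if (sqrt(sum(u^2)) == 0 || sqrt(sum(v^2)) == 0 ||
      sqrt(sum(cr^2)) < 1e-12 * sqrt(sum(u^2)) * sqrt(sum(v^2))) {
    stop("geometry error: u and v must be nonzero and non-parallel",
         call. = FALSE)
  }
  structure(list(o = o, u = u, v = v), class = "linear_anchoring")
}

#' @export
print.linear_anchoring <- function(x, ...) {
  cat(sprintf("<linear_anchoring> o=(%s) u=(%s) v=(%s)\n",
              paste(signif(x$o, 4), collapse = ","),
              paste(signif(x$u, 4), collapse = ","),
              paste(signif(x$v, 4), collapse = ",")))
  invisible(x)
}

#' 2D per-pixel atlas map
#'
#' Result of slicing (and optionally warping) the atlas for one section:
#' a `height x width` integer matrix of region IDs, 0 outside the volume.
#' Matrix rows index the image y axis (downward), columns the x axis.
#'
#' @param region_ids integer matrix (`height` rows, `width` columns).
#' @param provenance `"linear"` (slicing only) or `"nonlinear"` (warped).
#' @return object of class `atlas_map`.
#' @export
atlas_map <- function(region_ids, provenance = c("linear", "nonlinear")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(region_ids)) stop("`region_ids` must be a matrix",
                                   call. = FALSE)
  storage.mode(region_ids) <- "integer"
  structure(
    list(region_ids = region_ids, width = ncol(region_ids),
         height = nrow(region_ids), provenance = provenance),
    class = "atlas_map"
  )
}

#' @export
print.atlas_map <- function(x, ...) {
  cat(sprintf("<atlas_map> %dx%d px (%s), %d region IDs\n", x$width, x$height,
              x$provenance, length(setdiff(unique(as.vector(x$region_ids)), 0L))))
  invisible(x)
}

#' Slice an atlas volume along a linearly anchored plane
#'
#' Produces the per-pixel atlas map for a `width x height` section image.
#' Pixel `(x, y)` (0-based, x rightward, y downward) samples the atlas at
#' `p = o + ((x + 0.5) / width) * u + ((y + 0.5) / height) * v`
#' (pixel-center convention) with nearest-voxel lookup: each continuous
#' coordinate is rounded half-up per axis, and points falling outside the
#' volume yield 0.
#'
#' An axis-aligned anchoring with `o = (-0.5, -0.5, k)`, `u = (nx, 0, 0)`,
#' `v = (0, ny, 0)` reproduces the stored slice `labels[, , k + 1]` exactly at
#' native resolution.
#'
#' @param volume an [atlas_volume()].
#' @param anchoring a [linear_anchoring()].
#' @param width,height output pixel dimensions (>= 1).
#' @return an [atlas_map()] with provenance `"linear"`.
#' @export
slice_atlas <- function(volume, anchoring, width, height) {
  stopifnot(inherits(volume, "atlas_volume"),
            inherits(anchoring, "linear_anchoring"))
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stop("width and height must be >= 1",
                                      call. = FALSE)
  o <- anchoring$o; u <- anchoring$u; v <- anchoring$v
  fx <- (seq_len(width) - 0.5) / width
  fy <- (seq_len(height) - 0.5) / height
  nx <- volume$shape[1]; ny <- volume$shape[2]; nz <- volume$shape[3]
  # per-axis continuous coordinates, height x width matrices
  ix <- floor(outer(fy * v[1], fx * u[1], "+") + o[1] + 0.5)
  iy <- floor(outer(fy * v[2], fx * u[2], "+") + o[2] + 0.5)
  iz <- floor(outer(fy * v[3], fx * u[3], "+") + o[3] + 0.5)
  ok <- ix >= 0 & ix < nx & iy >= 0 & iy < ny & iz >= 0 & iz < nz
  out <- matrix(0L, nrow = height, ncol = width)
  if (any(ok)) {
    lin <- 1 + ix[ok] + nx * (iy[ok] + ny * iz[ok])
    out[ok] <- volume$labels[lin]
  }
  atlas_map(out, provenance = "linear")
}

#' Read / write registration descriptor files
#'
#' JSON dialect compatible with common section-registration tools:
#' \preformatted{
#' {"name": ..., "target": ...,
#'  "slices": [{"filename", "nr", "width", "height",
#'              "anchoring": [ox,oy,oz,ux,uy,uz,vx,vy,vz],
#'              "markers": [[tx,ty,sx,sy], ...]}]}
#' }
#' `markers` is optional; absent means linear registration only. An anchoring
#' of the wrong arity, or markers without an anchoring, is a format error.
#'
#' @param path JSON file.
#' @return list with `name`, `target` and `sections`; each section is a list
#'   `(filename, nr, width, height, anchoring, deformation)` where
#'   `anchoring` is a [linear_anchoring()] and `deformation` is a
#'   [deformation_spec()] or `NULL`.
#' @export
read_registration <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$slices)) {
    stop("registration format error: no `slices` array", call. = FALSE)
  }
  sections <- lapply(doc$slices, function(s) {
    if (is.null(s$anchoring)) {
      stop("registration format error: slice without `anchoring`",
           call. = FALSE)
    }
    a <- as.numeric(unlist(s$anchoring))
    if (length(a) != 9L) {
      stop(sprintf(
        "registration format error: anchoring must have 9 numbers, got %d",
        length(a)), call. = FALSE)
    }
    width <- as.integer(s$width); height <- as.integer(s$height)
    deformation <- NULL
    if (!is.null(s$markers) && length(s$markers)) {
      mk <- do.call(rbind, lapply(s$markers, function(m) as.numeric(unlist(m))))
      if (ncol(mk) != 4L) {
        stop("registration format error: markers must be [tx,ty,sx,sy]",
             call. = FALSE)
      }
      deformation <- deformation_spec(
        anchors = data.frame(sx = mk[, 3], sy = mk[, 4],
                             tx = mk[, 1], ty = mk[, 2]),
        width = width, height = height)
    }
    list(filename = s$filename, nr = as.integer(s$nr),
         width = width, height = height,
         anchoring = linear_anchoring(a[1:3], a[4:6], a[7:9]),
         deformation = deformation)
  })
  list(name = doc$name, target = doc$target, sections = sections)
}

#' @rdname read_registration
#' @param reg a list as returned by [read_registration()].
#' @export
write_registration <- function(reg, path) {
  slices <- lapply(reg$sections, function(s) {
    out <- list(
      filename = s$filename, nr = s$nr, width = s$width, height = s$height,
      anchoring = c(s$anchoring$o, s$anchoring$u, s$anchoring$v))
    if (!is.null(s$deformation)) {
      a <- s$deformation$anchors
      out$markers <- lapply(seq_len(nrow(a)), function(i) {
        c(a$tx[i], a$ty[i], a$sx[i], a$sy[i])
      })
    }
    out
  })
  jsonlite::write_json(
    list(name = reg$name, target = reg$target, slices = slices),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Export / import an atlas map as raw int32 + JSON sidecar
#'
#' Flat dump of the per-pixel region IDs (row-major by image rows) with a
#' sidecar carrying `width`, `height` and `provenance`.
#' @param map an [atlas_map()].
#' @param path payload path; sidecar is `<path>.json`.
#' @export
write_atlas_map <- function(map, path) {
  stopifnot(inherits(map, "atlas_map"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(t(map$region_ids)), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(width = map$width, height = map$height, provenance = map$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_atlas_map
#' @export
read_atlas_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$width * meta$height
  raw <- readBin(path, what = "integer", n = n + 1L, size = 4L,
                 endian = "little")
  if (length(raw) != n) {
    stop("atlas map format error: payload size disagrees with sidecar",
         call. = FALSE)
  }
  m <- matrix(raw, nrow = meta$height, ncol = meta$width, byrow = TRUE)
  atlas_map(m, provenance = meta$provenance)
}

#' Stain-specific preprocessing scale factors
#'
#' Section images are downscaled per stain before segmentation and
#' registration (chosen to shrink files without visible information loss),
#' then halved again to meet registration-tool size limits. Registration
#' operates on the preprocessed dimensions.
#'
#' @param stain one of `"AB1-42"`, `"GFAP"`, `"Iba1"`, `"NeuN"`,
#'   `"thionine"`.
#' @param final_halving apply the extra 0.5 resize step.
#' @return scalar scale factor.
#' @export
stain_scale_factor <- function(stain, final_halving = TRUE) {
  base <- c(`AB1-42` = 0.20, GFAP = 0.40, Iba1 = 0.40, NeuN = 0.40,
            thionine = 0.35)
  if (!stain %in% names(base)) {
    stop(sprintf("unknown stain '%s'", stain), call. = FALSE)
  }
  unname(base[[stain]] * (if (final_halving) 0.5 else 1))
}
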