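#' Anchor-point deformation specification
#'
#' Nonlinear in-plane refinement is driven by user anchor points: pairs of a
#' source and a target position in section-pixel coordinates. The resulting
#' field maps each target-space position back to where it should sample the
#' linear atlas map (backward warping, appropriate for categorical region
#' IDs).
#'
#' @param anchors data.frame/matrix with columns `sx, sy, tx, ty` (source and
#'   target pixel coordinates); may have zero rows.
#' @param width,height section pixel dimensions.
#' @return object of class `deformation_spec`.
#' @export
deformation_spec <- function(anchors, width, height) {
  if (is.null(anchors) || (is.data.frame(anchors) && !nrow(anchors)) ||
      (is.matrix(anchors) && !nrow(anchors))) {
    anchors <- data.frame(sx = numeric(), sy = numeric(),
                          tx = numeric(), ty = numeric())
  }
  anchors <- as.data.frame(anchors)
  stopifnot(all(c("sx", "sy", "tx", "ty") %in% names(anchors)))
  width <- as.numeric(width); height <- as.numeric(height)
  if (nrow(anchors)) {
    with(anchors, {
      if (any(tx < 0 | tx > width | ty < 0 | ty > height)) {
        stop("anchor target points must lie within [0,width] x [0,height]",
             call. = FALSE)
      }
      if (any(!is.finite(sx)) || any(!is.finite(sy))) {
        stop("anchor source points must be finite", call. = FALSE)
      }
    })
    if (anyDuplicated(anchors[, c("tx", "ty")])) {
      stop("duplicate target anchor points", call. = FALSE)
    }
  }
  structure(list(anchors = anchors, width = width, height = height),
            class = "deformation_spec")
}

# TRUE for query points on or inside the convex hull of pts (n x 2).
# Degenerate hulls (fewer than 3 distinct points / collinear) contain nothing.
.in_hull <- function(pts, qx, qy, eps = 1e-9) {
  res <- rep(FALSE, length(qx))
  if (nrow(pts) < 3L) return(res)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(h) < 3L) return(res)
  hx <- pts[h, 1]; hy <- pts[h, 2]
  # orient counter-clockwise
  area2 <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  if (abs(area2) < eps) return(res)
  if (area2 < 0) { hx <- rev(hx); hy <- rev(hy) }
  inside <- rep(TRUE, length(qx))
  k <- length(hx)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    cross <- (hx[j] - hx[i]) * (qy - hy[i]) - (hy[j] - hy[i]) * (qx - hx[i])
    inside <- inside & (cross >= -eps)
  }
  inside
}

#' Build a continuous deformation field from anchor points
#'
#' The interpolant is piecewise linear over a Delaunay triangulation of the
#' anchor target points, augmented with fixed zero-displacement points at the
#' four image corners and edge midpoints so the field covers the entire image
#' and decays to identity at the frame. Frame points already on or inside the
#' convex hull of the targets (or coinciding with a target) are omitted, so
#' e.g. four corner anchors translated uniformly yield an exactly uniform
#' field. The displacement stored is target-to-source (`source - target`),
#' exact at every anchor; with zero anchors the field is identically zero.
#'
#' @param spec a [deformation_spec()].
#' @return object of class `deformation_field` with per-pixel displacement
#'   grids `dx`, `dy` (`height x width`, evaluated at pixel centers) plus the
#'   triangulation needed for exact point queries via [displacement_at()].
#' @export
build_deformation <- function(spec) {
  stopifnot(inherits(spec, "deformation_spec"))
  w <- spec$width; h <- spec$height
  a <- spec$anchors
  if (!nrow(a)) {
    fld <- list(nodes = NULL, disp = NULL, triangles = NULL,
                width = w, height = h,
                dx = matrix(0, h, w), dy = matrix(0, h, w))
    return(structure(fld, class = "deformation_field"))
  }
  nodes <- cbind(a$tx, a$ty)
  disp <- cbind(a$sx - a$tx, a$sy - a$ty)
  frame <- rbind(
    c(0, 0), c(w, 0), c(0, h), c(w, h),
    c(w / 2, 0), c(0, h / 2), c(w, h / 2), c(w / 2, h))
  covered <- .in_hull(nodes, frame[, 1], frame[, 2])
  dup <- vapply(seq_len(nrow(frame)), function(i) {
    any(abs(nodes[, 1] - frame[i, 1]) < 1e-9 &
        abs(nodes[, 2] - frame[i, 2]) < 1e-9)
  }, logical(1))
  keep <- !(covered | dup)
  if (any(keep)) {
    nodes <- rbind(nodes, frame[keep, , drop = FALSE])
    disp <- rbind(disp, matrix(0, sum(keep), 2))
  }
  dd <- deldir::deldir(nodes[, 1], nodes[, 2], suppressMsge = TRUE)
  tri <- deldir::triMat(dd)
  fld <- structure(
    list(nodes = nodes, disp = disp, triangles = tri, width = w, height = h,
         dx = NULL, dy = NULL),
    class = "deformation_field")
  cx <- rep(seq_len(w) - 0.5, each = h)
  cy <- rep(seq_len(h) - 0.5, times = w)
  d <- displacement_at(fld, cx, cy)
  fld$dx <- matrix(d[, 1], h, w)
  fld$dy <- matrix(d[, 2], h, w)
  fld
}

#' @export
print.deformation_field <- function(x, ...) {
  n <- if (is.null(x$nodes)) 0L else nrow(x$nodes)
  cat(sprintf("<deformation_field> %gx%g px, %d nodes, max |d| = %.3g px\n",
              x$width, x$height, n, max(abs(c(x$dx, x$dy)))))
  invisible(x)
}

#' Evaluate a deformation field at arbitrary points
#'
#' Barycentric piecewise-linear interpolation over the field's triangulation;
#' points outside every triangle (possible only outside the image frame) get
#' zero displacement. At an anchor target the result equals
#' `source - target` exactly (up to machine arithmetic).
#'
#' @param field a [build_deformation()] result.
#' @param x,y numeric vectors of query coordinates (pixel units).
#' @return numeric matrix with columns `dx`, `dy`.
#' @export
displacement_at <- function(field, x, y) {
  stopifnot(inherits(field, "deformation_field"))
  n <- length(x)
  out <- matrix(0, n, 2, dimnames = list(NULL, c("dx", "dy")))
  if (is.null(field$triangles) || !nrow(field$triangles)) return(out)
  nodes <- field$nodes; disp <- field$disp
  unassigned <- rep(TRUE, n)
  eps <- 1e-9
  for (t in seq_len(nrow(field$triangles))) {
    if (!any(unassigned)) break
    vi <- field$triangles[t, ]
    ax <- nodes[vi[1], 1]; ay <- nodes[vi[1], 2]
    bx <- nodes[vi[2], 1]; by <- nodes[vi[2], 2]
    cx <- nodes[vi[3], 1]; cy <- nodes[vi[3], 2]
    det <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
    if (abs(det) < 1e-12) next
    idx <- which(unassigned)
    px <- x[idx]; py <- y[idx]
    l1 <- ((by - cy) * (px - cx) + (cx - bx) * (py - cy)) / det
    l2 <- ((cy - ay) * (px - cx) + (ax - cx) * (py - cy)) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -eps & l2 >= -eps & l3 >= -eps
    if (!any(inside)) next
    hit <- idx[inside]
    out[hit, 1] <- l1[inside] * disp[vi[1], 1] + l2[inside] * disp[vi[2], 1] +
      l3[inside] * disp[vi[3], 1]
    out[hit, 2] <- l1[inside] * disp[vi[1], 2] + l2[inside] * disp[vi[2], 2] +
      l3[inside] * disp[vi[3], 2]
    unassigned[hit] <- FALSE
  }
  out
}

#' Warp an atlas map through a deformation field
#'
#' Backward warping with nearest-neighbor sampling: output pixel `(x, y)`
#' takes the input map value at the pixel containing
#' `(x + 0.5, y + 0.5) + displacement(x, y)`; positions falling outside the
#' map yield 0. Nearest-neighbor is mandatory because region IDs are
#' categorical. The warped map can contain no labels absent from the input,
#' and a zero field is the identity.
#'
#' @param map an [atlas_map()].
#' @param field a [build_deformation()] result with matching dimensions.
#' @return an [atlas_map()] with provenance `"nonlinear"`.
#' @export
warp_atlas_map <- function(map, field) {
  stopifnot(inherits(map, "atlas_map"), inherits(field, "deformation_field"))
  if (map$width != field$width || map$height != field$height) {
    stop("map and field dimensions disagree", call. = FALSE)
  }
  h <- map$height; w <- map$width
  cx <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  cy <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  sx <- cx + field$dx
  sy <- cy + field$dy
  col <- floor(sx) + 1
  row <- floor(sy) + 1
  ok <- col >= 1 & col <= w & row >= 1 & row <= h
  out <- matrix(0L, h, w)
  out[ok] <- map$region_ids[cbind(row[ok], col[ok])]
  atlas_map(out, provenance = "nonlinear")
}

#' Atlas map for a section, linear or nonlinearly refined
#'
#' Convenience wrapper: slices the atlas with the section's linear anchoring
#' and, when a deformation spec is present and `nonlinear = TRUE`, warps the
#' result through the anchor-point field.
#'
#' @param volume an [atlas_volume()].
#' @param section one element of `read_registration()$sections`.
#' @param nonlinear apply the nonlinear refinement when available.
#' @return an [atlas_map()].
#' @export
section_atlas_map <- function(volume, section, nonlinear = TRUE) {
  m <- slice_atlas(volume, section$anchoring, section$width, section$height)
  if (nonlinear && !is.null(section$deformation)) {
    m <- warp_atlas_map(m, build_deformation(section$deformation))
  }
  m
}
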