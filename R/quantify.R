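#' Binary segmentation image
#'
#' Output of the pixel-classification step: each pixel is either `label`
#' (stained) or `background`. Stored as a logical `height x width` matrix
#' (TRUE = stained), matching the paired atlas map's orientation.
#'
#' @param pixels logical matrix (`height` rows, `width` columns).
#' @param stain stain name (free text; conventional values `NeuN`, `GFAP`,
#'   `Iba1`, `AB1-42`, `thionine`, `other`).
#' @return object of class `segmentation_image`.
#' @export
segmentation_image <- function(pixels, stain = "other") {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    stop("`pixels` must be a logical matrix", call. = FALSE)
  }
  structure(list(pixels = pixels, width = ncol(pixels),
                 height = nrow(pixels), stain = stain),
            class = "segmentation_image")
}

#' @export
print.segmentation_image <- function(x, ...) {
  cat(sprintf("<segmentation_image> %dx%d px (%s), %d stained\n",
              x$width, x$height, x$stain, sum(x$pixels)))
  invisible(x)
}

#' Read / write a segmentation as 8-bit PNG
#'
#' Convention: 0 = background, 255 = label, grayscale 8-bit.
#' @param path PNG file.
#' @param stain stain tag to attach on read.
#' @export
read_segmentation_png <- function(path, stain = "other") {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  segmentation_image(img > 0.5, stain = stain)
}

#' @rdname read_segmentation_png
#' @param seg a [segmentation_image()].
#' @export
write_segmentation_png <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation_image"))
  png::writePNG(ifelse(seg$pixels, 1, 0), path)
  invisible(path)
}

#' Label connected stained objects
#'
#' Maximal connected components of stained pixels under 8-connectivity
#' (diagonal neighbors touch; configurable to 4). Object IDs are 1..K in
#' order of each component's first pixel in column-major scan order. Object
#' identity is what lets a stained object straddling a region boundary be
#' split correctly between regions.
#'
#' @param seg a [segmentation_image()].
#' @param connectivity 8 (default) or 4.
#' @return list with `labels` (integer matrix, 0 = background) and
#'   `n_objects`.
#' @export
label_objects <- function(seg, connectivity = 8) {
  stopifnot(inherits(seg, "segmentation_image"), connectivity %in% c(4, 8))
  m <- seg$pixels
  h <- nrow(m); w <- ncol(m)
  idx <- which(m)  # column-major linear indices of stained pixels
  lab <- matrix(0L, h, w)
  if (!length(idx)) return(list(labels = lab, n_objects = 0L))
  rank <- integer(h * w)
  rank[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    root <- i
    while (parent[root] != root) root <- parent[root]
    while (parent[i] != root) { nxt <- parent[i]; parent[i] <<- root; i <- nxt }
    root
  }
  rows <- ((idx - 1L) %% h) + 1L
  cols <- ((idx - 1L) %/% h) + 1L
  # neighbor offsets scanning backwards: up, left (+ diagonals for 8-conn)
  offs <- list(c(-1L, 0L), c(0L, -1L))
  if (connectivity == 8) offs <- c(offs, list(c(-1L, -1L), c(1L, -1L)))
  for (off in offs) {
    ok <- rows + off[1] >= 1L & rows + off[1] <= h & cols + off[2] >= 1L
    nb <- idx[ok] + off[1] + off[2] * h
    src <- idx[ok]
    hit <- m[nb]
    a <- rank[src[hit]]; b <- rank[nb[hit]]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  ids <- match(roots, unique(roots))  # first-appearance order (scan order)
  lab[idx] <- ids
  list(labels = lab, n_objects = max(ids))
}

#' Per-region stained-pixel statistics for one section
#'
#' The regional load is the percentage of stained pixel area within the
#' region's pixel area. Only pixels inside the mask and with a nonzero atlas
#' label contribute — excluded pixels are absent from both numerator and
#' denominator. Pixels are pooled to the custom hierarchy; labels without a
#' selected ancestor are tallied under the reserved `UNMAPPED` row
#' (region_id -1). Objects intersecting several regions are split: each
#' region receives exactly its own stained pixels and counts the object once
#' (`n_objects` increments in every region the object overlaps).
#'
#' @param seg a [segmentation_image()].
#' @param map the paired [atlas_map()] (same dimensions).
#' @param hierarchy a [collapse_to_custom()] result covering the map's labels.
#' @param mask optional logical matrix (TRUE = keep), e.g. a hemisphere mask
#'   sliced to the section; `NULL` keeps everything.
#' @param connectivity object connectivity, see [label_objects()].
#' @return data.table: `region_id, region_area_px, stained_px, n_objects,
#'   load_pct` for every region with nonzero area under the mask.
#' @export
regional_counts <- function(seg, map, hierarchy, mask = NULL,
                            connectivity = 8) {
  stopifnot(inherits(seg, "segmentation_image"), inherits(map, "atlas_map"),
            inherits(hierarchy, "custom_hierarchy"))
  if (seg$width != map$width || seg$height != map$height) {
    stop("segmentation and atlas map dimensions disagree", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, map$height, map$width)
  }
  if (!identical(dim(mask), dim(map$region_ids))) {
    stop("mask dimensions disagree with the atlas map", call. = FALSE)
  }
  reg <- custom_region_of(hierarchy, map$region_ids)
  counted <- mask & map$region_ids != 0L
  area <- table(reg[counted])
  stained_mask <- seg$pixels & counted
  stained <- table(reg[stained_mask])
  obj <- label_objects(seg, connectivity = connectivity)
  if (obj$n_objects > 0L) {
    sel <- stained_mask & obj$labels > 0L
    pairs <- unique(data.table::data.table(
      object = obj$labels[sel], region_id = reg[sel]))
    nobj <- pairs[, .N, by = .(region_id)]
  } else {
    nobj <- data.table::data.table(region_id = integer(), N = integer())
  }
  out <- data.table::data.table(
    region_id = as.integer(names(area)),
    region_area_px = as.integer(area))
  st <- data.table::data.table(region_id = as.integer(names(stained)),
                               stained_px = as.integer(stained))
  out <- merge(out, st, by = "region_id", all.x = TRUE)
  out <- merge(out, nobj, by = "region_id", all.x = TRUE)
  out[is.na(stained_px), stained_px := 0L]
  out[is.na(N), N := 0L]
  data.table::setnames(out, "N", "n_objects")
  out[, load_pct := 100 * stained_px / region_area_px]
  data.table::setkey(out, region_id)
  out[]
}

#' Pool per-section regional stats to the brain level
#'
#' The brain-level load keeps the "% stained area per region area" meaning:
#' it is computed from pixel sums over the kept sections,
#' `100 * sum(stained_px) / sum(region_area_px)`, not as a mean of section
#' loads (offered via `method = "mean_of_sections"` for sensitivity
#' analysis). Sections listed in `excluded_sections` (e.g. damaged ones) are
#' removed first. A region present only in excluded sections is reported
#' with `NA` load.
#'
#' @param section_stats data.table of [regional_counts()] rows with an added
#'   `section_id` column.
#' @param excluded_sections character vector of section IDs to drop.
#' @param method pooling rule.
#' @return data.table per region: pooled `region_area_px`, `stained_px`,
#'   `n_objects` (summed), `load_pct`, `n_sections`.
#' @export
brain_load <- function(section_stats, excluded_sections = character(),
                       method = c("pixel_sum", "mean_of_sections")) {
  method <- match.arg(method)
  dt <- data.table::as.data.table(section_stats)
  stopifnot(all(c("section_id", "region_id", "region_area_px",
                  "stained_px") %in% names(dt)))
  all_regions <- unique(dt$region_id)
  kept <- dt[!section_id %in% excluded_sections]
  pooled <- kept[, .(
    region_area_px = sum(region_area_px),
    stained_px = sum(stained_px),
    n_objects = if ("n_objects" %in% names(dt)) sum(n_objects) else NA_integer_,
    load_pct = if (method == "pixel_sum") {
      100 * sum(stained_px) / sum(region_area_px)
    } else {
      mean(100 * stained_px / region_area_px)
    },
    n_sections = data.table::uniqueN(section_id)
  ), keyby = .(region_id)]
  missing <- setdiff(all_regions, pooled$region_id)
  if (length(missing)) {
    pooled <- rbind(pooled, data.table::data.table(
      region_id = missing, region_area_px = 0L, stained_px = 0L,
      n_objects = 0L, load_pct = NA_real_, n_sections = 0L))
    data.table::setkey(pooled, region_id)
  }
  pooled[]
}

#' Per-region load difference between two registrations
#'
#' Quantifies how much the nonlinear refinement moves regional loads:
#' `difference = nonlinear load - linear load` per brain/stain/region, then
#' mean and SEM across brains.
#'
#' @param linear,nonlinear data.frames with columns `brain_id`, `region_id`,
#'   `load_pct` (and optionally `stain`), from the linear-only and the
#'   refined registration respectively. Keys must match one-to-one.
#' @return data.table per region (and stain if present): `mean_diff`,
#'   `sem_diff`, `n`.
#' @export
load_difference <- function(linear, nonlinear) {
  lin <- data.table::as.data.table(linear)
  non <- data.table::as.data.table(nonlinear)
  keys <- intersect(c("brain_id", "stain", "region_id"), names(lin))
  stopifnot(all(c("brain_id", "region_id", "load_pct") %in% names(lin)),
            all(keys %in% names(non)))
  if (nrow(lin) != nrow(non)) {
    stop("mismatched keys between linear and nonlinear reports",
         call. = FALSE)
  }
  merged <- merge(lin[, c(keys, "load_pct"), with = FALSE],
                  non[, c(keys, "load_pct"), with = FALSE],
                  by = keys, suffixes = c("_linear", "_nonlinear"))
  if (nrow(merged) != nrow(lin)) {
    stop("mismatched keys between linear and nonlinear reports",
         call. = FALSE)
  }
  merged[, diff := load_pct_nonlinear - load_pct_linear]
  by_cols <- setdiff(keys, "brain_id")
  merged[, .(
    mean_diff = mean(diff),
    sem_diff = if (.N >= 2L) stats::sd(diff) / sqrt(.N) else NA_real_,
    n = .N
  ), keyby = by_cols]
}

#' Write / read a load report TSV
#'
#' Columns: `brain_id, stain, section_id, region_id, region_area_px,
#' stained_px, n_objects, load_pct` (missing columns allowed on write).
#' @param report data.frame of load rows.
#' @param path TSV file.
#' @export
write_load_report <- function(report, path) {
  data.table::fwrite(as.data.frame(report), path, sep = "\t")
  invisible(path)
}

#' @rdname write_load_report
#' @export
read_load_report <- function(path) {
  data.table::fread(path, sep = "\t")
}
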