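#' Systematic sampling grid
#'
#' Quality control assessments (registration accuracy, section damage) use
#' stereology-style systematic sampling: markers on a regular grid overlaid on
#' the section. Spacing is stated in atlas voxels and converted to pixels via
#' the section's linear anchoring. The grid origin offset defaults to half the
#' spacing in both axes, giving deterministic "systematic" sampling; pass an
#' explicit offset (e.g. drawn from a seeded RNG) for a random start.
#'
#' @param spacing_px grid spacing in pixels (>= 1).
#' @param origin_offset_px numeric length-2 `(ox, oy)`; default
#'   `floor(spacing_px / 2)` in both axes.
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(spacing_px, origin_offset_px = NULL) {
  if (!is.numeric(spacing_px) || length(spacing_px) != 1L || spacing_px < 1) {
    stop("`spacing_px` must be a scalar >= 1", call. = FALSE)
  }
  if (is.null(origin_offset_px)) {
    origin_offset_px <- rep(floor(spacing_px / 2), 2L)
  }
  stopifnot(length(origin_offset_px) == 2L, all(origin_offset_px >= 0))
  structure(list(spacing_px = as.numeric(spacing_px),
                 origin_offset_px = as.numeric(origin_offset_px)),
            class = "grid_spec")
}

#' Convert a voxel-stated grid spacing to pixels
#'
#' Grid spacings are quoted in atlas voxels (e.g. 5-voxel damage grid,
#' 15-voxel accuracy grid) while markers live in section pixels. One pixel
#' spans `|u| / width` voxels along the image width, so
#' `spacing_px = spacing_voxels * width / |u|`.
#'
#' @param spacing_voxels spacing in atlas voxel units.
#' @param anchoring the section's [linear_anchoring()].
#' @param width section width in pixels.
#' @return spacing in pixels.
#' @export
voxel_spacing_to_pixels <- function(spacing_voxels, anchoring, width) {
  stopifnot(inherits(anchoring, "linear_anchoring"))
  nu <- sqrt(sum(anchoring$u^2))
  if (nu <= 0) stop("geometry error: zero-length u", call. = FALSE)
  spacing_voxels * width / nu
}

#' Generate systematic grid points over an image
#'
#' Points at `(ox + i * spacing, oy + j * spacing)` for integer `i, j >= 0`
#' that fall strictly inside the image (`0 <= x < width`, `0 <= y < height`),
#' in row-major order (rows of constant y).
#'
#' @param width,height image dimensions in pixels (>= 1).
#' @param spec a [grid_spec()].
#' @return data.frame with columns `x`, `y` (pixel coordinates).
#' @export
generate_grid <- function(width, height, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  if (width < 1 || height < 1) stop("image dims must be >= 1", call. = FALSE)
  s <- spec$spacing_px
  ox <- spec$origin_offset_px[1]; oy <- spec$origin_offset_px[2]
  xs <- if (ox < width) seq(ox, width - 1e-9, by = s) else numeric()
  xs <- xs[xs < width]
  ys <- if (oy < height) seq(oy, height - 1e-9, by = s) else numeric()
  ys <- ys[ys < height]
  if (!length(xs) || !length(ys)) {
    return(data.frame(x = numeric(), y = numeric()))
  }
  data.frame(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
}

.marker_labels <- c("accurate", "inaccurate", "uncertain", "damage", "none")

#' Marker set: grid-sampled rater judgments
#'
#' @param section_id,rater_id identifiers.
#' @param points data.frame with `x`, `y`, `label` (one of `accurate`,
#'   `inaccurate`, `uncertain`, `damage`, `none`) and `region_id` (the
#'   atlas-registered region under the point — the thing being audited).
#' @return object of class `marker_set` (a data.table).
#' @export
marker_set <- function(section_id, rater_id, points) {
  points <- data.table::as.data.table(points)
  need <- c("x", "y", "label", "region_id")
  stopifnot(all(need %in% names(points)))
  bad <- setdiff(unique(points$label), .marker_labels)
  if (length(bad)) {
    stop(sprintf("marker format error: unknown label(s) %s",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  dt <- data.table::data.table(
    section_id = as.character(section_id), rater_id = as.character(rater_id),
    points[, need, with = FALSE])
  data.table::setattr(dt, "class", c("marker_set", class(dt)))
  dt
}

#' Read / write marker files (TSV)
#'
#' Dialect: tab-separated with header
#' `section_id rater_id x y label region_id`. Round-trips losslessly; an
#' unknown label token is a format error; an empty file (header only) yields
#' an empty marker set.
#' @param path TSV file.
#' @export
read_marker_file <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = c("section_id", "rater_id", "label"),
    numeric = c("x", "y"), integer = "region_id"))
  bad <- setdiff(unique(dt$label), .marker_labels)
  if (length(bad)) {
    stop(sprintf("marker format error: unknown label(s) %s",
                 paste(sQuote(bad), collapse = ", ")), call. = FALSE)
  }
  data.table::setattr(dt, "class", c("marker_set", class(dt)))
  dt
}

#' @rdname read_marker_file
#' @param markers a `marker_set` (or rbind of several).
#' @export
write_marker_file <- function(markers, path) {
  data.table::fwrite(as.data.frame(markers), path, sep = "\t")
  invisible(path)
}

#' Damage fraction of a section
#'
#' `damage = # damage markers / # total markers` over all markers on the
#' section. With zero markers the fraction is undefined (`NA`, never 0).
#'
#' @param markers a [marker_set()] for one section.
#' @return scalar in `[0, 1]`, or `NA_real_` for an empty set.
#' @export
score_damage <- function(markers) {
  n <- nrow(markers)
  if (!n) return(NA_real_)
  sum(markers$label == "damage") / n
}

#' Triage sections by damage
#'
#' Sections with damage fraction strictly greater than the threshold (default
#' 30%) are unsuited for analysis; a section at exactly the threshold is
#' kept. Order is preserved and the filter is idempotent.
#'
#' @param damage data.frame with columns `section_id` and `damage_fraction`.
#' @param threshold exclusion threshold (strict `>`).
#' @return list with `kept` and `excluded` data.frames.
#' @export
filter_damaged_sections <- function(damage, threshold = 0.30) {
  damage <- as.data.frame(damage)
  stopifnot(all(c("section_id", "damage_fraction") %in% names(damage)))
  if (!nrow(damage)) return(list(kept = damage, excluded = damage))
  if (anyNA(damage$damage_fraction)) {
    stop("damage fraction undefined for some sections", call. = FALSE)
  }
  drop <- damage$damage_fraction > threshold
  list(kept = damage[!drop, , drop = FALSE],
       excluded = damage[drop, , drop = FALSE])
}

#' Accuracy and uncertainty scores from marker counts
#'
#' For one region/rater/brain assessment:
#' `accuracy = acc / (acc + inacc)` — undefined (`NA`) when no marker could
#' be verified (`acc + inacc == 0`), e.g. a region marked entirely uncertain;
#' such assessments are excluded from mean accuracy downstream.
#' `uncertainty = unc / (acc + inacc + unc)` — always defined when any
#' marker is present. High uncertainty flags that the accuracy score speaks
#' for a limited part of the region only.
#'
#' @param n_accurate,n_inaccurate,n_uncertain non-negative marker counts.
#' @return list with `accuracy` and `uncertainty` (each possibly `NA`).
#' @export
score_region <- function(n_accurate, n_inaccurate, n_uncertain) {
  stopifnot(n_accurate >= 0, n_inaccurate >= 0, n_uncertain >= 0)
  total <- n_accurate + n_inaccurate + n_uncertain
  if (total == 0) {
    stop("no markers in region: no result", call. = FALSE)
  }
  verif <- n_accurate + n_inaccurate
  list(
    accuracy = if (verif > 0) n_accurate / verif else NA_real_,
    uncertainty = n_uncertain / total
  )
}

#' Count markers per region for one assessment
#'
#' @param markers a [marker_set()] (accuracy grid labels).
#' @return data.table: `region_id, n_accurate, n_inaccurate, n_uncertain,
#'   accuracy, uncertainty` (regions with zero markers absent). Markers over
#'   background (region 0) or labeled `none`/`damage` are ignored.
#' @export
score_markers_by_region <- function(markers) {
  dt <- data.table::as.data.table(as.data.frame(markers))
  dt <- dt[region_id != 0L & label %in% c("accurate", "inaccurate", "uncertain")]
  out <- dt[, .(
    n_accurate = sum(label == "accurate"),
    n_inaccurate = sum(label == "inaccurate"),
    n_uncertain = sum(label == "uncertain")
  ), by = .(region_id)]
  out[, c("accuracy", "uncertainty") := {
    s <- Map(score_region, n_accurate, n_inaccurate, n_uncertain)
    .(vapply(s, `[[`, numeric(1), "accuracy"),
      vapply(s, `[[`, numeric(1), "uncertainty"))
  }]
  data.table::setkey(out, region_id)
  out[]
}

#' Aggregate per-assessment scores to regional means
#'
#' One assessment = one rater on one brain. The regional mean is the summed
#' score over assessments divided by the number of assessments; undefined
#' accuracy entries (all-uncertain assessments) are excluded from the
#' accuracy mean and its `n`. SEM uses the sample SD (`n - 1` denominator)
#' over `sqrt(n)` and is `NA` when `n < 2`. Regions with zero defined
#' accuracy assessments are reported with `n = 0` and `NA` mean.
#'
#' @param assessments data.frame with columns `region_id`, `rater_id`,
#'   `brain_id`, `accuracy`, `uncertainty` (accuracy may be `NA`).
#' @return data.table keyed by region with mean/SEM/n for both scores.
#' @export
aggregate_scores <- function(assessments) {
  dt <- data.table::as.data.table(assessments)
  stopifnot(all(c("region_id", "accuracy", "uncertainty") %in% names(dt)))
  sem <- function(x) if (length(x) >= 2L) stats::sd(x) / sqrt(length(x))
         else NA_real_
  dt[, {
    acc <- accuracy[!is.na(accuracy)]
    unc <- uncertainty[!is.na(uncertainty)]
    .(accuracy_mean = if (length(acc)) mean(acc) else NA_real_,
      accuracy_sem = sem(acc),
      accuracy_n = length(acc),
      uncertainty_mean = if (length(unc)) mean(unc) else NA_real_,
      uncertainty_sem = sem(unc),
      uncertainty_n = length(unc))
  }, keyby = .(region_id)]
}

#' Maximum number of assessments implied by a rater-per-brain design
#'
#' Each brain contributes one assessment per rater that scored it, so the
#' maximum per-region assessment count is the sum of raters over brains
#' (e.g. 10+7+7+6+6 = 36 for the nonlinear-refined registration, 2 raters
#' on each of 5 brains = 10 for the linear-only registration).
#'
#' @param raters_per_brain integer vector, raters assessing each brain.
#' @return integer total.
#' @export
max_assessments <- function(raters_per_brain) {
  stopifnot(all(raters_per_brain >= 0))
  as.integer(sum(raters_per_brain))
}

#' Write a QC report TSV
#' @param report [aggregate_scores()] output (optionally merged with counts).
#' @param path output TSV.
#' @export
write_qc_report <- function(report, path) {
  data.table::fwrite(as.data.frame(report), path, sep = "\t")
  invisible(path)
}
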