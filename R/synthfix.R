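#' Deterministic synthetic atlas with a nested ontology
#'
#' Builds a labeled volume whose "brain" is an axis-aligned box split into
#' major divisions along the third axis and leaf regions along the first —
#' a three-level ontology (root, divisions, leaves) whose leaves tile the
#' brain exactly. Split positions are jittered per seed; the same seed gives
#' a bit-identical volume. Expected per-leaf voxel counts are attached as
#' ground truth (computed by box arithmetic, independently of any labeling
#' code).
#'
#' @param shape integer length-3 voxel dimensions.
#' @param n_major number of major divisions (>= 1).
#' @param leaves_per_major leaf regions within each division (>= 1).
#' @param margin background margin (voxels) around the brain box.
#' @param voxel_size_um voxel size.
#' @param seed integer seed.
#' @return list with `volume` ([atlas_volume()]), `ontology`
#'   ([build_ontology()]) and `truth` (data.table `region_id`, `n_voxels`).
#' @export
make_synthetic_atlas <- function(shape = c(32L, 32L, 32L), n_major = 4L,
                                 leaves_per_major = 2L, margin = 2L,
                                 voxel_size_um = 25, seed = 1L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L), n_major >= 1L,
            leaves_per_major >= 1L, margin >= 0L)
  lo <- rep(margin + 1L, 3L)             # 1-based inclusive brain box
  hi <- shape - margin
  if (any(hi - lo + 1L < c(leaves_per_major, 1L, n_major))) {
    stop("spec error: shape too small for the requested region layout",
         call. = FALSE)
  }
  jitter_breaks <- function(from, to, k) {
    # k segments covering from..to, deterministic jitter around even splits
    if (k == 1L) return(c(from, to + 1L))
    base <- as.integer(round(seq(from, to + 1L, length.out = k + 1L)))
    if (k > 1L) {
      mid <- 2:k
      wiggle <- sample(c(-1L, 0L, 1L), length(mid), replace = TRUE)
      base[mid] <- pmin(pmax(base[mid] + wiggle, from + 1L), to)
      base[mid] <- sort(base[mid])
    }
    base
  }
  res <- with_seed(seed, {
    zb <- jitter_breaks(lo[3], hi[3], n_major)
    xb <- lapply(seq_len(n_major), function(i) {
      jitter_breaks(lo[1], hi[1], leaves_per_major)
    })
    labels <- array(0L, dim = shape)
    records <- list(list(id = 1L, name = "brain", parent_id = NA_integer_))
    truth <- list()
    for (i in seq_len(n_major)) {
      major_id <- 1L + i
      records <- c(records, list(list(
        id = major_id, name = sprintf("division_%d", i), parent_id = 1L)))
      z1 <- zb[i]; z2 <- zb[i + 1L] - 1L
      for (j in seq_len(leaves_per_major)) {
        leaf_id <- 100L * major_id + j
        records <- c(records, list(list(
          id = leaf_id, name = sprintf("region_%d_%d", i, j),
          parent_id = major_id)))
        x1 <- xb[[i]][j]; x2 <- xb[[i]][j + 1L] - 1L
        labels[x1:x2, lo[2]:hi[2], z1:z2] <- leaf_id
        truth <- c(truth, list(list(
          region_id = leaf_id,
          n_voxels = (x2 - x1 + 1L) * (hi[2] - lo[2] + 1L) * (z2 - z1 + 1L))))
      }
    }
    list(labels = labels, records = records, truth = truth)
  })
  list(
    volume = atlas_volume(res$labels, voxel_size_um = voxel_size_um),
    ontology = build_ontology(data.table::rbindlist(res$records)),
    truth = data.table::rbindlist(res$truth)
  )
}

#' Section spacing from thickness and sampling interval
#'
#' Serial sections cut at a given thickness and sampled every `interval`-th
#' section are spaced `thickness_um * interval` apart (e.g. 40 um sections on
#' every 24th section: 960 um; every 12th: 480 um).
#'
#' @param thickness_um section thickness in micrometers (> 0).
#' @param interval sampling interval (>= 1).
#' @return spacing in micrometers.
#' @export
section_spacing_um <- function(thickness_um = 40, interval = 24) {
  stopifnot(thickness_um > 0, interval >= 1)
  thickness_um * interval
}

#' Specification for a synthetic brain series
#'
#' Stated-world defaults: 40 um sections sampled at the every-24th interval,
#' three emitted sections per series (a desk-scale stand-in for the ~9
#' sections a real hemibrain series yields), 3x3-pixel axis-aligned block
#' objects (exact pixel accounting), two objects per leaf region.
#'
#' @param n_sections sections to emit.
#' @param thickness_um,interval see [section_spacing_um()].
#' @param objects_per_region blocks to place in each leaf region present.
#' @param object_size integer `(height, width)` of each block in pixels.
#' @param stain stain tag for the segmentations.
#' @param deform_anchors number of random deformation anchor points per
#'   section (0 = linear registration only).
#' @param deform_max_px maximum anchor displacement in pixels.
#' @return list of class `synth_brain_spec`.
#' @export
synth_brain_spec <- function(n_sections = 3L, thickness_um = 40,
                             interval = 24L, objects_per_region = 2L,
                             object_size = c(3L, 3L), stain = "NeuN",
                             deform_anchors = 0L, deform_max_px = 2) {
  structure(list(n_sections = as.integer(n_sections),
                 thickness_um = thickness_um, interval = as.integer(interval),
                 objects_per_region = as.integer(objects_per_region),
                 object_size = as.integer(object_size), stain = stain,
                 deform_anchors = as.integer(deform_anchors),
                 deform_max_px = deform_max_px),
            class = "synth_brain_spec")
}

# place a oh x ow block fully inside region rid on map `reg`, avoiding
# `occupied`; returns top-left (row, col) or NULL
.place_block <- function(reg, rid, oh, ow, occupied) {
  h <- nrow(reg); w <- ncol(reg)
  if (oh > h || ow > w) return(NULL)
  ok <- matrix(TRUE, h - oh + 1L, w - ow + 1L)
  good <- reg == rid & !occupied
  for (dr in seq_len(oh) - 1L) {
    for (dc in seq_len(ow) - 1L) {
      ok <- ok & good[seq_len(h - oh + 1L) + dr, seq_len(w - ow + 1L) + dc,
                      drop = FALSE]
    }
  }
  cand <- which(ok)
  if (!length(cand)) return(NULL)
  pick <- cand[[sample.int(length(cand), 1L)]]
  c(row = ((pick - 1L) %% nrow(ok)) + 1L,
    col = ((pick - 1L) %/% nrow(ok)) + 1L)
}

#' Generate a synthetic brain series with known ground truth
#'
#' Emits, for one synthetic brain: a registration descriptor (linear
#' anchorings, optionally with deformation anchor points), per-section binary
#' segmentations containing axis-aligned block objects of known size placed
#' inside leaf regions, and the exact per-section/per-region ground truth
#' (area, stained pixels, load) obtained by direct per-pixel tallying against
#' the emitted atlas maps — the "objects of known size and anatomical
#' location" validation strategy. Sections are planes of constant y slicing
#' the volume (u along x, v along z) so every division is visible.
#'
#' @param atlas a [make_synthetic_atlas()] result.
#' @param spec a [synth_brain_spec()].
#' @param seed integer seed (bit-identical outputs per seed).
#' @param dir optional directory; when given, writes `registration.json`,
#'   `section_<k>.png` and `ground_truth.json` there.
#' @return list: `registration` (as consumed by [write_registration()]),
#'   `segmentations`, `maps`, `truth` (data.table `section_id, region_id,
#'   area_px, stained_px, load_pct`), `spacing_um`.
#' @export
make_synthetic_brain <- function(atlas, spec = synth_brain_spec(), seed = 1L,
                                 dir = NULL) {
  vol <- atlas$volume
  nx <- vol$shape[1]; ny <- vol$shape[2]; nz <- vol$shape[3]
  width <- nx; height <- nz
  # y planes that intersect the brain
  ys <- which(apply(vol$labels != 0L, 2, any)) - 1L
  if (!length(ys)) stop("spec error: atlas has no labeled voxels",
                        call. = FALSE)
  take <- unique(round(seq(min(ys), max(ys),
                           length.out = spec$n_sections)))
  res <- with_seed(child_seed(seed, 1L), {
    sections <- list()
    segs <- list()
    maps <- list()
    truth <- list()
    for (k in seq_along(take)) {
      anch <- linear_anchoring(o = c(-0.5, take[k], -0.5),
                               u = c(nx, 0, 0), v = c(0, 0, nz))
      m <- slice_atlas(vol, anch, width, height)
      deformation <- NULL
      if (spec$deform_anchors > 0L) {
        tx <- runif(spec$deform_anchors, 0.15 * width, 0.85 * width)
        ty <- runif(spec$deform_anchors, 0.15 * height, 0.85 * height)
        dx <- runif(spec$deform_anchors, -spec$deform_max_px,
                    spec$deform_max_px)
        dy <- runif(spec$deform_anchors, -spec$deform_max_px,
                    spec$deform_max_px)
        deformation <- deformation_spec(
          data.frame(sx = pmin(pmax(tx + dx, 0), width),
                     sy = pmin(pmax(ty + dy, 0), height),
                     tx = tx, ty = ty),
          width = width, height = height)
        m <- warp_atlas_map(m, build_deformation(deformation))
      }
      reg <- m$region_ids
      occupied <- matrix(FALSE, height, width)
      present <- setdiff(sort(unique(as.vector(reg))), 0L)
      for (rid in present) {
        for (rep_i in seq_len(spec$objects_per_region)) {
          pos <- .place_block(reg, rid, spec$object_size[1],
                              spec$object_size[2], occupied)
          if (is.null(pos)) next  # region too small/crowded: skip quietly
          occupied[pos[1]:(pos[1] + spec$object_size[1] - 1L),
                   pos[2]:(pos[2] + spec$object_size[2] - 1L)] <- TRUE
        }
      }
      sec_id <- sprintf("section_%02d", k)
      # ground truth by direct per-pixel tally
      area <- table(reg[reg != 0L])
      stained <- table(reg[occupied & reg != 0L])
      tr <- data.table::data.table(
        section_id = sec_id,
        region_id = as.integer(names(area)),
        area_px = as.integer(area))
      st <- data.table::data.table(region_id = as.integer(names(stained)),
                                   stained_px = as.integer(stained))
      tr <- merge(tr, st, by = "region_id", all.x = TRUE)
      tr[is.na(stained_px), stained_px := 0L]
      tr[, load_pct := 100 * stained_px / area_px]
      truth[[k]] <- tr
      segs[[sec_id]] <- segmentation_image(occupied, stain = spec$stain)
      maps[[sec_id]] <- m
      sections[[k]] <- list(filename = paste0(sec_id, ".png"),
                            nr = k * spec$interval,
                            width = width, height = height,
                            anchoring = anch, deformation = deformation)
    }
    list(sections = sections, segs = segs, maps = maps,
         truth = data.table::rbindlist(truth))
  })
  out <- list(
    registration = list(name = "synthetic_brain", target = "synthetic_atlas",
                        sections = res$sections),
    segmentations = res$segs,
    maps = res$maps,
    truth = data.table::setcolorder(
      res$truth, c("section_id", "region_id", "area_px", "stained_px",
                   "load_pct")),
    spacing_um = section_spacing_um(spec$thickness_um, spec$interval)
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_registration(out$registration, file.path(dir, "registration.json"))
    for (nm in names(out$segmentations)) {
      write_segmentation_png(out$segmentations[[nm]],
                             file.path(dir, paste0(nm, ".png")))
    }
    jsonlite::write_json(out$truth, file.path(dir, "ground_truth.json"),
                         digits = NA)
  }
  out
}

#' Simulated rater markups with known generative accuracy
#'
#' Places the systematic accuracy grid over a section's atlas map and labels
#' each on-tissue marker per rater: `uncertain` with probability
#' `p_uncertain`, otherwise `accurate` with probability `p_correct` and
#' `inaccurate` with the remainder. The generative accuracy (`p_correct`) is
#' what aggregated mean accuracy should converge to.
#'
#' @param map an [atlas_map()] for the section.
#' @param n_raters number of raters.
#' @param p_correct,p_uncertain generative probabilities.
#' @param grid a [grid_spec()].
#' @param seed integer seed.
#' @param section_id identifier stored in the marker sets.
#' @return single `marker_set` data.table covering all raters.
#' @export
make_synthetic_raters <- function(map, n_raters = 10L, p_correct = 0.8,
                                  p_uncertain = 0.1,
                                  grid = grid_spec(15), seed = 1L,
                                  section_id = "section_01") {
  stopifnot(inherits(map, "atlas_map"), p_correct >= 0, p_correct <= 1,
            p_uncertain >= 0, p_uncertain <= 1)
  pts <- generate_grid(map$width, map$height, grid)
  if (!nrow(pts)) stop("grid produced no points", call. = FALSE)
  rid <- map$region_ids[cbind(floor(pts$y) + 1L, floor(pts$x) + 1L)]
  keep <- rid != 0L
  pts <- pts[keep, , drop = FALSE]
  rid <- rid[keep]
  with_seed(child_seed(seed, 2L), {
    sets <- lapply(seq_len(n_raters), function(r) {
      n <- nrow(pts)
      unc <- runif(n) < p_uncertain
      acc <- runif(n) < p_correct
      label <- ifelse(unc, "uncertain", ifelse(acc, "accurate", "inaccurate"))
      marker_set(section_id, sprintf("rater_%02d", r),
                 data.frame(x = pts$x, y = pts$y, label = label,
                            region_id = rid))
    })
    data.table::rbindlist(sets)
  })
}

#' Simulated damage markup for a section
#'
#' Damage grid markers over on-tissue points: `damage` with probability
#' `p_damage`, else `none`.
#'
#' @inheritParams make_synthetic_raters
#' @param p_damage generative per-marker damage probability.
#' @export
make_synthetic_damage_markers <- function(map, p_damage = 0.1,
                                          grid = grid_spec(5), seed = 1L,
                                          section_id = "section_01") {
  pts <- generate_grid(map$width, map$height, grid)
  rid <- map$region_ids[cbind(floor(pts$y) + 1L, floor(pts$x) + 1L)]
  keep <- rid != 0L
  pts <- pts[keep, , drop = FALSE]
  rid <- rid[keep]
  with_seed(child_seed(seed, 3L), {
    label <- ifelse(runif(nrow(pts)) < p_damage, "damage", "none")
    marker_set(section_id, "damage_rater",
               data.frame(x = pts$x, y = pts$y, label = label,
                          region_id = rid))
  })
}

#' Synthetic per-animal load table
#'
#' Loads for two age groups with a stated between-group shift (in units of
#' the within-group SD) — the stated world for amyloid/glial-like stains
#' with strong, near-global age increases. Values are kept within [0, 100].
#'
#' @param n_per_group integer length-2 `(n_young, n_old)`.
#' @param base_load,within_sd young-group mean and within-group SD (%).
#' @param age_shift_sd between-group shift in within-SD units.
#' @param seed integer seed.
#' @return data.frame `brain_id, age_group, load`.
#' @export
synth_load_table <- function(n_per_group = c(17L, 20L), base_load = 5,
                             within_sd = 0.5, age_shift_sd = 8, seed = 1L) {
  with_seed(child_seed(seed, 4L), {
    n <- sum(n_per_group)
    age <- factor(rep(c("6m", "14m"), n_per_group), levels = c("6m", "14m"))
    mu <- ifelse(age == "14m", base_load + age_shift_sd * within_sd, base_load)
    load <- pmin(pmax(stats::rnorm(n, mu, within_sd), 0), 100)
    data.frame(brain_id = sprintf("brain_%02d", seq_len(n)),
               age_group = age, load = load)
  })
}

#' Specification for synthetic expression data
#'
#' Three generative gene classes matching the downstream classification:
#' `null` (no association), `load_driven` (association with the within-age
#' component of load but no marginal age difference in expression — the
#' age-independent archetype: load rises with age while expression does
#' not), and `age_driven` (expression shifts with age only; load and
#' expression are conditionally independent given age — the age-dependent
#' archetype). Defaults come from an a priori power/dilution analysis (see
#' the methods vignette): within-group effect `beta = 1` per within-SD of
#' load against `noise_sd = 1` (within-group r ~ 0.71), age-driven shift 2
#' noise-SDs. `age_var_sd` can add age-linked expression variance of random
#' sign to load_driven genes; it defaults to 0 because any such term
#' re-couples expression to load through the shared age shift.
#'
#' @param n_null,n_load,n_age genes per class.
#' @param beta load effect (load_driven genes).
#' @param noise_sd residual SD.
#' @param age_var_sd SD of an optional age-linked offset on load_driven
#'   genes (random sign per gene).
#' @param age_shift expression shift of age_driven genes (in noise SDs).
#' @param n_lowcount extra genes emitted below the ERC filter threshold.
#' @return list of class `synth_expression_spec`.
#' @export
synth_expression_spec <- function(n_null = 20L, n_load = 20L, n_age = 20L,
                                  beta = 1, noise_sd = 1, age_var_sd = 0,
                                  age_shift = 2, n_lowcount = 5L) {
  structure(list(n_null = as.integer(n_null), n_load = as.integer(n_load),
                 n_age = as.integer(n_age), beta = beta, noise_sd = noise_sd,
                 age_var_sd = age_var_sd, age_shift = age_shift,
                 n_lowcount = as.integer(n_lowcount)),
            class = "synth_expression_spec")
}

#' Synthetic expression matrix with known gene classes
#'
#' @param loads numeric per-sample regional loads.
#' @param ages factor per sample (two age groups).
#' @param spec a [synth_expression_spec()].
#' @param seed integer seed.
#' @return list: `norm` (genes x samples normalized/transformed matrix),
#'   `counts` (raw expected-read-count stand-in, includes the low-count
#'   genes), `truth` (data.table `gene, class`).
#' @export
make_synthetic_expression <- function(loads, ages,
                                      spec = synth_expression_spec(),
                                      seed = 1L) {
  stopifnot(length(loads) == length(ages))
  ages <- as.factor(ages)
  n <- length(loads)
  load_c <- loads - stats::ave(loads, ages)      # within-age component
  sw <- stats::sd(load_c)
  load_z <- if (sw > 0) load_c / sw else load_c
  age_num <- as.numeric(ages == levels(ages)[2])
  with_seed(child_seed(seed, 5L), {
    gen_row <- function(class) {
      eps <- stats::rnorm(n, 0, spec$noise_sd)
      switch(class,
        null = eps,
        load_driven = {
          s <- sample(c(-1, 1), 1L)
          spec$beta * load_z + s * spec$age_var_sd * age_num + eps
        },
        age_driven = spec$age_shift * spec$noise_sd * age_num + eps)
    }
    classes <- rep(c("null", "load_driven", "age_driven"),
                   c(spec$n_null, spec$n_load, spec$n_age))
    norm <- t(vapply(classes, gen_row, numeric(n)))
    rownames(norm) <- sprintf("gene_%03d", seq_along(classes))
    truth <- data.table::data.table(gene = rownames(norm), class = classes)
    # raw ERC stand-in: expressed genes well above the >10 filter,
    # plus deliberately low-count genes that must be filtered out
    mu <- stats::runif(nrow(norm), 6, 10)
    counts <- round(2^(mu + 0.25 * norm))
    if (spec$n_lowcount > 0L) {
      low <- matrix(stats::rpois(spec$n_lowcount * n, 3),
                    nrow = spec$n_lowcount)
      rownames(low) <- sprintf("lowcount_%03d", seq_len(spec$n_lowcount))
      counts <- rbind(counts, low)
    }
    list(norm = norm, counts = counts, truth = truth)
  })
}
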