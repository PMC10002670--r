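test_that("synthetic atlases are deterministic and leaves tile the brain", {
  a1 <- make_synthetic_atlas(seed = 7)
  a2 <- make_synthetic_atlas(seed = 7)
  expect_identical(a1$volume$labels, a2$volume$labels)
  expect_identical(a1$ontology$nodes, a2$ontology$nodes)
  a3 <- make_synthetic_atlas(seed = 8)
  expect_false(identical(a1$volume$labels, a3$volume$labels))

  # leaves tile the brain: every nonzero voxel carries a leaf ID, and the
  # per-leaf voxel counts match the generator's box-arithmetic ground truth
  leaves <- a1$truth$region_id
  expect_setequal(region_ids(a1$volume), leaves)
  tab <- table(a1$volume$labels[a1$volume$labels != 0L])
  expect_identical(as.integer(tab[as.character(a1$truth$region_id)]),
                   a1$truth$n_voxels)

  # three-level ontology: every leaf's chain is leaf -> division -> root
  for (l in leaves) {
    expect_length(ancestors(a1$ontology, l), 2L)
  }
  expect_error(make_synthetic_atlas(shape = c(3, 3, 3), n_major = 5),
               "spec error")
})

test_that("section spacing equals thickness times sampling interval", {
  expect_equal(section_spacing_um(40, 24), 960)
  expect_equal(section_spacing_um(40, 12), 480)
  expect_equal(section_spacing_um(40, 1), 40)
  expect_error(section_spacing_um(0, 5))
})

test_that("synthetic brains carry exact ground truth the pipeline recovers", {
  atl <- make_synthetic_atlas(seed = 9)
  br <- make_synthetic_brain(atl, synth_brain_spec(n_sections = 3L), seed = 9)
  hier <- collapse_to_custom(atl$ontology, atl$truth$region_id, atl$volume)
  for (sec in names(br$maps)) {
    rc <- regional_counts(br$segmentations[[sec]], br$maps[[sec]], hier)
    tr <- br$truth[br$truth$section_id == sec]
    data.table::setkey(tr, region_id)
    expect_identical(rc$region_id, tr$region_id)
    expect_identical(rc$region_area_px, tr$area_px)
    expect_identical(rc$stained_px, tr$stained_px)
    expect_identical(rc$load_pct, tr$load_pct)  # bit-equal, not approximate
  }
  # zero objects -> all loads zero
  br0 <- make_synthetic_brain(atl, synth_brain_spec(objects_per_region = 0L),
                              seed = 9)
  expect_true(all(br0$truth$load_pct == 0))
  # determinism
  br2 <- make_synthetic_brain(atl, synth_brain_spec(n_sections = 3L), seed = 9)
  expect_identical(br$truth, br2$truth)
})

test_that("emitted files parse back through the package readers", {
  dir <- withr::local_tempdir()
  atl <- make_synthetic_atlas(seed = 11)
  br <- make_synthetic_brain(atl, synth_brain_spec(n_sections = 2L),
                             seed = 11, dir = dir)
  reg <- read_registration(file.path(dir, "registration.json"))
  expect_length(reg$sections, 2L)
  seg <- read_segmentation_png(file.path(dir, "section_01.png"))
  expect_identical(seg$pixels, br$segmentations[["section_01"]]$pixels)
  # registration reproduces the emitted maps
  m <- section_atlas_map(atl$volume, reg$sections[[1]])
  expect_identical(m$region_ids, br$maps[[1]]$region_ids)
})

test_that("deformed synthetic brains still ground-truth exactly", {
  atl <- make_synthetic_atlas(seed = 12)
  br <- make_synthetic_brain(
    atl, synth_brain_spec(n_sections = 2L, deform_anchors = 3L), seed = 12)
  hier <- collapse_to_custom(atl$ontology, atl$truth$region_id, atl$volume)
  sec <- names(br$maps)[1]
  rc <- regional_counts(br$segmentations[[sec]], br$maps[[sec]], hier)
  tr <- br$truth[br$truth$section_id == sec]
  data.table::setkey(tr, region_id)
  expect_identical(rc$load_pct, tr$load_pct)
  expect_false(is.null(br$registration$sections[[1]]$deformation))
})

test_that("simulated raters at the probability extremes behave as stated", {
  atl <- make_synthetic_atlas(seed = 13)
  map <- make_synthetic_brain(atl, synth_brain_spec(n_sections = 1L),
                              seed = 13)$maps[[1]]
  perfect <- make_synthetic_raters(map, n_raters = 2L, p_correct = 1,
                                   p_uncertain = 0, grid = grid_spec(4),
                                   seed = 13)
  sc <- score_markers_by_region(perfect)
  expect_true(all(sc$accuracy == 1))

  unsure <- make_synthetic_raters(map, n_raters = 1L, p_correct = 0.5,
                                  p_uncertain = 1, grid = grid_spec(4),
                                  seed = 13)
  sc2 <- score_markers_by_region(unsure)
  expect_true(all(is.na(sc2$accuracy)))
  expect_true(all(sc2$uncertainty == 1))
})

test_that("synthetic damage markers drive the triage", {
  atl <- make_synthetic_atlas(seed = 14)
  map <- make_synthetic_brain(atl, synth_brain_spec(n_sections = 1L),
                              seed = 14)$maps[[1]]
  clean <- make_synthetic_damage_markers(map, p_damage = 0, seed = 14)
  expect_equal(score_damage(clean), 0)
  wrecked <- make_synthetic_damage_markers(map, p_damage = 1, seed = 14)
  expect_equal(score_damage(wrecked), 1)
})

test_that("synthetic expression honors its generative classes", {
  set.seed(0)
  tab <- synth_load_table(seed = 15)
  expect_equal(nrow(tab), 37L)
  expect_equal(as.vector(table(tab$age_group)), c(17L, 20L))

  ex <- make_synthetic_expression(
    tab$load, tab$age_group,
    synth_expression_spec(n_null = 5L, n_load = 5L, n_age = 5L), seed = 15)
  expect_equal(dim(ex$norm), c(15L, 37L))
  expect_equal(nrow(ex$counts), 15L + 5L)
  expect_identical(ex$truth$class,
                   rep(c("null", "load_driven", "age_driven"), each = 5L))
  # low-count genes fail the ERC filter; expressed genes pass
  kept <- filter_genes(ex$counts)
  expect_true(all(!grepl("^lowcount", rownames(kept))))
  expect_true(all(rownames(ex$norm) %in% rownames(kept)))

  # zero effects -> all classes generate pure noise
  ex0 <- make_synthetic_expression(
    tab$load, tab$age_group,
    synth_expression_spec(n_null = 2L, n_load = 2L, n_age = 2L,
                          beta = 0, age_var_sd = 0, age_shift = 0),
    seed = 15)
  res0 <- suppressWarnings(correlate_load_expression(
    ex0$norm, tab$load, tab$age_group))
  expect_true(all(res0$q_unadjusted > 0.05 | is.na(res0$q_unadjusted)) ||
              mean(res0$p_unadjusted < 0.05) <= 0.5)

  # huge load effect, no noise: adjusted r = 1
  ex1 <- make_synthetic_expression(
    tab$load, tab$age_group,
    synth_expression_spec(n_null = 0L, n_load = 1L, n_age = 0L,
                          beta = 5, noise_sd = 1e-9, age_var_sd = 1),
    seed = 15)
  r1 <- corr_age_adjusted(ex1$norm[1, ], tab$load, tab$age_group)
  expect_equal(r1$r, 1, tolerance = 1e-6)

  # determinism
  exa <- make_synthetic_expression(tab$load, tab$age_group, seed = 16)
  exb <- make_synthetic_expression(tab$load, tab$age_group, seed = 16)
  expect_identical(exa$norm, exb$norm)
})
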