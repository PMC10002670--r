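test_that("object labeling follows the declared connectivity", {
  px <- matrix(FALSE, 4, 4)
  px[1, 1] <- TRUE; px[2, 2] <- TRUE  # diagonal touch
  seg <- segmentation_image(px)
  expect_equal(label_objects(seg, 8)$n_objects, 1L)
  expect_equal(label_objects(seg, 4)$n_objects, 2L)

  empty <- segmentation_image(matrix(FALSE, 3, 3))
  expect_equal(label_objects(empty)$n_objects, 0L)
})

test_that("object labeling agrees with a flood-fill oracle", {
  set.seed(21)
  for (rep_i in 1:12) {
    px <- matrix(runif(18 * 15) < 0.35, 15, 18)
    seg <- segmentation_image(px)
    for (conn in c(8, 4)) {
      got <- label_objects(seg, conn)
      want <- oracle_flood_fill(px, conn)
      expect_equal(got$n_objects, want$n_objects)
      # both implementations number components by first pixel in
      # column-major scan order, so labels must match exactly
      expect_identical(got$labels, want$labels)
    }
  }
  # K isolated 3x3 blocks -> K objects
  px <- matrix(FALSE, 20, 20)
  origins <- list(c(1, 1), c(1, 10), c(8, 5), c(15, 14), c(12, 1))
  for (o in origins) px[o[1]:(o[1] + 2), o[2]:(o[2] + 2)] <- TRUE
  expect_equal(label_objects(segmentation_image(px))$n_objects, 5L)
})

make_flat_hierarchy <- function(ids) {
  ont <- build_ontology(data.frame(
    id = c(1L, ids), name = c("root", paste0("r", ids)),
    parent_id = c(NA, rep(1L, length(ids)))))
  lab <- array(rep(ids, length.out = 27), dim = c(3, 3, 3))
  collapse_to_custom(ont, ids, atlas_volume(lab))
}

test_that("regional loads are stained-over-area percentages", {
  h <- make_flat_hierarchy(c(10L, 20L))
  # 10x20 map: region 10 = left 10 columns (100 px), region 20 = rest
  m <- atlas_map(cbind(matrix(10L, 10, 10), matrix(20L, 10, 10)))
  px <- matrix(FALSE, 10, 20)
  px[1:5, 1:5] <- TRUE  # 25 stained px wholly inside region 10
  rc <- regional_counts(segmentation_image(px), m, h)
  expect_equal(rc[rc$region_id == 10L, ]$load_pct, 25)
  expect_equal(rc[rc$region_id == 10L, ]$region_area_px, 100L)
  expect_equal(rc[rc$region_id == 20L, ]$stained_px, 0L)
  expect_equal(rc[rc$region_id == 20L, ]$n_objects, 0L)
})

test_that("objects straddling a boundary are split with one count per region", {
  h <- make_flat_hierarchy(c(10L, 20L))
  m <- atlas_map(cbind(matrix(10L, 10, 6), matrix(20L, 10, 4)))
  px <- matrix(FALSE, 10, 10)
  px[4, 2:11 - 1] <- TRUE  # 10-px horizontal object: 6 px in 10, 4 px in 20
  rc <- regional_counts(segmentation_image(px), m, h)
  expect_equal(rc[rc$region_id == 10L, ]$stained_px, 6L)
  expect_equal(rc[rc$region_id == 20L, ]$stained_px, 4L)
  expect_equal(rc[rc$region_id == 10L, ]$n_objects, 1L)
  expect_equal(rc[rc$region_id == 20L, ]$n_objects, 1L)
})

test_that("masked pixels are absent from numerator and denominator", {
  h <- make_flat_hierarchy(c(10L, 20L))
  m <- atlas_map(cbind(matrix(10L, 10, 10), matrix(20L, 10, 10)))
  px <- matrix(TRUE, 10, 20)
  mask <- cbind(matrix(TRUE, 10, 10), matrix(FALSE, 10, 10))
  rc <- regional_counts(segmentation_image(px), m, h, mask = mask)
  expect_false(20L %in% rc$region_id)
  expect_equal(rc[rc$region_id == 10L, ]$region_area_px, 100L)
  expect_equal(rc[rc$region_id == 10L, ]$load_pct, 100)
  expect_error(regional_counts(segmentation_image(px), m, h,
                               mask = matrix(TRUE, 2, 2)), "dimensions")
  expect_error(regional_counts(segmentation_image(matrix(FALSE, 3, 3)), m, h),
               "dimensions")
})

test_that("pixel-partition identities hold on random sections (UNMAPPED included)", {
  ids <- c(10L, 20L, 30L)
  ont <- build_ontology(data.frame(
    id = c(1L, ids), name = c("root", paste0("r", ids)),
    parent_id = c(NA, rep(1L, 3))))
  lab <- array(rep(ids, length.out = 27), dim = c(3, 3, 3))
  # select only two regions: label 30 becomes UNMAPPED
  suppressMessages(h <- collapse_to_custom(ont, c(10L, 20L),
                                           atlas_volume(lab)))
  set.seed(31)
  for (rep_i in 1:20) {
    mvals <- sample(c(0L, ids), 14 * 12, replace = TRUE)
    m <- atlas_map(matrix(mvals, 12, 14))
    px <- matrix(runif(12 * 14) < 0.4, 12, 14)
    mask <- matrix(runif(12 * 14) < 0.8, 12, 14)
    rc <- regional_counts(segmentation_image(px), m, h, mask = mask)
    counted <- mask & m$region_ids != 0L
    expect_identical(sum(rc$region_area_px), sum(counted))
    expect_identical(sum(rc$stained_px), sum(px & counted))
    expect_true(all(rc$load_pct >= 0 & rc$load_pct <= 100))
    if (any(m$region_ids[counted] == 30L)) {
      expect_true(-1L %in% rc$region_id)
    }
  }
})

test_that("brain pooling is pixel-weighted over kept sections", {
  one <- data.table::data.table(
    section_id = "s1", region_id = 10L, region_area_px = 100L,
    stained_px = 10L, n_objects = 2L, load_pct = 10)
  expect_equal(brain_load(one)$load_pct, 10)

  two <- rbind(one, data.table::data.table(
    section_id = "s2", region_id = 10L, region_area_px = 100L,
    stained_px = 30L, n_objects = 1L, load_pct = 30))
  expect_equal(brain_load(two)$load_pct, 20)  # equal areas: midpoint

  uneq <- rbind(one, data.table::data.table(
    section_id = "s2", region_id = 10L, region_area_px = 300L,
    stained_px = 90L, n_objects = 1L, load_pct = 30))
  # pixel-sum oracle: 100*(10+90)/(100+300)
  expect_equal(brain_load(uneq)$load_pct, 25)
  expect_equal(brain_load(uneq, method = "mean_of_sections")$load_pct, 20)

  # excluding a section whose load equals the pooled load changes nothing
  bal <- rbind(two, data.table::data.table(
    section_id = "s3", region_id = 10L, region_area_px = 50L,
    stained_px = 10L, n_objects = 1L, load_pct = 20))
  expect_equal(brain_load(bal)$load_pct,
               brain_load(bal, excluded_sections = "s3")$load_pct)

  # region present only in an excluded section: NA load, reported
  drop <- brain_load(two, excluded_sections = c("s1", "s2"))
  expect_true(is.na(drop$load_pct))
  expect_equal(drop$n_sections, 0L)
})

test_that("load differences are nonlinear minus linear with mean and SEM", {
  lin <- data.frame(brain_id = rep(c("b1", "b2", "b3"), each = 2),
                    region_id = rep(c(10L, 20L), 3),
                    load_pct = c(1, 2, 3, 4, 5, 6))
  non <- lin
  expect_equal(load_difference(lin, non)$mean_diff, c(0, 0))

  non2 <- lin; non2$load_pct <- lin$load_pct + 2.5
  d <- load_difference(lin, non2)
  expect_equal(d$mean_diff, c(2.5, 2.5))
  expect_equal(d$sem_diff, c(0, 0))
  expect_equal(d$n, c(3L, 3L))

  set.seed(5)
  non3 <- lin; non3$load_pct <- lin$load_pct + rnorm(6)
  d3 <- load_difference(lin, non3)
  for (r in c(10L, 20L)) {
    diffs <- non3$load_pct[non3$region_id == r] -
      lin$load_pct[lin$region_id == r]
    expect_equal(d3[d3$region_id == r, ]$mean_diff, mean(diffs))
  }
  expect_error(load_difference(lin, non2[-1, ]), "mismatched")
})

test_that("segmentation PNGs round-trip through 8-bit grayscale", {
  px <- matrix(runif(30) < 0.5, 5, 6)
  seg <- segmentation_image(px, stain = "GFAP")
  path <- withr::local_tempfile(fileext = ".png")
  write_segmentation_png(seg, path)
  back <- read_segmentation_png(path, stain = "GFAP")
  expect_identical(back$pixels, px)
})
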