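# Droplet segmentation, line profiles and co-condensation.

disk_image <- function(ny, nx, centers, radii, value = 100, background = 0) {
  img <- matrix(background, ny, nx)
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(ny) - centers[i, 1])^2,
                (seq_len(nx) - centers[i, 2])^2, "+")
    img[d2 <= radii[i]^2] <- value
  }
  img
}

test_that("disjoint generator droplets are recovered one to one", {
  fld <- make_droplet_field(droplet_field_spec(
    n_droplets = 20, radius_range_px = c(4, 6), min_separation_px = 30,
    image_shape = c(512, 512), noise_sd = 0, seed = 21))
  seg <- segment_droplets(fld$channel_a)
  expect_identical(nrow(seg$droplets), 20L)
  # each area close to pi r^2 (discretization aside)
  ord <- order(seg$droplets$centroid_y)
  tru <- fld$truth[order(fld$truth$center_y), ]
  expect_true(all(abs(seg$droplets$area_px[ord] - pi * tru$radius_px^2) <=
                    0.1 * pi * tru$radius_px^2))
  expect_true(all(abs(seg$droplets$centroid_y[ord] - tru$center_y) < 1))
})

test_that("blank images yield empty segmentations, not errors", {
  seg <- segment_droplets(matrix(5, 64, 64))
  expect_identical(nrow(seg$droplets), 0L)
  expect_true(all(seg$label_image == 0L))
})

test_that("labeling is 8-connected and merges touching disks", {
  merged <- disk_image(64, 64, rbind(c(30, 28), c(30, 36)), c(5, 5))
  seg <- segment_droplets(merged, threshold = 50)
  expect_identical(nrow(seg$droplets), 1L)

  diag_touch <- matrix(0, 16, 16)
  diag_touch[4, 4] <- 100; diag_touch[5, 5] <- 100
  seg2 <- segment_droplets(diag_touch, min_area_px = 1, threshold = 50)
  expect_identical(nrow(seg2$droplets), 1L)
  expect_identical(seg2$droplets$area_px, 2L)

  apart <- disk_image(64, 64, rbind(c(20, 20), c(44, 44)), c(5, 5))
  expect_identical(nrow(segment_droplets(apart, threshold = 50)$droplets), 2L)
})

test_that("per-droplet areas always add up to the labeled foreground", {
  for (seed in 1:5) {
    fld <- make_droplet_field(droplet_field_spec(seed = seed))
    seg <- segment_droplets(fld$channel_a)
    expect_identical(sum(seg$droplets$area_px),
                     sum(seg$label_image > 0L))
  }
})

test_that("Otsu segmentation is invariant to positive affine rescaling", {
  fld <- make_droplet_field(droplet_field_spec(seed = 31))
  a <- segment_droplets(fld$channel_a)
  b <- segment_droplets(2.5 * fld$channel_a + 40)
  expect_identical(a$label_image, b$label_image)
})

test_that("line profiles interpolate bilinearly", {
  flat <- line_profile(matrix(6, 32, 32), c(5, 5), c(28, 28), 50)
  expect_equal(flat$intensity, rep(6, 50))
  expect_identical(flat$position_px[1], 0)
  expect_true(all(diff(flat$position_px) > 0))

  ramp <- matrix(rep(1:32, each = 32), 32, 32)  # intensity = x
  prof <- line_profile(list(ch = ramp), c(16, 4), c(16, 28), 25)
  expect_equal(prof$ch, seq(4, 28, length.out = 25))

  fld <- make_droplet_field(droplet_field_spec(noise_sd = 0, seed = 41))
  inner <- fld$truth$center_x > 20 & fld$truth$center_x < 236
  tru <- fld$truth[which(inner)[1], ]
  p0 <- c(tru$center_y, tru$center_x - 15)
  p1 <- c(tru$center_y, tru$center_x + 15)
  prof <- line_profile(list(a = fld$channel_a), p0, p1, 301)
  half <- 10 + 150 / 2
  width <- diff(range(prof$position_px[prof$a > half]))
  expect_lt(abs(width - 2 * tru$radius_px), 2)

  expect_error(line_profile(matrix(0, 8, 8), c(0, 4), c(5, 5)), "outside")
})

test_that("co-condensation efficiency matches object overlap", {
  fld <- make_droplet_field(droplet_field_spec(
    n_droplets = 20, overlap_fraction = 0.6, min_separation_px = 30,
    image_shape = c(512, 512), noise_sd = 0, seed = 51))
  seg_a <- segment_droplets(fld$channel_a)
  seg_b <- segment_droplets(fld$channel_b)
  cc <- co_condensation_efficiency(seg_a, seg_b)
  expect_identical(cc$n_ref, 20L)
  expect_equal(cc$efficiency, mean(fld$truth$in_channel_b))

  expect_equal(co_condensation_efficiency(seg_a, seg_a)$efficiency, 1)
  blank <- segment_droplets(matrix(0, 512, 512))
  expect_equal(co_condensation_efficiency(seg_a, blank)$efficiency, 0)
  undef <- co_condensation_efficiency(blank, seg_a)
  expect_true(is.na(undef$efficiency))
  expect_identical(undef$flag, "no_reference_droplets")
})

test_that("efficiency is monotone non-increasing in the overlap threshold", {
  fld <- make_droplet_field(droplet_field_spec(overlap_fraction = 0.5,
                                               seed = 61))
  seg_a <- segment_droplets(fld$channel_a)
  seg_b <- segment_droplets(fld$channel_b)
  effs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9, 1), function(f) {
    co_condensation_efficiency(seg_a, seg_b, f)$efficiency
  }, numeric(1))
  expect_true(all(diff(effs) <= 0))
})

test_that("droplet-positive cell fractions count cells, not droplets", {
  pos <- segment_droplets(disk_image(64, 64, rbind(c(32, 32)), 5),
                          threshold = 50)
  neg <- segment_droplets(matrix(0, 64, 64))
  cells <- c(rep(list(pos), 6), rep(list(neg), 2))
  res <- droplet_formation_fraction(cells)
  expect_equal(res$fraction, 0.75)
  expect_identical(res$counts, rep(c(1L, 0L), c(6, 2)))
  expect_equal(droplet_formation_fraction(cells, min_droplets = 99)$fraction, 0)
  expect_equal(droplet_formation_fraction(list(neg, neg))$fraction, 0)
  expect_error(droplet_formation_fraction(list()), "no cells")
})

test_that("area summaries pool droplets by group", {
  img <- matrix(0, 64, 64)
  img[10:14, 10:19] <- 100   # 50 px
  img[30:39, 10:19] <- 100   # 100 px
  img[10:24, 40:49] <- 100   # 150 px
  seg3 <- segment_droplets(img, threshold = 50)
  expect_setequal(seg3$droplets$area_px, c(50L, 100L, 150L))
  one <- segment_droplets(disk_image(64, 64, rbind(c(20, 20)), 5),
                          threshold = 50)

  summ <- droplet_area_summary(list(seg3, one), c("wt", "mut"))
  expect_equal(summ$mean_area_px[summ$group == "wt"], 100)
  expect_equal(summ$median_area_px[summ$group == "wt"], 100)
  expect_identical(summ$n_droplets[summ$group == "mut"], 1L)

  with_empty <- droplet_area_summary(list(seg3), "wt",
                                     levels = c("wt", "empty"))
  expect_identical(with_empty$n_droplets[with_empty$group == "empty"], 0L)
  expect_true(is.na(with_empty$mean_area_px[with_empty$group == "empty"]))
  expect_error(droplet_area_summary(list(seg3), "mystery", levels = "wt"),
               "unknown group")
})
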