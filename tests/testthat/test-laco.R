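# Tethering enrichment pipeline: each stage against hand-computable cases
# and the brute-force loop oracles.

noise_free_scene <- function(amplitude_mch = 0, sigma = 3,
                             center = c(48, 48), background_mch = 20) {
  make_laco_scene(punctum_spec(center_yx = center, sigma_px = sigma,
                               amplitude_mch = amplitude_mch,
                               background_mch = background_mch,
                               noise_sd = 0))
}

test_that("brightest-slice selection follows the GFP maximum with low-index ties", {
  sc <- noise_free_scene()
  expect_identical(select_brightest_slice(sc), 5L)

  single <- laco_scene(matrix(runif(64), 8, 8), matrix(0, 8, 8))
  expect_identical(select_brightest_slice(single), 1L)

  flat <- laco_scene(array(7, dim = c(8, 8, 3)), array(0, dim = c(8, 8, 3)))
  expect_identical(select_brightest_slice(flat), 1L)

  dark <- laco_scene(array(0, dim = c(8, 8, 3)), array(0, dim = c(8, 8, 3)))
  expect_error(select_brightest_slice(dark), "no punctum signal")
})

test_that("center localization finds the punctum to the nearest pixel", {
  sc <- noise_free_scene(center = c(40, 60))
  expect_identical(locate_center(sc$gfp[, , 5]), c(y = 40L, x = 60L))

  sub <- make_laco_scene(punctum_spec(center_yx = c(40.4, 60),
                                      noise_sd = 0))
  expect_identical(locate_center(sub$gfp[, , 5]), c(y = 40L, x = 60L))

  expect_error(locate_center(matrix(3, 10, 10)), "no punctum signal")
})

test_that("radial profiles bin pixels by rounded distance", {
  uni <- radial_profile(matrix(4.5, 31, 31), c(16, 16), 10)
  expect_true(all(uni$mean_intensity == 4.5))
  expect_identical(uni$pixel_count[1L], 1L)
  expect_false(attr(uni, "truncated"))

  spot <- matrix(5, 7, 7); spot[4, 4] <- 100
  prof <- radial_profile(spot, c(4, 4), 3)
  expect_identical(prof$mean_intensity[1L], 100)
  expect_identical(prof$mean_intensity[2L], 5)
  expect_false(attr(prof, "truncated"))  # annulus 3 still fits in 7x7
  over <- radial_profile(spot, c(4, 4), 4)
  expect_true(attr(over, "truncated"))   # annulus 4 spills over the border

  sc <- noise_free_scene()
  gauss <- radial_profile(sc$gfp[, , 5], c(48, 48), 12)
  expect_true(all(diff(gauss$mean_intensity) <= 0))
})

test_that("vectorized radial profile equals per-pixel binning on random images", {
  set.seed(99)
  for (i in 1:100) {
    img <- matrix(stats::runif(64 * 64, 0, 1000), 64, 64)
    center <- c(sample(5:60, 1), sample(5:60, 1))
    fast <- radial_profile(img, center, 9)
    slow <- oracle_radial_profile(img, center, 9)
    expect_equal(fast$mean_intensity, slow$mean_intensity, tolerance = 0)
    expect_identical(fast$pixel_count, slow$pixel_count)
  }
})

test_that("the punctum radius is the first non-negative profile derivative", {
  expect_identical(
    punctum_radius(profile_from_values(c(100, 60, 30, 29, 31, 30)))$radius_px,
    3L)
  rising <- punctum_radius(profile_from_values(c(1, 2, 3, 4)))
  expect_identical(rising$radius_px, 1L)
  expect_false(rising$truncated)
  falling <- punctum_radius(profile_from_values(c(9, 7, 4, 2, 1)))
  expect_identical(falling$radius_px, 4L)
  expect_true(falling$truncated)
  expect_error(punctum_radius(profile_from_values(c(2, 1))), "3 annuli")
})

test_that("noise-free radius matches the oracle scan for several widths", {
  for (sigma in c(2, 3, 4)) {
    sc <- noise_free_scene(sigma = sigma)
    r_max <- as.integer(4 * sigma)
    prof <- radial_profile(sc$gfp[, , 5], c(48, 48), r_max)
    expect_identical(punctum_radius(prof)$radius_px,
                     oracle_radius_scan(prof$mean_intensity))
  }
})

test_that("the 5x5 box filter behaves like a local mean with reflect borders", {
  expect_equal(smooth_J5(matrix(3, 9, 9)), matrix(3, 9, 9))

  imp <- matrix(0, 11, 11); imp[6, 6] <- 25
  sm <- smooth_J5(imp)
  expect_true(all(sm[4:8, 4:8] == 1))
  expect_true(all(sm[-(4:8), ] == 0) && all(sm[, -(4:8)] == 0))

  ramp <- matrix(rep(1:12, each = 12), 12, 12)  # constant columns, x-ramp
  expect_equal(smooth_J5(ramp)[3:10, 3:10], ramp[3:10, 3:10])

  rnd <- matrix(stats::rnorm(100), 10, 10)
  expect_equal(smooth_J5(rnd), oracle_smooth_J5(rnd), tolerance = 1e-12)
  expect_equal(smooth_J5(rnd, normalize = FALSE),
               oracle_smooth_J5(rnd, normalize = FALSE), tolerance = 1e-12)
})

test_that("Ipeak averages the four neighbors of the smoothed peak", {
  expect_identical(peak_intensity(matrix(2.5, 20, 20), c(10, 10), 3), 2.5)

  sc <- noise_free_scene(amplitude_mch = 80)
  sm <- oracle_smooth_J5(sc$mch[, , 5])
  expected <- mean(c(sm[47, 48], sm[49, 48], sm[48, 47], sm[48, 49]))
  expect_equal(peak_intensity(smooth_J5(sc$mch[, , 5]), c(48, 48), 5),
               expected, tolerance = 1e-12)

  edge <- matrix(0, 20, 20); edge[1, 10] <- 50
  expect_error(peak_intensity(edge, c(2, 10), 2), "border")
})

test_that("Iperiphery averages the two annuli just outside the radius", {
  prof <- profile_from_values(c(50, 40, 30, 20, 12, 10, 9))
  expect_identical(periphery_intensity(prof, 3L), 11)  # mean(12, 10)
  expect_error(periphery_intensity(prof, 5L), "r_max")
})

test_that("null scenes give ratio exactly 1 and no interaction call", {
  m <- measure_enrichment(noise_free_scene(amplitude_mch = 0))
  expect_equal(m$ratio, 1, tolerance = 1e-9)
  expect_false(m$interacting)
  expect_identical(m$i_peak, m$i_periphery)
})

test_that("a zero-background partner channel is rejected, not divided by", {
  sc <- noise_free_scene(amplitude_mch = 0, background_mch = 0)
  expect_error(measure_enrichment(sc), "Iperiphery")
})

test_that("the full pipeline matches the loop oracle on enriched scenes", {
  for (seed in 1:3) {
    sc <- make_laco_scene(punctum_spec(amplitude_mch = 100,
                                       background_mch = 20,
                                       noise_sd = 2, seed = seed))
    m <- measure_enrichment(sc, r_max = 12)
    o <- oracle_enrichment(sc, r_max = 12)
    expect_identical(m$slice_index, o$slice_index)
    expect_identical(unname(m$center), o$center)
    expect_identical(m$radius_px, o$radius_px)
    expect_equal(m$ratio, o$ratio, tolerance = 1e-12)
  }
})

test_that("the enrichment ratio is scale-invariant and offsets pull it to 1", {
  sc <- noise_free_scene(amplitude_mch = 100)
  base <- measure_enrichment(sc)

  scaled <- sc
  scaled$mch <- sc$mch * 7.3
  expect_equal(measure_enrichment(scaled)$ratio, base$ratio,
               tolerance = 1e-12)

  prev <- base$ratio
  for (offset in c(50, 200, 1000)) {
    shifted <- sc
    shifted$gfp <- sc$gfp + offset
    shifted$mch <- sc$mch + offset
    r <- measure_enrichment(shifted)$ratio
    expect_gt(r, 1)
    expect_lt(r, prev)
    prev <- r
  }
})

test_that("the ratio does not depend on the box-filter normalization", {
  sc <- noise_free_scene(amplitude_mch = 60)
  m <- measure_enrichment(sc, r_max = 12)
  # manual pipeline with the unnormalized kernel
  center <- locate_center(sc$gfp[, , 5])
  r <- punctum_radius(radial_profile(sc$gfp[, , 5], center, 12))$radius_px
  sm <- smooth_J5(sc$mch[, , 5], normalize = FALSE)
  ratio_raw <- peak_intensity(sm, center, r) /
    periphery_intensity(radial_profile(sm, center, r + 2L), r)
  expect_equal(ratio_raw, m$ratio, tolerance = 1e-12)
})

test_that("interacting scenes at five times the noise are called positive", {
  hits <- vapply(1:20, function(seed) {
    sc <- make_laco_scene(punctum_spec(amplitude_mch = 10, noise_sd = 2,
                                       seed = 100 + seed))
    measure_enrichment(sc)$interacting
  }, logical(1))
  expect_true(all(hits))
})
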