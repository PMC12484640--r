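# LacO/LacI tethering enrichment statistic.
#
# Pipeline (single punctum per scene): pick the brightest GFP slice, locate
# the punctum center, estimate the punctum radius from the first
# non-negative step of the GFP radial-profile derivative, smooth the
# mCherry slice with the 5x5 all-ones kernel, then report
# ratio = Ipeak / Iperiphery, where Ipeak is the mean of the four
# edge-adjacent neighbors of the smoothed-mCherry peak inside the punctum
# disk and Iperiphery is the mean of the smoothed-mCherry radial profile at
# the two annuli immediately outside the radius. A ratio above 1 is called
# as recruitment (interaction).
#
# Conventions: coordinates are (y, x), 1-based, pixel centers at integers;
# all tie-breaks take the first candidate in row-major order (lowest y,
# then lowest x; lowest z for slices).

roi_or_whole <- function(roi, ny, nx) {
  if (is.null(roi)) c(1L, ny, 1L, nx) else as.integer(roi)
}

#' Select the brightest GFP slice of a tethering scene
#'
#' Returns the 1-based z index whose maximum GFP intensity inside the ROI
#' is largest; ties go to the lowest index.
#'
#' @param scene a [laco_scene()].
#' @return Integer slice index.
#' @export
select_brightest_slice <- function(scene) {
  stopifnot(inherits(scene, "laco_scene"))
  d <- dim(scene$gfp)
  roi <- roi_or_whole(scene$roi, d[1L], d[2L])
  peaks <- vapply(seq_len(d[3L]), function(z) {
    max(scene$gfp[roi[1L]:roi[2L], roi[3L]:roi[4L], z])
  }, numeric(1))
  if (max(peaks) <= 0) stopf("no punctum signal: GFP stack is all zero")
  which.max(peaks)  # which.max returns the first (lowest) index on ties
}

#' Locate the punctum center on a GFP slice
#'
#' The center is the pixel of maximum GFP intensity within the ROI after
#' 5x5 all-ones smoothing (the smoothing suppresses single-pixel noise).
#' Ties are broken in row-major order.
#'
#' @param gfp_slice numeric matrix (y, x).
#' @param roi optional `(y0, y1, x0, x1)` region, 1-based inclusive.
#' @return Integer `(y, x)` pixel.
#' @export
locate_center <- function(gfp_slice, roi = NULL) {
  stopifnot(is.matrix(gfp_slice))
  roi <- roi_or_whole(roi, nrow(gfp_slice), ncol(gfp_slice))
  sm <- smooth_J5(gfp_slice)
  sub <- sm[roi[1L]:roi[2L], roi[3L]:roi[4L], drop = FALSE]
  if (diff(range(sub)) == 0) {
    stopf("no punctum signal: ROI has zero dynamic range")
  }
  hit <- which(sub == max(sub), arr.ind = TRUE)
  # row-major tie-break: lowest y, then lowest x
  hit <- hit[order(hit[, 1L], hit[, 2L])[1L], ]
  c(y = unname(hit[1L]) + roi[1L] - 1L, x = unname(hit[2L]) + roi[3L] - 1L)
}

#' Radial intensity profile around a pixel
#'
#' Annulus `k` (k = 0..r_max) collects the pixels whose Euclidean distance
#' `d` from the center satisfies `round(d) = k`; annulus 0 is the center
#' pixel alone. Pixels outside the image are simply absent, and the profile
#' is flagged as truncated when `r_max` exceeds the distance to the nearest
#' border (some annuli then sample incomplete rings).
#'
#' @param slice numeric matrix (y, x).
#' @param center integer `(y, x)` pixel inside the image.
#' @param r_max largest annulus index (>= 2).
#' @return An object of class `radial_profile`: data frame with columns
#'   `radius`, `mean_intensity`, `pixel_count`, and attribute `truncated`.
#' @export
radial_profile <- function(slice, center, r_max) {
  stopifnot(is.matrix(slice))
  ny <- nrow(slice); nx <- ncol(slice)
  center <- as.numeric(center)
  if (center[1L] < 1 || center[1L] > ny || center[2L] < 1 || center[2L] > nx) {
    stopf("profile center (%g, %g) outside the image", center[1L], center[2L])
  }
  if (r_max < 2) stopf("'r_max' must be >= 2")
  r_max <- as.integer(r_max)
  k <- round(sqrt(outer((seq_len(ny) - center[1L])^2,
                        (seq_len(nx) - center[2L])^2, "+")))
  keep <- k <= r_max
  kk <- as.integer(k[keep])
  vv <- slice[keep]
  cnt <- tabulate(kk + 1L, nbins = r_max + 1L)
  sums <- numeric(r_max + 1L)
  agg <- rowsum(vv, kk)
  sums[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
  mean_int <- ifelse(cnt > 0, sums / cnt, NA_real_)
  truncated <- r_max > min(center[1L] - 1, ny - center[1L],
                           center[2L] - 1, nx - center[2L])
  out <- data.frame(radius = 0:r_max, mean_intensity = mean_int,
                    pixel_count = cnt)
  attr(out, "truncated") <- truncated
  class(out) <- c("radial_profile", "data.frame")
  out
}

#' Punctum radius from the radial-profile derivative
#'
#' Scanning outward from the center, the punctum edge is where the
#' intensity has stopped falling: the radius is the smallest `k >= 1` whose
#' forward difference `D[k] = mean[k+1] - mean[k]` is non-negative (the
#' derivative of intensity with respect to distance has first dropped to
#' zero). If the profile is still strictly decreasing at its end, the
#' radius is reported as `r_max` with `truncated = TRUE`.
#'
#' @param profile a [radial_profile()] of the GFP channel with at least 3
#'   annuli.
#' @return List with `radius_px` (integer) and `truncated` (logical).
#' @export
punctum_radius <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  m <- profile$mean_intensity
  m <- m[!is.na(m)]
  if (length(m) < 3L) stopf("radial profile has fewer than 3 annuli")
  d <- diff(m)              # d[i] = D[k = i - 1]
  hits <- which(d[-1L] >= 0)  # candidate k >= 1
  if (length(hits)) {
    list(radius_px = as.integer(hits[1L]), truncated = FALSE)
  } else {
    list(radius_px = length(m) - 1L, truncated = TRUE)
  }
}

#' Smooth a slice with the 5x5 all-ones kernel
#'
#' Box filter used to suppress single-pixel noise before reading peak
#' intensities: each output pixel is the (normalized) sum of its 5x5
#' neighborhood. Borders are handled by reflect padding (edge pixels
#' mirrored, edge included). The enrichment ratio is invariant to the
#' normalization constant; the default divides by 25 so smoothed values
#' remain on the input intensity scale.
#'
#' @param slice numeric matrix, at least 5x5.
#' @param normalize divide by 25 (default `TRUE`).
#' @return Smoothed matrix of the same shape.
#' @export
smooth_J5 <- function(slice, normalize = TRUE) {
  stopifnot(is.matrix(slice))
  ny <- nrow(slice); nx <- ncol(slice)
  if (ny < 5L || nx < 5L) stopf("slice must be at least 5x5")
  pad <- slice[c(2L, 1L, seq_len(ny), ny, ny - 1L),
               c(2L, 1L, seq_len(nx), nx, nx - 1L)]
  out <- matrix(0, ny, nx)
  for (dy in 0:4) {
    for (dx in 0:4) {
      out <- out + pad[dy + seq_len(ny), dx + seq_len(nx)]
    }
  }
  if (normalize) out / 25 else out
}

#' Peak intensity of the smoothed partner channel at the punctum
#'
#' Finds the maximum pixel of the smoothed mCherry slice within the punctum
#' disk (pixels whose rounded distance from the center is at most `r`,
#' i.e. annuli 0..r) and returns the mean of its four edge-adjacent
#' neighbors (up, down, left, right) in the smoothed slice.
#'
#' @param smoothed_mch smoothed mCherry matrix (see [smooth_J5()]).
#' @param center integer `(y, x)` punctum center.
#' @param r punctum radius in pixels (>= 1).
#' @return `Ipeak`, a single number.
#' @export
peak_intensity <- function(smoothed_mch, center, r) {
  stopifnot(is.matrix(smoothed_mch))
  if (r < 1) stopf("'r' must be >= 1")
  ny <- nrow(smoothed_mch); nx <- ncol(smoothed_mch)
  k <- round(sqrt(outer((seq_len(ny) - center[1L])^2,
                        (seq_len(nx) - center[2L])^2, "+")))
  inside <- which(k <= r, arr.ind = FALSE)
  vals <- smoothed_mch[inside]
  best <- inside[vals == max(vals)]
  # row-major tie-break on (y, x)
  by <- ((best - 1L) %% ny) + 1L
  bx <- ((best - 1L) %/% ny) + 1L
  o <- order(by, bx)[1L]
  py <- by[o]; px <- bx[o]
  if (py == 1L || py == ny || px == 1L || px == nx) {
    stopf("punctum too close to border: peak neighbor out of bounds")
  }
  mean(c(smoothed_mch[py - 1L, px], smoothed_mch[py + 1L, px],
         smoothed_mch[py, px - 1L], smoothed_mch[py, px + 1L]))
}

#' Periphery intensity just outside the punctum
#'
#' Mean of the two radial-profile values immediately outside the punctum
#' radius (annuli `r + 1` and `r + 2`) on the smoothed mCherry channel.
#'
#' @param mch_profile a [radial_profile()] of the smoothed mCherry slice.
#' @param r punctum radius in pixels.
#' @return `Iperiphery`, a single number.
#' @export
periphery_intensity <- function(mch_profile, r) {
  stopifnot(inherits(mch_profile, "radial_profile"))
  need <- r + 2L
  if (max(mch_profile$radius) < need ||
      any(is.na(mch_profile$mean_intensity[mch_profile$radius %in%
                                           (r + 1L):(r + 2L)]))) {
    stopf("radial profile too short for periphery at r = %d; recompute with r_max >= %d",
          r, need)
  }
  m <- mch_profile$mean_intensity[match((r + 1L):(r + 2L),
                                        mch_profile$radius)]
  mean(m)
}

#' Measure mCherry enrichment at a LacO-array punctum
#'
#' Runs the full two-channel enrichment pipeline on a scene: brightest GFP
#' slice, punctum center (argmax of the 5x5-smoothed GFP inside the ROI),
#' punctum radius from the GFP radial-profile derivative, 5x5 smoothing of
#' the mCherry slice, then `Ipeak` (mean of the four neighbors of the
#' smoothed-mCherry peak within the punctum disk) over `Iperiphery` (mean
#' of the two smoothed-mCherry profile values just outside the radius).
#' A ratio exceeding 1 is reported as a (potential) interaction.
#'
#' @param scene a [laco_scene()].
#' @param r_max largest annulus of the GFP radial profile used for the
#'   radius estimate; choose it to cover the expected punctum extent
#'   (about four times the punctum Gaussian width works well).
#' @return An object of class `punctum_measurement`: list with
#'   `slice_index`, `center` (y, x), `radius_px`, `radius_truncated`,
#'   `i_peak`, `i_periphery`, `ratio`, `interacting`.
#' @export
measure_enrichment <- function(scene, r_max = 12L) {
  stopifnot(inherits(scene, "laco_scene"))
  n <- with_stage("slice selection", select_brightest_slice(scene))
  gfp_slice <- scene$gfp[, , n]
  mch_slice <- scene$mch[, , n]
  center <- with_stage("center localization", locate_center(gfp_slice, scene$roi))
  gfp_prof <- with_stage("GFP radial profile",
                         radial_profile(gfp_slice, center, r_max))
  rad <- with_stage("radius estimation", punctum_radius(gfp_prof))
  sm <- with_stage("mCherry smoothing", smooth_J5(mch_slice))
  i_peak <- with_stage("peak intensity",
                       peak_intensity(sm, center, rad$radius_px))
  mch_prof <- with_stage("mCherry radial profile",
                         radial_profile(sm, center, rad$radius_px + 2L))
  i_periphery <- with_stage("periphery intensity",
                            periphery_intensity(mch_prof, rad$radius_px))
  if (i_periphery <= 0) {
    stopf("enrichment ratio undefined: Iperiphery = %g (zero background?)",
          i_periphery)
  }
  ratio <- i_peak / i_periphery
  structure(
    list(slice_index = n, center = center, radius_px = rad$radius_px,
         radius_truncated = rad$truncated, i_peak = i_peak,
         i_periphery = i_periphery, ratio = ratio,
         interacting = ratio > 1),
    class = "punctum_measurement"
  )
}

#' @export
print.punctum_measurement <- function(x, ...) {
  cat(sprintf(
    paste0("Punctum measurement: slice %d, center (%d, %d), radius %d px%s\n",
           "  Ipeak = %.4f, Iperiphery = %.4f, ratio = %.4f -> %s\n"),
    x$slice_index, x$center[1L], x$center[2L], x$radius_px,
    if (x$radius_truncated) " (truncated)" else "",
    x$i_peak, x$i_periphery, x$ratio,
    if (x$interacting) "interacting (ratio > 1)" else "not interacting"))
  invisible(x)
}

#' Measure a batch of scenes into a results table
#'
#' @param scenes list of [laco_scene()] objects.
#' @param r_max passed to [measure_enrichment()].
#' @param scene_ids optional character ids (defaults to `scene_001` ...).
#' @return Data frame with one row per scene (id, slice, center, radius,
#'   Ipeak, Iperiphery, ratio, interacting, flags).
#' @export
measure_enrichment_batch <- function(scenes, r_max = 12L, scene_ids = NULL) {
  if (!length(scenes)) stopf("no scenes supplied")
  ids <- scene_ids %||% sprintf("scene_%03d", seq_along(scenes))
  rows <- lapply(seq_along(scenes), function(i) {
    m <- measure_enrichment(scenes[[i]], r_max = r_max)
    data.frame(scene_id = ids[[i]], slice_index = m$slice_index,
               center_y = m$center[1L], center_x = m$center[2L],
               radius_px = m$radius_px, i_peak = m$i_peak,
               i_periphery = m$i_periphery, ratio = m$ratio,
               interacting = m$interacting,
               flags = if (m$radius_truncated) "radius_truncated" else "")
  })
  do.call(rbind, rows)
}
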