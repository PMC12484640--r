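# Droplet segmentation and co-condensation readouts for in vitro and
# cellular condensate images.

# 8-connected labeling: EBImage::bwlabel is 4-connected, so components that
# touch only diagonally are merged afterwards with a union-find pass.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  ny <- nrow(lab); nx <- ncol(lab)
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    dy <- shift[1L]; dx <- shift[2L]
    ys <- seq_len(ny - 1L)
    xs <- if (dx > 0) seq_len(nx - 1L) else 2L:nx
    a <- lab[ys, xs]
    b <- lab[ys + dy, xs + dx]
    touch <- which(a > 0L & b > 0L & a != b)
    for (i in touch) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

relabel_consecutive <- function(lab, keep) {
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Segment droplets in a 2-D image
#'
#' Thresholds the image (global Otsu by default, after rescaling intensities
#' to `[0, 1]`, which makes the segmentation invariant to positive affine
#' intensity changes; or a fixed intensity value), labels 8-connected
#' foreground components and removes components smaller than `min_area_px`.
#'
#' @param image numeric matrix (y, x) of non-negative intensities.
#' @param min_area_px minimum component area kept, in pixels (>= 1).
#' @param threshold `"otsu"` (default) or a fixed numeric intensity
#'   threshold on the original scale; pixels strictly above it are
#'   foreground.
#' @param extra_channels optional named list of same-shape matrices whose
#'   per-droplet mean intensities are reported alongside the segmented
#'   channel.
#' @return An object of class `droplet_segmentation`: list with
#'   `label_image` (integer matrix, 0 = background, labels consecutive from
#'   1) and `droplets`, a data frame with one row per droplet (id, area_px,
#'   centroid_y, centroid_x, equivalent_diameter_px, mean_intensity, and
#'   one `mean_<name>` column per extra channel).
#' @export
segment_droplets <- function(image, min_area_px = 5L, threshold = "otsu",
                             extra_channels = NULL) {
  stopifnot(is.matrix(image))
  if (min_area_px < 1) stopf("'min_area_px' must be >= 1")
  rng <- range(image)
  if (identical(threshold, "otsu")) {
    if (diff(rng) == 0) {
      mask <- matrix(FALSE, nrow(image), ncol(image))
      thr_used <- NA_real_
    } else {
      scaled <- (image - rng[1L]) / diff(rng)
      t01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1),
                           levels = 256L)
      thr_used <- rng[1L] + t01 * diff(rng)
      mask <- scaled > t01
    }
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    thr_used <- threshold
    mask <- image > threshold
  } else {
    stopf("'threshold' must be \"otsu\" or a single number")
  }
  empty <- function() {
    data.frame(id = integer(0), area_px = integer(0),
               centroid_y = numeric(0), centroid_x = numeric(0),
               equivalent_diameter_px = numeric(0),
               mean_intensity = numeric(0))
  }
  if (!any(mask)) {
    return(structure(list(label_image = matrix(0L, nrow(image), ncol(image)),
                          droplets = empty(), threshold = thr_used),
                     class = "droplet_segmentation"))
  }
  lab <- label_components_8(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area_px)
  lab <- relabel_consecutive(lab, keep)
  if (!length(keep)) {
    return(structure(list(label_image = lab, droplets = empty(),
                          threshold = thr_used),
                     class = "droplet_segmentation"))
  }
  idx <- which(lab > 0L)
  ids <- lab[idx]
  ys <- ((idx - 1L) %% nrow(lab)) + 1L
  xs <- ((idx - 1L) %/% nrow(lab)) + 1L
  area <- tabulate(ids)
  droplets <- data.frame(
    id = seq_along(area),
    area_px = area,
    centroid_y = as.vector(rowsum(as.numeric(ys), ids)) / area,
    centroid_x = as.vector(rowsum(as.numeric(xs), ids)) / area,
    equivalent_diameter_px = 2 * sqrt(area / pi),
    mean_intensity = as.vector(rowsum(image[idx], ids)) / area
  )
  for (nm in names(extra_channels)) {
    ch <- extra_channels[[nm]]
    if (!identical(dim(ch), dim(image))) {
      stopf("extra channel '%s' shape differs from the segmented image", nm)
    }
    droplets[[paste0("mean_", nm)]] <-
      as.vector(rowsum(ch[idx], ids)) / area
  }
  structure(list(label_image = lab, droplets = droplets,
                 threshold = thr_used),
            class = "droplet_segmentation")
}

#' Fraction of cells scored droplet-positive
#'
#' A cell is droplet-positive when its segmentation contains at least
#' `min_droplets` droplets. Returns the positive fraction together with the
#' per-cell droplet counts so either per-cell or per-population readings
#' can be reproduced.
#'
#' @param segmentations list of [segment_droplets()] results, one per cell.
#' @param min_droplets positivity threshold (default 1).
#' @return List with `fraction`, `n_cells` and `counts`.
#' @export
droplet_formation_fraction <- function(segmentations, min_droplets = 1L) {
  if (!length(segmentations)) stopf("no cells supplied")
  counts <- vapply(segmentations, function(s) {
    stopifnot(inherits(s, "droplet_segmentation"))
    nrow(s$droplets)
  }, integer(1))
  list(fraction = mean(counts >= min_droplets),
       n_cells = length(counts), counts = counts)
}

bilinear_at <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- pmin(pmax(floor(y), 1L), ny - 1L)
  x0 <- pmin(pmax(floor(x), 1L), nx - 1L)
  fy <- y - y0; fx <- x - x0
  img[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    img[cbind(y0 + 1L, x0)] * fy * (1 - fx) +
    img[cbind(y0, x0 + 1L)] * (1 - fy) * fx +
    img[cbind(y0 + 1L, x0 + 1L)] * fy * fx
}

#' Intensity line profile across one or more channels
#'
#' Samples each channel by bilinear interpolation at `n_samples` evenly
#' spaced points along the segment from `p0` to `p1` (both `(y, x)`,
#' 1-based, inside the image).
#'
#' @param channels named list of numeric matrices, all the same shape.
#' @param p0,p1 segment endpoints `(y, x)`.
#' @param n_samples number of samples (>= 2).
#' @return Data frame with `position_px` (distance along the segment,
#'   starting at 0) and one intensity column per channel.
#' @export
line_profile <- function(channels, p0, p1, n_samples = 100L) {
  if (!length(channels)) stopf("no channels supplied")
  if (is.matrix(channels)) channels <- list(intensity = channels)
  d <- dim(channels[[1L]])
  for (ch in channels) {
    if (!identical(dim(ch), d)) stopf("channel shapes differ")
  }
  if (n_samples < 2L) stopf("'n_samples' must be >= 2")
  for (p in list(p0, p1)) {
    if (p[1L] < 1 || p[1L] > d[1L] || p[2L] < 1 || p[2L] > d[2L]) {
      stopf("endpoint (%g, %g) outside the %d x %d image",
            p[1L], p[2L], d[1L], d[2L])
    }
  }
  t <- seq(0, 1, length.out = n_samples)
  ys <- p0[1L] + t * (p1[1L] - p0[1L])
  xs <- p0[2L] + t * (p1[2L] - p0[2L])
  out <- data.frame(position_px = t * sqrt(sum((p1 - p0)^2)))
  for (nm in names(channels)) out[[nm]] <- bilinear_at(channels[[nm]], ys, xs)
  out
}

#' Object-based co-condensation efficiency
#'
#' A reference droplet is colocalized when the fraction of its area that
#' overlaps partner-channel foreground is at least `min_overlap_fraction`.
#' Efficiency is the colocalized fraction of reference droplets. A
#' pixel-based Manders-style overlap fraction (reference foreground pixels
#' that are also partner foreground) is reported alongside as a secondary
#' readout.
#'
#' @param seg_ref,seg_partner [segment_droplets()] results on the same
#'   image grid.
#' @param min_overlap_fraction area-overlap threshold in `[0, 1]`
#'   (default 0.5).
#' @return An object of class `co_condensation`: list with `n_ref`,
#'   `n_coloc`, `efficiency` (`NA` with `flag = "no_reference_droplets"`
#'   when the reference segmentation is empty), `pixel_overlap_fraction`,
#'   `min_overlap_fraction` and `per_droplet` overlap fractions.
#' @export
co_condensation_efficiency <- function(seg_ref, seg_partner,
                                       min_overlap_fraction = 0.5) {
  stopifnot(inherits(seg_ref, "droplet_segmentation"),
            inherits(seg_partner, "droplet_segmentation"))
  if (!identical(dim(seg_ref$label_image), dim(seg_partner$label_image))) {
    stopf("segmentations are on different image grids")
  }
  assert_scalar_num(min_overlap_fraction, "min_overlap_fraction",
                    lower = 0, upper = 1)
  n_ref <- nrow(seg_ref$droplets)
  ref_fg <- seg_ref$label_image > 0L
  par_fg <- seg_partner$label_image > 0L
  if (n_ref == 0L) {
    return(structure(list(n_ref = 0L, n_coloc = 0L, efficiency = NA_real_,
                          pixel_overlap_fraction = NA_real_,
                          min_overlap_fraction = min_overlap_fraction,
                          per_droplet = numeric(0),
                          flag = "no_reference_droplets"),
                     class = "co_condensation"))
  }
  ids <- seg_ref$label_image[ref_fg]
  overlap <- as.vector(rowsum(as.numeric(par_fg[ref_fg]), ids))
  frac <- overlap / seg_ref$droplets$area_px
  n_coloc <- sum(frac >= min_overlap_fraction)
  structure(list(n_ref = n_ref, n_coloc = n_coloc,
                 efficiency = n_coloc / n_ref,
                 pixel_overlap_fraction = sum(par_fg & ref_fg) / sum(ref_fg),
                 min_overlap_fraction = min_overlap_fraction,
                 per_droplet = frac, flag = ""),
            class = "co_condensation")
}

#' Per-group droplet area summary
#'
#' Pools droplet areas across the segmentations of each group and returns
#' long-format descriptive statistics.
#'
#' @param segmentations list of [segment_droplets()] results.
#' @param groups character/factor vector, one group label per segmentation.
#' @param levels optional expected group labels; an error is raised if
#'   `groups` contains a label not in `levels`.
#' @return Data frame with columns `group`, `n_droplets`, `mean_area_px`,
#'   `median_area_px` (statistics are `NA` for empty groups).
#' @export
droplet_area_summary <- function(segmentations, groups, levels = NULL) {
  if (length(segmentations) != length(groups)) {
    stopf("'groups' must label each segmentation")
  }
  groups <- as.character(groups)
  if (is.null(levels)) {
    levels <- unique(groups)
  } else if (length(bad <- setdiff(groups, levels))) {
    stopf("unknown group label: %s", bad[1L])
  }
  rows <- lapply(levels, function(g) {
    areas <- unlist(lapply(segmentations[groups == g],
                           function(s) s$droplets$area_px))
    data.frame(group = g, n_droplets = length(areas),
               mean_area_px = if (length(areas)) mean(areas) else NA_real_,
               median_area_px = if (length(areas)) {
                 stats::median(areas)
               } else {
                 NA_real_
               })
  })
  do.call(rbind, rows)
}
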