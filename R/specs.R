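#' Specification of a synthetic LacO-tethering scene
#'
#' Describes a two-channel z-stack of a nucleus bearing a single bright
#' tethering punctum: a radially symmetric Gaussian spot on a uniform
#' background in each channel, with Gaussian attenuation across z-slices and
#' additive Gaussian noise. The GFP channel carries the tethered (bait)
#' protein; the mCherry channel carries the candidate partner, whose
#' amplitude at the punctum is zero when the two proteins do not interact.
#'
#' Defaults emulate a bright transfected punctum imaged by spinning-disk
#' confocal: amplitude 100 counts over a background of 20 with additive
#' noise of 2 counts (2\% of the spot amplitude).
#'
#' @param image_shape integer vector `(n_z, n_y, n_x)`.
#' @param center_yx punctum center `(y, x)` in pixels (may be fractional;
#'   1-based, pixel centers at integers).
#' @param z_index 1-based slice carrying the punctum at full amplitude.
#' @param sigma_px Gaussian width of the punctum in pixels (> 0).
#' @param amplitude_gfp,amplitude_mch peak intensity above background per
#'   channel (arbitrary units, >= 0). `amplitude_mch = 0` encodes a
#'   non-interacting partner.
#' @param background_gfp,background_mch uniform background level per channel.
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param margin_px optional minimum distance from the punctum center to any
#'   image border; generation fails if violated. Use `5 * sigma_px` to
#'   guarantee the punctum lies fully inside the image.
#' @param seed integer seed; generation is bit-reproducible.
#' @return An object of class `punctum_spec`.
#' @export
punctum_spec <- function(image_shape = c(9L, 96L, 96L),
                         center_yx = c(48, 48),
                         z_index = 5L,
                         sigma_px = 3,
                         amplitude_gfp = 100,
                         amplitude_mch = 0,
                         background_gfp = 20,
                         background_mch = 20,
                         noise_sd = 2,
                         margin_px = NULL,
                         seed = 1L) {
  if (length(image_shape) != 3L || any(image_shape < 1)) {
    stopf("'image_shape' must be (n_z, n_y, n_x), all >= 1")
  }
  image_shape <- as.integer(image_shape)
  if (length(center_yx) != 2L || !all(is.finite(center_yx))) {
    stopf("'center_yx' must be finite (y, x)")
  }
  assert_scalar_num(sigma_px, "sigma_px", lower = 0, strict_lower = TRUE)
  assert_scalar_num(amplitude_gfp, "amplitude_gfp", lower = 0)
  assert_scalar_num(amplitude_mch, "amplitude_mch", lower = 0)
  assert_scalar_num(background_gfp, "background_gfp", lower = 0)
  assert_scalar_num(background_mch, "background_mch", lower = 0)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  z_index <- as.integer(z_index)
  if (z_index < 1L || z_index > image_shape[1L]) {
    stopf("'z_index' outside the stack (1..%d)", image_shape[1L])
  }
  ny <- image_shape[2L]; nx <- image_shape[3L]
  if (center_yx[1L] < 1 || center_yx[1L] > ny ||
      center_yx[2L] < 1 || center_yx[2L] > nx) {
    stopf("punctum center (%.1f, %.1f) outside the %d x %d image",
          center_yx[1L], center_yx[2L], ny, nx)
  }
  if (!is.null(margin_px)) {
    assert_scalar_num(margin_px, "margin_px", lower = 0)
    d_border <- min(center_yx[1L] - 1, ny - center_yx[1L],
                    center_yx[2L] - 1, nx - center_yx[2L])
    if (d_border < margin_px) {
      stopf("punctum violates the requested margin: center is %.1f px from the nearest border, margin_px = %.1f",
            d_border, margin_px)
    }
  }
  structure(
    list(image_shape = image_shape, center_yx = as.numeric(center_yx),
         z_index = z_index, sigma_px = sigma_px,
         amplitude_gfp = amplitude_gfp, amplitude_mch = amplitude_mch,
         background_gfp = background_gfp, background_mch = background_mch,
         noise_sd = noise_sd, margin_px = margin_px,
         seed = as.integer(seed)),
    class = "punctum_spec"
  )
}

#' Specification of a synthetic droplet field
#'
#' Describes a two-channel 2-D image of disk-shaped liquid droplets on a
#' uniform background. Droplet centers are placed by rejection sampling with
#' a minimum center-to-center separation; a chosen fraction of the
#' channel-A droplets is also painted in channel B (co-condensation).
#'
#' @param n_droplets number of droplets (>= 0).
#' @param radius_range_px `(min, max)` droplet radius in pixels.
#' @param intensity_per_channel length-2 vector: droplet intensity above
#'   background in channels A and B.
#' @param background length-2 vector of per-channel background levels.
#' @param overlap_fraction fraction of A-droplets that also carry channel-B
#'   signal, in `[0, 1]`.
#' @param min_separation_px minimum center-to-center distance between
#'   droplets; `>= 2 * max(radius) + 2` guarantees disjoint, non-touching
#'   droplets.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param image_shape `(n_y, n_x)` in pixels.
#' @param max_attempts_per_droplet rejection-sampling cap before placement
#'   is declared infeasible.
#' @param seed integer seed.
#' @return An object of class `droplet_field_spec`.
#' @export
droplet_field_spec <- function(n_droplets = 12L,
                               radius_range_px = c(4, 6),
                               intensity_per_channel = c(150, 150),
                               background = c(10, 10),
                               overlap_fraction = 0.5,
                               min_separation_px = 30,
                               noise_sd = 2,
                               image_shape = c(256L, 256L),
                               max_attempts_per_droplet = 500L,
                               seed = 1L) {
  if (length(image_shape) != 2L || any(image_shape < 1)) {
    stopf("'image_shape' must be (n_y, n_x), all >= 1")
  }
  if (length(radius_range_px) != 2L || radius_range_px[1L] <= 0 ||
      radius_range_px[2L] < radius_range_px[1L]) {
    stopf("'radius_range_px' must be (min, max) with 0 < min <= max")
  }
  if (length(intensity_per_channel) != 2L || any(intensity_per_channel < 0)) {
    stopf("'intensity_per_channel' must be two non-negative intensities")
  }
  if (length(background) != 2L || any(background < 0)) {
    stopf("'background' must be two non-negative levels")
  }
  assert_scalar_num(overlap_fraction, "overlap_fraction", lower = 0, upper = 1)
  assert_scalar_num(min_separation_px, "min_separation_px", lower = 0)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  if (n_droplets < 0) stopf("'n_droplets' must be >= 0")
  structure(
    list(n_droplets = as.integer(n_droplets),
         radius_range_px = as.numeric(radius_range_px),
         intensity_per_channel = as.numeric(intensity_per_channel),
         background = as.numeric(background),
         overlap_fraction = overlap_fraction,
         min_separation_px = min_separation_px,
         noise_sd = noise_sd,
         image_shape = as.integer(image_shape),
         max_attempts_per_droplet = as.integer(max_attempts_per_droplet),
         seed = as.integer(seed)),
    class = "droplet_field_spec"
  )
}

#' Specification of a synthetic FRAP trace
#'
#' Describes a fluorescence-recovery-after-photobleaching time series with a
#' single-exponential recovery model. Pre-bleach frames sit at `I0`; the
#' bleach removes `bleach_depth * I0`, after which intensity recovers as
#' `Ib + (I0 - Ib) * M * (1 - exp(-k * t))` with `Ib = I0 * (1 -
#' bleach_depth)`, mobile fraction `M` and rate `k` (per second). A constant
#' background column is carried alongside, mirroring how background ROIs are
#' recorded in practice.
#'
#' @param I0 pre-bleach intensity (background-free, arbitrary units).
#' @param bleach_depth fraction of `I0` removed at the bleach, in `(0, 1]`.
#' @param mobile_fraction recovered fraction `M` in `[0, 1]`.
#' @param rate_k recovery rate per second (> 0).
#' @param background_level constant background ROI intensity.
#' @param n_pre,n_post number of pre- and post-bleach frames.
#' @param dt frame interval in seconds.
#' @param noise_sd additive Gaussian noise on the intensity column.
#' @param seed integer seed.
#' @return An object of class `frap_spec`.
#' @export
frap_spec <- function(I0 = 100,
                      bleach_depth = 0.8,
                      mobile_fraction = 0.6,
                      rate_k = 0.1,
                      background_level = 10,
                      n_pre = 5L,
                      n_post = 60L,
                      dt = 1,
                      noise_sd = 0,
                      seed = 1L) {
  assert_scalar_num(I0, "I0", lower = 0, strict_lower = TRUE)
  assert_scalar_num(bleach_depth, "bleach_depth", lower = 0, upper = 1,
                    strict_lower = TRUE)
  assert_scalar_num(mobile_fraction, "mobile_fraction", lower = 0, upper = 1)
  assert_scalar_num(rate_k, "rate_k", lower = 0, strict_lower = TRUE)
  assert_scalar_num(background_level, "background_level", lower = 0)
  assert_scalar_num(dt, "dt", lower = 0, strict_lower = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  if (n_pre < 1L) stopf("'n_pre' must be >= 1 (need a pre-bleach baseline)")
  if (n_post < 1L) stopf("'n_post' must be >= 1")
  structure(
    list(I0 = I0, bleach_depth = bleach_depth,
         mobile_fraction = mobile_fraction, rate_k = rate_k,
         background_level = background_level,
         n_pre = as.integer(n_pre), n_post = as.integer(n_post),
         dt = dt, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "frap_spec"
  )
}

#' Specification of a synthetic pooled CRISPR screen
#'
#' Describes a dropout screen across one or more cell lines: an sgRNA
#' library with `sgrnas_per_gene` guides per gene, sequenced at `T0` and at
#' a late timepoint. Counts are negative-binomial around the expected guide
#' abundance (variance `mu + dispersion * mu^2`); at the late timepoint the
#' expected abundance of each line's essential genes is multiplied by
#' `2^depletion_log2fc` and all abundances are rescaled to the library size,
#' emulating fixed sequencing depth.
#'
#' By default each cell line receives its own disjoint block of
#' `n_essential` essential genes (gene ids `gene_0001` onward, in line
#' order), so line-specific dropout is recoverable by construction; pass
#' `essential_sets` to override (e.g. to create shared essentials).
#'
#' @param n_genes number of genes in the library.
#' @param sgrnas_per_gene guides per gene.
#' @param n_essential depleted genes per cell line (used when
#'   `essential_sets` is `NULL`).
#' @param depletion_log2fc true mean log2 effect of essential genes at the
#'   late timepoint (negative for dropout).
#' @param library_size_per_sample expected total reads per sample.
#' @param dispersion negative-binomial overdispersion (>= 0; 0 is Poisson).
#' @param cell_lines character vector of cell-line labels.
#' @param essential_sets optional named list (one element per cell line) of
#'   essential gene ids.
#' @param seed integer seed.
#' @return An object of class `screen_spec`.
#' @export
screen_spec <- function(n_genes = 500L,
                        sgrnas_per_gene = 4L,
                        n_essential = 25L,
                        depletion_log2fc = -3,
                        library_size_per_sample = 1e6,
                        dispersion = 0.1,
                        cell_lines = c("line_A", "line_B"),
                        essential_sets = NULL,
                        seed = 1L) {
  if (n_genes < 1L) stopf("'n_genes' must be >= 1")
  if (sgrnas_per_gene < 1L) stopf("'sgrnas_per_gene' must be >= 1")
  if (n_essential < 0L || n_essential > n_genes) {
    stopf("'n_essential' must be in 0..n_genes")
  }
  assert_scalar_num(depletion_log2fc, "depletion_log2fc")
  assert_scalar_num(library_size_per_sample, "library_size_per_sample",
                    lower = 0, strict_lower = TRUE)
  assert_scalar_num(dispersion, "dispersion", lower = 0)
  if (length(cell_lines) < 1L || anyDuplicated(cell_lines)) {
    stopf("'cell_lines' must be distinct labels")
  }
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  if (is.null(essential_sets)) {
    if (n_essential * length(cell_lines) > n_genes) {
      stopf("default disjoint essential sets need n_essential * n_lines <= n_genes")
    }
    essential_sets <- lapply(seq_along(cell_lines) - 1L, function(i) {
      genes[seq_len(n_essential) + i * n_essential]
    })
    names(essential_sets) <- cell_lines
  } else {
    if (!setequal(names(essential_sets), cell_lines)) {
      stopf("'essential_sets' must be named by cell line")
    }
    bad <- setdiff(unlist(essential_sets), genes)
    if (length(bad)) stopf("unknown gene in essential_sets: %s", bad[1L])
    essential_sets <- essential_sets[cell_lines]
  }
  structure(
    list(n_genes = as.integer(n_genes),
         sgrnas_per_gene = as.integer(sgrnas_per_gene),
         n_essential = as.integer(n_essential),
         depletion_log2fc = depletion_log2fc,
         library_size_per_sample = library_size_per_sample,
         dispersion = dispersion,
         cell_lines = as.character(cell_lines),
         genes = genes,
         essential_sets = essential_sets,
         seed = as.integer(seed)),
    class = "screen_spec"
  )
}
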