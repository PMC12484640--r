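# Synthetic-data generators. Every generator is deterministic given the
# spec's seed and restores the caller's RNG state on exit. Noise-free
# outputs are exactly their analytic model; noise is added after model
# evaluation and intensities are clipped at 0.

# Analytic punctum slice: background + amp * exp(-d^2 / (2 sigma^2)) with d
# the Euclidean distance of each pixel center from `center_yx`.
gaussian_slice <- function(ny, nx, center_yx, sigma_px, amplitude, background) {
  dy2 <- ((seq_len(ny)) - center_yx[1L])^2
  dx2 <- ((seq_len(nx)) - center_yx[2L])^2
  background + amplitude * exp(-outer(dy2, dx2, "+") / (2 * sigma_px^2))
}

#' Generate a synthetic two-channel LacO-tethering scene
#'
#' Builds GFP and mCherry z-stacks containing one Gaussian punctum on a
#' uniform background. The punctum amplitude is attenuated on neighboring
#' slices by a Gaussian falloff in z with `sigma_z = sigma_px`, so the
#' brightest slice is well defined but slice selection is non-trivial.
#' Seeded Gaussian noise is added to every voxel (GFP stack first, then
#' mCherry) and intensities are clipped at zero.
#'
#' @param spec a [punctum_spec()].
#' @return An object of class `laco_scene`: list with `gfp` and `mch`
#'   arrays of dim `(n_y, n_x, n_z)` (z is the third margin), `roi = NULL`
#'   (whole image), and a `truth` list recording the generating parameters.
#' @export
make_laco_scene <- function(spec) {
  stopifnot(inherits(spec, "punctum_spec"))
  nz <- spec$image_shape[1L]; ny <- spec$image_shape[2L]
  nx <- spec$image_shape[3L]
  z_fall <- exp(-((seq_len(nz) - spec$z_index)^2) / (2 * spec$sigma_px^2))
  build <- function(amplitude, background) {
    stack <- array(0, dim = c(ny, nx, nz))
    for (z in seq_len(nz)) {
      stack[, , z] <- gaussian_slice(ny, nx, spec$center_yx, spec$sigma_px,
                                     amplitude * z_fall[z], background)
    }
    stack
  }
  gfp <- build(spec$amplitude_gfp, spec$background_gfp)
  mch <- build(spec$amplitude_mch, spec$background_mch)
  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      gfp <- gfp + array(stats::rnorm(length(gfp), 0, spec$noise_sd), dim(gfp))
      mch <- mch + array(stats::rnorm(length(mch), 0, spec$noise_sd), dim(mch))
    })
    gfp[gfp < 0] <- 0
    mch[mch < 0] <- 0
  }
  structure(
    list(gfp = gfp, mch = mch, roi = NULL,
         truth = list(center_yx = spec$center_yx, z_index = spec$z_index,
                      sigma_px = spec$sigma_px,
                      amplitude_gfp = spec$amplitude_gfp,
                      amplitude_mch = spec$amplitude_mch,
                      background_gfp = spec$background_gfp,
                      background_mch = spec$background_mch,
                      interacting = spec$amplitude_mch > 0,
                      seed = spec$seed)),
    class = "laco_scene"
  )
}

#' Assemble a LacO scene from two image stacks
#'
#' @param gfp,mch arrays of dim `(n_y, n_x, n_z)` (matrices are treated as
#'   single-slice stacks) with non-negative intensities.
#' @param roi optional rectangular region `(y0, y1, x0, x1)` (1-based,
#'   inclusive) expected to contain the punctum; `NULL` means whole image.
#' @return An object of class `laco_scene`.
#' @export
laco_scene <- function(gfp, mch, roi = NULL) {
  as_stack <- function(a, name) {
    if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
    if (!is.array(a) || length(dim(a)) != 3L) {
      stopf("'%s' must be a (y, x, z) array or a matrix", name)
    }
    a
  }
  gfp <- as_stack(gfp, "gfp"); mch <- as_stack(mch, "mch")
  if (!identical(dim(gfp), dim(mch))) {
    stopf("channel shapes differ: gfp %s vs mch %s",
          paste(dim(gfp), collapse = "x"), paste(dim(mch), collapse = "x"))
  }
  if (!is.null(roi)) {
    roi <- as.integer(roi)
    if (length(roi) != 4L || roi[1L] < 1L || roi[3L] < 1L ||
        roi[2L] > dim(gfp)[1L] || roi[4L] > dim(gfp)[2L] ||
        roi[1L] > roi[2L] || roi[3L] > roi[4L]) {
      stopf("'roi' must be (y0, y1, x0, x1) within the image")
    }
  }
  structure(list(gfp = gfp, mch = mch, roi = roi, truth = NULL),
            class = "laco_scene")
}

#' Generate a synthetic two-channel droplet field
#'
#' Places disk-shaped droplets by seeded rejection sampling subject to a
#' minimum center-to-center separation. All droplets are painted in channel
#' A; a seeded random subset of `round(overlap_fraction * n)` droplets is
#' also painted in channel B. Gaussian noise is added per channel and
#' intensities clipped at zero.
#'
#' @param spec a [droplet_field_spec()].
#' @return An object of class `droplet_field`: list with `channel_a`,
#'   `channel_b` matrices and a `truth` data frame (id, center_y, center_x,
#'   radius_px, in_channel_b).
#' @export
make_droplet_field <- function(spec) {
  stopifnot(inherits(spec, "droplet_field_spec"))
  ny <- spec$image_shape[1L]; nx <- spec$image_shape[2L]
  r_max <- spec$radius_range_px[2L]
  pad <- ceiling(r_max) + 1
  if (spec$n_droplets > 0 && (ny <= 2 * pad || nx <= 2 * pad)) {
    stopf("image too small to hold droplets of radius %.1f", r_max)
  }
  truth <- with_seed(spec$seed, {
    centers <- matrix(numeric(0), ncol = 2L)
    radii <- numeric(0)
    for (i in seq_len(spec$n_droplets)) {
      placed <- FALSE
      for (attempt in seq_len(spec$max_attempts_per_droplet)) {
        cand <- c(stats::runif(1, pad + 1, ny - pad),
                  stats::runif(1, pad + 1, nx - pad))
        ok <- nrow(centers) == 0L ||
          all(sqrt(rowSums(sweep(centers, 2L, cand)^2)) >=
                spec$min_separation_px)
        if (ok) {
          centers <- rbind(centers, cand)
          radii <- c(radii, stats::runif(1, spec$radius_range_px[1L],
                                         spec$radius_range_px[2L]))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stopf(paste0("could not place droplet %d of %d after %d attempts: ",
                     "min_separation_px = %.1f is too dense for a %d x %d image"),
              i, spec$n_droplets, spec$max_attempts_per_droplet,
              spec$min_separation_px, ny, nx)
      }
    }
    in_b <- rep(FALSE, spec$n_droplets)
    n_b <- round(spec$overlap_fraction * spec$n_droplets)
    if (n_b > 0) in_b[sample.int(spec$n_droplets, n_b)] <- TRUE
    list(centers = centers, radii = radii, in_b = in_b,
         noise = if (spec$noise_sd > 0) {
           list(a = stats::rnorm(ny * nx, 0, spec$noise_sd),
                b = stats::rnorm(ny * nx, 0, spec$noise_sd))
         })
  })
  paint <- function(which_b) {
    img <- matrix(spec$background[if (which_b) 2L else 1L], ny, nx)
    amp <- spec$intensity_per_channel[if (which_b) 2L else 1L]
    for (i in seq_len(spec$n_droplets)) {
      if (which_b && !truth$in_b[i]) next
      cy <- truth$centers[i, 1L]; cx <- truth$centers[i, 2L]
      r <- truth$radii[i]
      ys <- max(1L, floor(cy - r)):min(ny, ceiling(cy + r))
      xs <- max(1L, floor(cx - r)):min(nx, ceiling(cx + r))
      d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
      img[ys, xs][d2 <= r^2] <- img[ys, xs][d2 <= r^2] + amp
    }
    img
  }
  a <- paint(FALSE); b <- paint(TRUE)
  if (spec$noise_sd > 0) {
    a <- a + matrix(truth$noise$a, ny, nx)
    b <- b + matrix(truth$noise$b, ny, nx)
    a[a < 0] <- 0; b[b < 0] <- 0
  }
  truth_df <- data.frame(
    id = seq_len(spec$n_droplets),
    center_y = if (spec$n_droplets) truth$centers[, 1L] else numeric(0),
    center_x = if (spec$n_droplets) truth$centers[, 2L] else numeric(0),
    radius_px = truth$radii,
    in_channel_b = truth$in_b
  )
  structure(list(channel_a = a, channel_b = b, truth = truth_df,
                 seed = spec$seed),
            class = "droplet_field")
}

#' Generate a synthetic FRAP trace
#'
#' Pre-bleach frames sit at `I0`; from the bleach frame onward intensity
#' follows `Ib + (I0 - Ib) * M * (1 - exp(-k * t))` with `t` the time since
#' the bleach and `Ib = I0 * (1 - bleach_depth)`. The recorded intensity
#' column additionally carries the constant background level (as a real ROI
#' measurement would); the background column is exactly
#' `background_level`. Noise is added to the intensity column only.
#'
#' @param spec a [frap_spec()].
#' @return An object of class `frap_trace`: data frame with columns
#'   `time_s`, `intensity`, `background`, plus attributes `bleach_index`
#'   (1-based first post-bleach frame) and `truth`.
#' @export
make_frap_trace <- function(spec) {
  stopifnot(inherits(spec, "frap_spec"))
  n <- spec$n_pre + spec$n_post
  time_s <- (seq_len(n) - 1) * spec$dt
  bleach_index <- spec$n_pre + 1L
  Ib <- spec$I0 * (1 - spec$bleach_depth)
  tau <- (seq_len(n) - bleach_index) * spec$dt
  model <- ifelse(
    seq_len(n) < bleach_index,
    spec$I0,
    Ib + (spec$I0 - Ib) * spec$mobile_fraction * (1 - exp(-spec$rate_k * tau))
  )
  intensity <- model + spec$background_level
  if (spec$noise_sd > 0) {
    intensity <- with_seed(spec$seed,
                           intensity + stats::rnorm(n, 0, spec$noise_sd))
    intensity[intensity < 0] <- 0
  }
  trace <- data.frame(time_s = time_s, intensity = intensity,
                      background = rep(spec$background_level, n))
  attr(trace, "bleach_index") <- bleach_index
  attr(trace, "truth") <- list(mobile_fraction = spec$mobile_fraction,
                               rate_k = spec$rate_k, I0 = spec$I0,
                               bleach_depth = spec$bleach_depth,
                               seed = spec$seed)
  class(trace) <- c("frap_trace", "data.frame")
  trace
}

#' Generate synthetic pooled CRISPR screen counts
#'
#' Draws negative-binomial sgRNA counts for each cell line at `T0` and a
#' late timepoint. `T0` expected abundance is uniform across guides. At the
#' late timepoint the expected abundance of guides targeting that line's
#' essential genes is multiplied by `2^depletion_log2fc`, and all expected
#' abundances are rescaled so the expected column total stays at the library
#' size (fixed sequencing depth). Variance is `mu + dispersion * mu^2`.
#'
#' @param spec a [screen_spec()].
#' @return An object of class `screen_counts`: list with `counts` (data
#'   frame: sgrna, gene, one integer column per sample), `samples` (data
#'   frame: sample, cell_line, timepoint in `T0`/`Tlate`) and `truth`
#'   (essential gene sets per line plus the generating effect size).
#' @export
make_screen_counts <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  n_sg <- spec$n_genes * spec$sgrnas_per_gene
  gene <- rep(spec$genes, each = spec$sgrnas_per_gene)
  sgrna <- sprintf("%s_sg%d", gene, rep(seq_len(spec$sgrnas_per_gene),
                                        times = spec$n_genes))
  draw <- function(mu) {
    if (spec$dispersion > 0) {
      stats::rnbinom(n_sg, mu = mu, size = 1 / spec$dispersion)
    } else {
      stats::rpois(n_sg, mu)
    }
  }
  counts <- data.frame(sgrna = sgrna, gene = gene)
  samples <- data.frame(sample = character(0), cell_line = character(0),
                        timepoint = character(0))
  with_seed(spec$seed, {
    for (line in spec$cell_lines) {
      mu0 <- rep(spec$library_size_per_sample / n_sg, n_sg)
      w <- rep(1, n_sg)
      w[gene %in% spec$essential_sets[[line]]] <- 2^spec$depletion_log2fc
      mu_late <- spec$library_size_per_sample * (mu0 * w) / sum(mu0 * w)
      for (tp in c("T0", "Tlate")) {
        sample_id <- paste(line, tp, sep = "_")
        counts[[sample_id]] <- draw(if (tp == "T0") mu0 else mu_late)
        samples <- rbind(samples,
                         data.frame(sample = sample_id, cell_line = line,
                                    timepoint = tp))
      }
    }
  })
  structure(list(counts = counts, samples = samples,
                 truth = list(essential_sets = spec$essential_sets,
                              depletion_log2fc = spec$depletion_log2fc,
                              seed = spec$seed)),
            class = "screen_counts")
}
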