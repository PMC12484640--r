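# Independent brute-force reference implementations: plain per-pixel loops,
# no vectorization, no code shared with the package internals. Used to
# cross-check the vectorized pipeline.

# Reflect padding lookup (edge pixel included in the mirror).
mirror_index <- function(i, n) {
  if (i < 1L) 1L - i else if (i > n) 2L * n + 1L - i else i
}

oracle_smooth_J5 <- function(slice, normalize = TRUE) {
  ny <- nrow(slice); nx <- ncol(slice)
  out <- matrix(0, ny, nx)
  for (y in seq_len(ny)) {
    for (x in seq_len(nx)) {
      s <- 0
      for (dy in -2:2) {
        for (dx in -2:2) {
          s <- s + slice[mirror_index(y + dy, ny), mirror_index(x + dx, nx)]
        }
      }
      out[y, x] <- if (normalize) s / 25 else s
    }
  }
  out
}

oracle_radial_profile <- function(slice, center, r_max) {
  sums <- numeric(r_max + 1L)
  cnts <- integer(r_max + 1L)
  for (x in seq_len(ncol(slice))) {    # column-major accumulation order
    for (y in seq_len(nrow(slice))) {
      k <- round(sqrt((y - center[1L])^2 + (x - center[2L])^2))
      if (k <= r_max) {
        sums[k + 1L] <- sums[k + 1L] + slice[y, x]
        cnts[k + 1L] <- cnts[k + 1L] + 1L
      }
    }
  }
  list(mean_intensity = ifelse(cnts > 0, sums / cnts, NA_real_),
       pixel_count = cnts)
}

# First k >= 1 whose forward difference is non-negative; r_max if none.
oracle_radius_scan <- function(mean_intensity) {
  m <- mean_intensity[!is.na(mean_intensity)]
  for (k in seq_len(length(m) - 2L)) {
    if (m[k + 2L] - m[k + 1L] >= 0) return(k)
  }
  length(m) - 1L
}

# Full enrichment pipeline, loops only.
oracle_enrichment <- function(scene, r_max) {
  d <- dim(scene$gfp)
  best_z <- 1L; best_val <- -Inf  # lowest z wins ties (strict >)
  for (z in seq_len(d[3L])) {
    m <- -Inf
    for (y in seq_len(d[1L])) {
      for (x in seq_len(d[2L])) {
        if (scene$gfp[y, x, z] > m) m <- scene$gfp[y, x, z]
      }
    }
    if (m > best_val) { best_val <- m; best_z <- z }
  }
  gfp <- scene$gfp[, , best_z]
  mch <- scene$mch[, , best_z]
  sm_gfp <- oracle_smooth_J5(gfp)
  cy <- 1L; cx <- 1L; m <- -Inf
  for (y in seq_len(nrow(sm_gfp))) {      # row-major argmax
    for (x in seq_len(ncol(sm_gfp))) {
      if (sm_gfp[y, x] > m) { m <- sm_gfp[y, x]; cy <- y; cx <- x }
    }
  }
  prof <- oracle_radial_profile(gfp, c(cy, cx), r_max)
  r <- oracle_radius_scan(prof$mean_intensity)
  sm <- oracle_smooth_J5(mch)
  py <- 0L; px <- 0L; m <- -Inf
  for (y in seq_len(nrow(sm))) {
    for (x in seq_len(ncol(sm))) {
      k <- round(sqrt((y - cy)^2 + (x - cx)^2))
      if (k <= r && sm[y, x] > m) { m <- sm[y, x]; py <- y; px <- x }
    }
  }
  i_peak <- (sm[py - 1L, px] + sm[py + 1L, px] +
               sm[py, px - 1L] + sm[py, px + 1L]) / 4
  prof_m <- oracle_radial_profile(sm, c(cy, cx), r + 2L)
  i_periphery <- (prof_m$mean_intensity[r + 2L] +
                    prof_m$mean_intensity[r + 3L]) / 2
  list(slice_index = best_z, center = c(cy, cx), radius_px = r,
       i_peak = i_peak, i_periphery = i_periphery,
       ratio = i_peak / i_periphery)
}

oracle_log2fc <- function(t0, late, pseudocount) {
  out <- numeric(length(t0))
  for (i in seq_along(t0)) {
    out[i] <- log2((late[i] + pseudocount) / (t0[i] + pseudocount))
  }
  out
}

# Build a radial_profile object from raw mean intensities (for scan tests).
profile_from_values <- function(values) {
  out <- data.frame(radius = seq_along(values) - 1L,
                    mean_intensity = values,
                    pixel_count = rep(1L, length(values)))
  attr(out, "truncated") <- FALSE
  class(out) <- c("radial_profile", "data.frame")
  out
}
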