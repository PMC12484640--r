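# Readers and writers. Images travel as grayscale multi-page TIFF (page
# order = z); tables as CSV/TSV with '#' header comments naming units and
# the tool version; configuration as YAML key-value files mirroring the
# generator specs. Intensities are kept as floating point in memory and
# quantized to 16-bit counts only on TIFF export. Coordinates in all
# tables are (y, x), 1-based inclusive.

#' Write an image stack as a 16-bit grayscale TIFF
#'
#' Values are rounded to integer counts, clipped to `[0, 65535]`, and
#' written one z-slice per page.
#'
#' @param stack numeric array `(y, x, z)` or a single matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3L)
  pages <- lapply(seq_len(dim(stack)[3L]), function(z) {
    q <- round(stack[, , z])
    q[q < 0] <- 0
    q[q > 65535] <- 65535
    q / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale TIFF stack
#'
#' Pages are stacked in file order as z-slices and returned as integer
#' counts (non-negative reals).
#'
#' @param path a grayscale 8- or 16-bit TIFF file.
#' @return Numeric array `(y, x, z)`.
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  for (p in pages) {
    if (!is.matrix(p)) {
      stopf("unsupported TIFF layout in %s: expected grayscale pages, got %s",
            path, paste(dim(p), collapse = "x"))
    }
  }
  d1 <- dim(pages[[1L]])
  for (p in pages) {
    if (!identical(dim(p), d1)) {
      stopf("mismatched page shapes in %s", path)
    }
  }
  out <- array(0, dim = c(d1, length(pages)))
  for (z in seq_along(pages)) out[, , z] <- pages[[z]]
  out
}

#' Load a two-channel LacO scene from TIFF files
#'
#' @param gfp_path,mch_path per-channel TIFF stacks of identical shape.
#' @param roi optional `(y0, y1, x0, x1)` region, 1-based inclusive.
#' @return A [laco_scene()].
#' @export
load_laco_scene <- function(gfp_path, mch_path, roi = NULL) {
  laco_scene(read_image_stack(gfp_path), read_image_stack(mch_path), roi)
}

#' Write a results table with a units header
#'
#' Writes a delimited table preceded by `#` comment lines recording the
#' tool version, the measurement units and any extra metadata. Numeric
#' columns are serialized with 17 significant digits so values round-trip
#' losslessly through [read_quant_table()].
#'
#' @param df data frame.
#' @param path output path.
#' @param units named character vector mapping column names to units
#'   (e.g. `c(radius_px = "px", time_s = "s")`); unnamed columns are
#'   reported as `a.u.` or dimensionless.
#' @param metadata optional named character vector of extra `# key: value`
#'   lines.
#' @param sep field separator (`","` for CSV, `"\t"` for TSV).
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(df, path, units = NULL, metadata = NULL,
                              sep = ",") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# puncta %s", pkg_version()), con)
  if (length(units)) {
    writeLines(sprintf("# units: %s",
                       paste(names(units), units, sep = " = ",
                             collapse = "; ")), con)
  }
  for (nm in names(metadata)) {
    writeLines(sprintf("# %s: %s", nm, metadata[[nm]]), con)
  }
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- sprintf("%.17g", out[[j]])
    }
  }
  utils::write.table(out, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a table written by [write_quant_table()]
#'
#' @param path input path.
#' @param sep field separator.
#' @return Data frame (comment lines are skipped).
#' @export
read_quant_table <- function(path, sep = ",") {
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
}

# ---- run configuration ------------------------------------------------

spec_constructors <- function() {
  list(laco = punctum_spec, droplets = droplet_field_spec,
       frap = frap_spec, screen = screen_spec)
}

#' Read a generator spec from a YAML config file
#'
#' The file must carry a `type` key (`laco`, `droplets`, `frap` or
#' `screen`); the remaining keys mirror the arguments of the matching spec
#' constructor. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @param overrides named list of values taking precedence over the file
#'   (e.g. a command-line seed).
#' @return A spec object of the matching class.
#' @export
read_spec_config <- function(path, overrides = NULL) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$type) || !cfg$type %in% names(spec_constructors())) {
    stopf("config must set type to one of: %s",
          paste(names(spec_constructors()), collapse = ", "))
  }
  ctor <- spec_constructors()[[cfg$type]]
  cfg$type <- NULL
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  if (length(bad <- setdiff(names(cfg), names(formals(ctor))))) {
    stopf("unknown config key: %s", bad[1L])
  }
  do.call(ctor, cfg)
}

# Resolved parameters are written next to every CLI output so a run can be
# reproduced from its artifacts alone.
write_resolved_config <- function(params, path) {
  params$tool_version <- pkg_version()
  yaml::write_yaml(params, path)
  invisible(path)
}
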