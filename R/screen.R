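# Pooled CRISPR screen scoring: depth normalization, per-sgRNA and
# gene-level log2 fold change, and candidate partitioning across cell
# lines.

count_columns <- function(counts) {
  setdiff(names(counts), c("sgrna", "gene"))
}

#' Normalize sgRNA counts to reads per 100,000
#'
#' Replaces every count by `100000 * count / column_total`, so each sample
#' column sums to 100,000. Idempotent and invariant to rescaling a sample's
#' counts by a positive constant.
#'
#' @param counts data frame with columns `sgrna`, `gene` and one numeric
#'   column per sample (e.g. the `counts` element of
#'   [make_screen_counts()]).
#' @return Data frame of the same shape with normalized sample columns.
#' @export
normalize_counts <- function(counts) {
  cols <- count_columns(counts)
  if (!length(cols)) stopf("no sample columns found")
  for (cl in cols) {
    tot <- sum(counts[[cl]])
    if (!is.finite(tot) || tot <= 0) {
      stopf("sample '%s' has zero total reads and cannot be normalized", cl)
    }
    counts[[cl]] <- 1e5 * counts[[cl]] / tot
  }
  counts
}

#' Per-sgRNA log2 fold change between timepoints
#'
#' Computes `log2((Tlate + pseudocount) / (T0 + pseudocount))` on
#' normalized counts for one cell line. If a timepoint has replicate
#' columns their normalized counts are averaged first.
#'
#' @param normalized a [normalize_counts()] result.
#' @param samples sample sheet: data frame with columns `sample`,
#'   `cell_line`, `timepoint` (values `T0` / `Tlate`).
#' @param cell_line which cell line to score.
#' @param pseudocount added to both timepoints before the ratio (default 1
#'   on the reads-per-100,000 scale; guards zero counts).
#' @return Data frame with columns `sgrna`, `gene`, `log2fc`.
#' @export
sgrna_log2fc <- function(normalized, samples, cell_line, pseudocount = 1) {
  req <- c("sample", "cell_line", "timepoint")
  if (!all(req %in% names(samples))) {
    stopf("sample sheet needs columns: %s", paste(req, collapse = ", "))
  }
  assert_scalar_num(pseudocount, "pseudocount", lower = 0)
  sel <- samples[samples$cell_line == cell_line, ]
  if (!nrow(sel)) stopf("unknown cell line '%s'", cell_line)
  tp_cols <- function(tp) {
    cols <- sel$sample[sel$timepoint == tp]
    if (!length(cols)) stopf("cell line '%s' has no %s sample", cell_line, tp)
    if (length(bad <- setdiff(cols, names(normalized)))) {
      stopf("sample '%s' missing from the count table", bad[1L])
    }
    rowMeans(as.matrix(normalized[cols]))
  }
  t0 <- tp_cols("T0")
  late <- tp_cols("Tlate")
  data.frame(sgrna = normalized$sgrna, gene = normalized$gene,
             log2fc = log2((late + pseudocount) / (t0 + pseudocount)))
}

#' Gene-level screen scores
#'
#' Aggregates per-sgRNA log2 fold changes to one score per gene. The
#' primary score is the median across the gene's sgRNAs (robust to a
#' single outlier guide); the mean and the number of guides are reported
#' alongside.
#'
#' @param sgrna_scores a [sgrna_log2fc()] result.
#' @return Data frame with columns `gene`, `log2fc` (median), `mean_log2fc`,
#'   `n_sgrna`, ordered by gene id.
#' @export
gene_score <- function(sgrna_scores) {
  if (!all(c("gene", "log2fc") %in% names(sgrna_scores))) {
    stopf("expected columns 'gene' and 'log2fc'")
  }
  split_lfc <- split(sgrna_scores$log2fc, sgrna_scores$gene)
  data.frame(gene = names(split_lfc),
             log2fc = vapply(split_lfc, stats::median, numeric(1)),
             mean_log2fc = vapply(split_lfc, mean, numeric(1)),
             n_sgrna = lengths(split_lfc),
             row.names = NULL)
}

#' Partition depleted genes into shared and line-specific candidates
#'
#' A gene is a hit in a cell line when its gene-level log2 fold change is
#' at or below `depletion_cutoff`. Shared candidates are hits in every
#' line; specific candidates are hits in exactly one.
#'
#' @param gene_scores named list (one element per cell line, >= 2) of
#'   [gene_score()] results.
#' @param depletion_cutoff log2 fold-change threshold (default -1, i.e.
#'   at least a two-fold drop).
#' @return List with `shared` (character vector), `specific` (named list of
#'   character vectors per line) and `table`, a data frame with one row per
#'   gene, per-line `log2fc_<line>` columns and a `category` column
#'   (`shared`, `<line>_specific`, or `none`).
#' @export
classify_candidates <- function(gene_scores, depletion_cutoff = -1) {
  if (length(gene_scores) < 2L || is.null(names(gene_scores))) {
    stopf("need a named list of gene scores for at least 2 cell lines")
  }
  lines <- names(gene_scores)
  tab <- NULL
  for (line in lines) {
    gs <- gene_scores[[line]][, c("gene", "log2fc")]
    names(gs)[2L] <- paste0("log2fc_", line)
    tab <- if (is.null(tab)) gs else merge(tab, gs, by = "gene", all = TRUE)
  }
  hits <- sapply(lines, function(line) {
    lfc <- tab[[paste0("log2fc_", line)]]
    !is.na(lfc) & lfc <= depletion_cutoff
  })
  n_hit <- rowSums(hits)
  category <- rep("none", nrow(tab))
  category[n_hit == length(lines)] <- "shared"
  for (line in lines) {
    only <- n_hit == 1L & hits[, line]
    category[only] <- paste0(line, "_specific")
  }
  tab$category <- category
  list(shared = tab$gene[category == "shared"],
       specific = stats::setNames(
         lapply(lines, function(line) {
           tab$gene[category == paste0(line, "_specific")]
         }),
         lines),
       table = tab)
}

#' Score a pooled screen end to end
#'
#' Convenience wrapper: normalize counts, compute per-sgRNA and gene-level
#' log2 fold changes for every cell line, and classify candidates.
#'
#' @param screen a [make_screen_counts()] result, or a list with `counts`
#'   and `samples` in the same layout.
#' @param pseudocount see [sgrna_log2fc()].
#' @param depletion_cutoff see [classify_candidates()].
#' @return List with `normalized`, `sgrna_scores` (named list per line),
#'   `gene_scores` (named list per line) and `candidates`.
#' @export
score_screen <- function(screen, pseudocount = 1, depletion_cutoff = -1) {
  normalized <- normalize_counts(screen$counts)
  lines <- unique(screen$samples$cell_line)
  sg <- lapply(lines, function(line) {
    sgrna_log2fc(normalized, screen$samples, line, pseudocount)
  })
  names(sg) <- lines
  gs <- lapply(sg, gene_score)
  candidates <- if (length(lines) >= 2L) {
    classify_candidates(gs, depletion_cutoff)
  }
  list(normalized = normalized, sgrna_scores = sg, gene_scores = gs,
       candidates = candidates)
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' Standard xenograft volume estimate `length * width^2 * 0.52` (mm^3 for
#' mm inputs).
#'
#' @param length_mm,width_mm caliper length and width in mm (vectorized).
#' @return Tumor volume in mm^3.
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm < 0) || any(width_mm < 0)) {
    stopf("caliper measurements must be non-negative")
  }
  length_mm * width_mm^2 * 0.52
}
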