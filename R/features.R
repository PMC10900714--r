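## Feature assembly: TF peak heights over promoter windows plus genomic and
## expression covariates, one row per lncRNA transcript.

#' TF peak height over a promoter window
#'
#' The feature value for one (TF, cell line) at one promoter: the maximum
#' narrowPeak signal height among peaks covering at least `min_frac` of the
#' promoter window (cutoff inclusive), or 0 when no peak qualifies. All
#' peaks must belong to a single (TF, cell line).
#'
#' @param promoter One-row data.frame with `chrom`, `start`, `end`.
#' @param peaks Peak data.frame (see [read_narrowpeak()]).
#' @param min_frac Minimum fraction of the promoter covered (default 0.10).
#' @return Non-negative scalar signal height.
#' @export
tf_peak_height <- function(promoter, peaks, min_frac = 0.10) {
  if (nrow(peaks) == 0L) return(0)
  if (length(unique(peaks$tf)) > 1L || length(unique(peaks$cell_line)) > 1L)
    stop_validation("peaks must share a single (tf, cell_line)")
  same <- peaks$chrom == promoter$chrom
  if (!any(same)) return(0)
  pk <- peaks[same, , drop = FALSE]
  frac <- overlap_fraction(promoter$start, promoter$end, pk$start, pk$end)
  ok <- frac >= min_frac
  if (!any(ok)) return(0)
  max(pk$signal[ok])
}

## Bulk version of the promoter x peak intersection via IRanges overlap
## machinery; returns max qualifying signal per (promoter, tf, cell) triple.
bulk_peak_heights <- function(promoters, peaks, min_frac = 0.10) {
  pr <- GenomicRanges::GRanges(promoters$chrom,
          IRanges::IRanges(promoters$start + 1L, promoters$end))
  pk <- GenomicRanges::GRanges(peaks$chrom,
          IRanges::IRanges(peaks$start + 1L, peaks$end))
  hits <- GenomicRanges::findOverlaps(pr, pk, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(pr)[qi],
                                           IRanges::ranges(pk)[si]))
  frac <- ov / (promoters$end[qi] - promoters$start[qi])
  keep <- frac >= min_frac
  data.frame(promoter_idx = qi[keep],
             tf = peaks$tf[si][keep],
             cell_line = peaks$cell_line[si][keep],
             signal = peaks$signal[si][keep],
             stringsAsFactors = FALSE)
}

#' Assemble the per-transcript feature matrix
#'
#' Builds the model's design matrix: one row per lncRNA transcript, with
#' three column families in deterministic order —
#' \describe{
#'   \item{tf_binding}{one column `tf_<TF>.<cell>` per (TF, cell line):
#'     the maximum qualifying peak height over the transcript's 400 bp
#'     promoter window (`[-300, +100]` around the TSS, strand-aware,
#'     10\% intersection cutoff); 0 encodes no qualifying peak.}
#'   \item{genomic}{`tss_pc_distance` (bp to the nearest protein-coding TSS
#'     on the same chromosome, capped at `no_neighbor` when none exists),
#'     `transcript_length`, `exon_count`, `enhancer_distance` (bp from the
#'     promoter midpoint to the nearest enhancer, 0 if overlapping; only
#'     when `enhancers` is supplied) and `n_tfs_bound` (number of TFs with
#'     a qualifying peak in the scoring cell line).}
#'   \item{expression}{one `log2_fpkm_<cell>` column per cell line, taken
#'     from the expression table.}
#' }
#'
#' @param transcripts lncRNA transcript records (see
#'   [read_gtf_transcripts()]); rows with other biotypes are dropped.
#' @param peaks Combined peak table with `tf` and `cell_line` columns.
#' @param expression Expression table; must contain every lncRNA transcript.
#' @param pcg_transcripts Protein-coding transcript records used for the
#'   TSS-distance feature.
#' @param enhancers Optional enhancer data.frame (`chrom`, `start`, `end`).
#' @param cell_lines Character vector of cell lines to featurize; the first
#'   is the scoring cell line used for `n_tfs_bound`.
#' @param chrom_lengths Named vector of contig lengths for promoter
#'   clipping; defaults to per-chromosome max coordinate seen in the inputs.
#' @param min_frac Promoter-intersection cutoff (default 0.10).
#' @param no_neighbor Sentinel distance when a chromosome has no
#'   protein-coding TSS (default 1e8 bp).
#' @return Numeric matrix (transcripts x features) with a `provenance`
#'   attribute classing each column as tf_binding / genomic / expression.
#' @export
assemble_features <- function(transcripts, peaks, expression, pcg_transcripts,
                              enhancers = NULL, cell_lines = NULL,
                              chrom_lengths = NULL, min_frac = 0.10,
                              no_neighbor = 1e8) {
  lnc <- transcripts[transcripts$biotype == "lncRNA", , drop = FALSE]
  if (nrow(lnc) == 0L) stop_validation("no lncRNA transcripts to featurize")
  if (is.null(cell_lines)) cell_lines <- sort(unique(peaks$cell_line))
  peaks <- peaks[peaks$cell_line %in% cell_lines, , drop = FALSE]
  tfs <- sort(unique(peaks$tf))
  if (length(tfs) == 0L) stop_validation("no peaks for the requested cell lines")

  missing <- setdiff(lnc$transcript_id, expression$transcript_id)
  if (length(missing))
    stop_validation("expression missing for transcript(s): %s%s",
                    paste(utils::head(missing, 10), collapse = ", "),
                    if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10) else "")

  if (is.null(chrom_lengths)) {
    all_chrom <- c(transcripts$chrom, peaks$chrom)
    all_end <- c(transcripts$end, peaks$end)
    chrom_lengths <- tapply(all_end, all_chrom, max) + 1e6
  }
  win <- promoter_window(lnc$tss, lnc$strand, chrom_lengths[lnc$chrom])
  promoters <- data.frame(chrom = lnc$chrom, start = win$start, end = win$end)

  ## TF-binding block
  tf_cols <- as.vector(t(outer(tfs, cell_lines,
                               function(a, b) paste0("tf_", a, ".", b))))
  tfb <- matrix(0, nrow(lnc), length(tf_cols),
                dimnames = list(lnc$transcript_id, tf_cols))
  hits <- bulk_peak_heights(promoters, peaks, min_frac)
  if (nrow(hits)) {
    col <- paste0("tf_", hits$tf, ".", hits$cell_line)
    agg <- tapply(hits$signal, list(hits$promoter_idx, col), max)
    ri <- as.integer(rownames(agg))
    for (j in colnames(agg)) {
      v <- agg[, j]
      ok <- !is.na(v)
      tfb[ri[ok], j] <- v[ok]
    }
  }

  ## Genomic block
  scoring_cols <- paste0("tf_", tfs, ".", cell_lines[1])
  n_tfs_bound <- rowSums(tfb[, scoring_cols, drop = FALSE] > 0)
  pcg_by_chrom <- split(pcg_transcripts$tss, pcg_transcripts$chrom)
  tss_pc_distance <- vapply(seq_len(nrow(lnc)), function(i)
    nearest_tss_distance(lnc$tss[i], pcg_by_chrom[[lnc$chrom[i]]] %||% numeric(0),
                         no_neighbor), numeric(1))
  genomic <- cbind(tss_pc_distance = tss_pc_distance,
                   transcript_length = as.numeric(lnc$length),
                   exon_count = as.numeric(lnc$exon_count))
  if (!is.null(enhancers)) {
    mid <- (promoters$start + promoters$end) / 2
    enh_by_chrom <- split(enhancers, enhancers$chrom)
    enhancer_distance <- vapply(seq_len(nrow(lnc)), function(i) {
      e <- enh_by_chrom[[lnc$chrom[i]]]
      if (is.null(e) || nrow(e) == 0L) return(no_neighbor)
      d <- pmax(0, pmax(e$start - mid[i], mid[i] - e$end))
      min(d)
    }, numeric(1))
    genomic <- cbind(genomic, enhancer_distance = enhancer_distance)
  }
  genomic <- cbind(genomic, n_tfs_bound = as.numeric(n_tfs_bound))

  ## Expression block
  expr_cols <- paste0("log2_fpkm_", cell_lines)
  have <- intersect(expr_cols, names(expression))
  if (length(have) != length(expr_cols))
    stop_validation("expression table lacks column(s): %s",
                    paste(setdiff(expr_cols, have), collapse = ", "))
  ei <- match(lnc$transcript_id, expression$transcript_id)
  expr <- as.matrix(expression[ei, expr_cols, drop = FALSE])
  rownames(expr) <- lnc$transcript_id
  if (any(!is.finite(expr)))
    stop_validation("non-finite expression values")

  m <- cbind(tfb, genomic, expr)
  attr(m, "provenance") <- stats::setNames(
    c(rep("tf_binding", ncol(tfb)), rep("genomic", ncol(genomic)),
      rep("expression", ncol(expr))), colnames(m))
  m
}
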