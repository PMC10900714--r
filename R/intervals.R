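## Interval layer. All coordinates inside the package are 0-based half-open
## [start, end), the BED convention; GTF input (1-based inclusive) is
## converted on read. Strand is "+", "-" or "." (unstranded).

#' Fraction of interval `a` covered by interval `b`
#'
#' Overlap is computed on 0-based half-open intervals. Intervals on
#' different chromosomes do not overlap. This is the quantity the 10%
#' promoter-intersection cutoff is applied to: the fraction of the
#' *promoter* (the `a` feature) covered by a ChIP-seq peak.
#'
#' @param a_start,a_end,b_start,b_end Interval bounds (0-based half-open).
#'   Vectorized; recycled to a common length.
#' @param a_chrom,b_chrom Optional chromosome names; when supplied, pairs on
#'   different chromosomes get overlap 0.
#' @return Numeric vector of fractions in `[0, 1]`: `|a intersect b| / |a|`.
#' @examples
#' overlap_fraction(0, 400, 360, 500)  # 40/400 = 0.1
#' @export
overlap_fraction <- function(a_start, a_end, b_start, b_end,
                             a_chrom = NULL, b_chrom = NULL) {
  n <- max(length(a_start), length(b_start))
  a_start <- rep_len(as.numeric(a_start), n); a_end <- rep_len(as.numeric(a_end), n)
  b_start <- rep_len(as.numeric(b_start), n); b_end <- rep_len(as.numeric(b_end), n)
  if (any(a_start >= a_end) || any(b_start >= b_end))
    stop_validation("intervals must satisfy start < end")
  ov <- pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start))
  frac <- ov / (a_end - a_start)
  if (!is.null(a_chrom) && !is.null(b_chrom)) {
    frac[rep_len(as.character(a_chrom), n) != rep_len(as.character(b_chrom), n)] <- 0
  }
  frac
}

#' Strand-aware promoter window around a TSS
#'
#' The promoter is the window `[-upstream, +downstream]` bp around the
#' transcription start site, oriented by strand and clipped at contig
#' boundaries. With the defaults (300 bp upstream, 100 bp downstream) the
#' unclipped window is 400 bp wide: `[tss-300, tss+100)` on the plus strand
#' and its mirror `[tss-99, tss+301)` on the minus strand.
#'
#' @param tss 0-based position(s) of the first transcribed base.
#' @param strand "+" or "-" (recycled).
#' @param chrom_length Contig length in bp, used for clipping.
#' @param upstream,downstream Window extent in bp relative to transcription
#'   direction.
#' @return A data.frame with columns `start`, `end` (0-based half-open).
#' @examples
#' promoter_window(1000, "+", 1e6)  # [700, 1100)
#' promoter_window(1000, "-", 1e6)  # [901, 1301)
#' @export
promoter_window <- function(tss, strand, chrom_length,
                            upstream = 300, downstream = 100) {
  n <- length(tss)
  strand <- rep_len(strand, n)
  chrom_length <- rep_len(as.numeric(chrom_length), n)
  if (any(tss < 0) || any(tss >= chrom_length))
    stop_validation("tss must lie within [0, chrom_length)")
  if (!all(strand %in% c("+", "-")))
    stop_validation("strand must be '+' or '-' for promoter windows")
  plus <- strand == "+"
  start <- ifelse(plus, tss - upstream, tss - (downstream - 1))
  end   <- ifelse(plus, tss + downstream, tss + upstream + 1)
  data.frame(start = pmax(0, start), end = pmin(chrom_length, end))
}

#' Distance to the nearest protein-coding TSS
#'
#' Minimum absolute TSS-to-TSS distance between a lncRNA TSS and a set of
#' protein-coding TSS positions on the same chromosome. When no
#' protein-coding TSS exists on the chromosome, a sentinel cap is returned
#' (default 1e8 bp) and should be treated as "no neighbor".
#'
#' @param lnc_tss 0-based TSS position.
#' @param pcg_tss Numeric vector of protein-coding TSS positions on the same
#'   chromosome (may be empty).
#' @param no_neighbor Sentinel value returned when `pcg_tss` is empty.
#' @return Distance in bp.
#' @export
nearest_tss_distance <- function(lnc_tss, pcg_tss, no_neighbor = 1e8) {
  if (length(pcg_tss) == 0L) return(no_neighbor)
  min(abs(lnc_tss - pcg_tss))
}
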