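## Convenience wrapper tying the readers and the feature assembler together
## for a directory laid out like a generated bundle (or any directory with
## the same file names).

#' Build a feature matrix from an input bundle directory
#'
#' Expects `annotation.gtf`, `peaks/*.narrowPeak` (named
#' `<TF>.<cell>.narrowPeak`), `expression.tsv` and optionally
#' `enhancers.bed` under `dir`, as written by [generate_dataset()].
#'
#' @param dir Bundle directory.
#' @param cell_lines Cell lines to featurize (default: all found, sorted);
#'   the first is the scoring cell line.
#' @param use_enhancers Include the enhancer-distance feature when
#'   `enhancers.bed` is present?
#' @param ... Passed to [assemble_features()].
#' @return Feature matrix (see [assemble_features()]).
#' @export
featurize_bundle <- function(dir, cell_lines = NULL, use_enhancers = TRUE, ...) {
  tx <- read_gtf_transcripts(file.path(dir, "annotation.gtf"))
  peaks <- read_peaks_dir(file.path(dir, "peaks"))
  expr <- read_expression_table(file.path(dir, "expression.tsv"))
  enh_path <- file.path(dir, "enhancers.bed")
  enh <- if (use_enhancers && file.exists(enh_path)) read_enhancers(enh_path) else NULL
  if (is.null(cell_lines)) cell_lines <- sort(unique(peaks$cell_line))
  assemble_features(tx[tx$biotype == "lncRNA", ], peaks, expr,
                    pcg_transcripts = tx[tx$biotype == "protein_coding", ],
                    enhancers = enh, cell_lines = cell_lines, ...)
}
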