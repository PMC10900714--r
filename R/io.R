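## Readers and writers for the standard formats the pipeline consumes:
## GTF annotation, narrowPeak ChIP-seq peaks, BED enhancers, TSV expression
## and label tables, TSV feature matrices with a JSON provenance sidecar.
## rtracklayer does the format-level parsing; this layer converts to the
## package's 0-based half-open transcript/peak tables and validates content.

#' Read transcript records from a GTF annotation
#'
#' Parses `transcript` and `exon` features, converts GTF 1-based inclusive
#' coordinates to 0-based half-open, derives the TSS from strand
#' (interval start on "+", `end - 1` on "-"), and sums exon lengths.
#' The biotype is read from the `transcript_biotype` (or `transcript_type`)
#' attribute and mapped to `lncRNA` / `protein_coding` / `other`.
#'
#' @param path GTF file (gzip allowed).
#' @return data.frame with columns `transcript_id`, `gene_id`, `biotype`,
#'   `chrom`, `start`, `end`, `strand`, `tss`, `exon_count`, `length`.
#' @export
read_gtf_transcripts <- function(path) {
  check_file_exists(path, "GTF")
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop_validation("GTF parse error in %s: %s",
                                                     path, conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (!all(c("type", "transcript_id") %in% names(df)))
    stop_validation("GTF %s lacks type/transcript_id attributes", path)
  bt_col <- intersect(c("transcript_biotype", "transcript_type", "gene_biotype"),
                      names(df))[1]
  tx <- df[df$type == "transcript", , drop = FALSE]
  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(tx) == 0L) stop_validation("GTF %s contains no transcript features", path)
  n_ex <- table(ex$transcript_id)
  missing_ex <- setdiff(tx$transcript_id, names(n_ex))
  if (length(missing_ex))
    stop_validation("transcript(s) without exons in %s: %s", path,
                    paste(utils::head(missing_ex, 5), collapse = ", "))
  ex_len <- tapply(ex$width, ex$transcript_id, sum)
  biotype <- if (is.na(bt_col)) rep("other", nrow(tx)) else as.character(tx[[bt_col]])
  biotype[!biotype %in% c("lncRNA", "protein_coding")] <- "other"
  strand <- as.character(tx$strand)
  start0 <- tx$start - 1L          # GTF 1-based inclusive -> 0-based half-open
  end0 <- tx$end
  out <- data.frame(
    transcript_id = tx$transcript_id,
    gene_id = if ("gene_id" %in% names(tx)) tx$gene_id else tx$transcript_id,
    biotype = biotype,
    chrom = as.character(tx$seqnames),
    start = start0,
    end = end0,
    strand = strand,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    exon_count = as.integer(n_ex[tx$transcript_id]),
    length = as.integer(ex_len[tx$transcript_id]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read a narrowPeak (BED6+4) peak file
#'
#' @param path narrowPeak file; 0-based half-open coordinates are kept as-is.
#' @param tf_name,cell_line Labels attached to every peak in the file.
#' @return data.frame with `chrom`, `start`, `end`, `tf`, `cell_line`,
#'   `signal` (the narrowPeak signalValue column, the analog peak height).
#' @export
read_narrowpeak <- function(path, tf_name, cell_line) {
  check_file_exists(path, "narrowPeak")
  extra <- c(signalValue = "numeric", pValue = "numeric",
             qValue = "numeric", peak = "integer")
  gr <- tryCatch(rtracklayer::import(path, format = "BED", extraCols = extra),
                 error = function(e) stop_validation("narrowPeak parse error in %s: %s",
                                                     path, conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (any(df$signalValue < 0))
    stop_validation("negative signalValue in %s", path)
  data.frame(chrom = as.character(df$seqnames),
             start = df$start - 1L,   # GRanges 1-based -> 0-based half-open
             end = df$end,
             tf = tf_name, cell_line = cell_line,
             signal = df$signalValue,
             stringsAsFactors = FALSE)
}

#' Read all narrowPeak files in a directory
#'
#' File names must follow `<TF>.<cell_line>.narrowPeak`.
#'
#' @param dir Directory of narrowPeak files.
#' @return Combined peak data.frame (see [read_narrowpeak()]).
#' @export
read_peaks_dir <- function(dir) {
  if (!dir.exists(dir)) stop_io("peaks directory not found: %s", dir)
  files <- sort(list.files(dir, pattern = "\\.narrowPeak$", full.names = TRUE))
  if (length(files) == 0L) stop_validation("no .narrowPeak files in %s", dir)
  parts <- strsplit(sub("\\.narrowPeak$", "", basename(files)), ".", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop_validation("peak file name must be <TF>.<cell>.narrowPeak: %s",
                    basename(files[bad][1]))
  do.call(rbind, Map(function(f, p) read_narrowpeak(f, p[1], p[2]), files, parts))
}

#' Read a BED6 enhancer file
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_enhancers <- function(path) {
  check_file_exists(path, "enhancer BED")
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop_validation("BED parse error in %s: %s",
                                                     path, conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  data.frame(chrom = as.character(df$seqnames), start = df$start - 1L,
             end = df$end, stringsAsFactors = FALSE)
}

#' Read a per-transcript expression table
#'
#' Tab-separated, first column `transcript_id`, remaining columns log2 FPKM
#' per cell line.
#'
#' @param path TSV file.
#' @return data.frame keyed by `transcript_id`.
#' @export
read_expression_table <- function(path) {
  check_file_exists(path, "expression table")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "transcript_id")
    stop_validation("expression table must start with a transcript_id column")
  if (anyDuplicated(df$transcript_id))
    stop_validation("duplicate transcript_id in expression table")
  df
}

#' Read binary screen labels
#'
#' Tab-separated with columns `transcript_id` and `hit` (0/1).
#'
#' @param path TSV file.
#' @return data.frame with `transcript_id`, `hit`.
#' @export
read_labels <- function(path) {
  check_file_exists(path, "labels table")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "hit") %in% names(df)))
    stop_validation("labels table needs transcript_id and hit columns")
  if (!all(df$hit %in% c(0L, 1L)))
    stop_validation("hit labels must be 0 or 1")
  if (anyDuplicated(df$transcript_id))
    stop_validation("duplicate transcript_id in labels table")
  df[c("transcript_id", "hit")]
}

#' Write a feature matrix as TSV plus a JSON provenance sidecar
#'
#' Output is byte-reproducible: fixed column order, plain decimal notation.
#' The sidecar (`<out>.provenance.json`) records each column's provenance
#' class (`tf_binding`, `genomic`, `expression`).
#'
#' @param x Feature matrix from [assemble_features()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- paste(c("transcript_id", colnames(x)), collapse = "\t")
  lines <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], format_num(x[i, ])), collapse = "\t"), character(1))
  writeLines(c(header, lines), con, sep = "\n")
  prov <- attr(x, "provenance") %||%
    stats::setNames(rep("genomic", ncol(x)), colnames(x))
  jsonlite::write_json(as.list(prov), paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path TSV path.
#' @return Numeric matrix with transcript_id rownames; the `provenance`
#'   attribute is restored from the sidecar when present.
#' @export
read_feature_matrix <- function(path) {
  check_file_exists(path, "feature matrix")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar)) {
    prov <- unlist(jsonlite::read_json(sidecar))
    attr(m, "provenance") <- prov[colnames(m)]
  }
  m
}
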