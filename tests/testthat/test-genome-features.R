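write_mini_gtf <- function(path) {
  attrs <- function(id, bt) sprintf(
    'gene_id "G_%s"; transcript_id "%s"; transcript_biotype "%s";', id, id, bt)
  writeLines(c(
    sprintf("chr1\tsynth\ttranscript\t101\t500\t.\t+\t.\t%s", attrs("TXP", "lncRNA")),
    sprintf("chr1\tsynth\texon\t101\t200\t.\t+\t.\t%s", attrs("TXP", "lncRNA")),
    sprintf("chr1\tsynth\texon\t301\t500\t.\t+\t.\t%s", attrs("TXP", "lncRNA")),
    sprintf("chr1\tsynth\ttranscript\t101\t500\t.\t-\t.\t%s", attrs("TXM", "protein_coding")),
    sprintf("chr1\tsynth\texon\t101\t500\t.\t-\t.\t%s", attrs("TXM", "protein_coding"))
  ), path)
  path
}

test_that("GTF parsing converts coordinates and derives TSS by strand", {
  tx <- read_gtf_transcripts(write_mini_gtf(tempfile(fileext = ".gtf")))
  plus <- tx[tx$transcript_id == "TXP", ]
  minus <- tx[tx$transcript_id == "TXM", ]
  # 1-based inclusive [101, 500] -> 0-based half-open [100, 500)
  expect_equal(c(plus$start, plus$end, plus$tss), c(100, 500, 100))
  expect_equal(plus$exon_count, 2L)
  expect_equal(plus$length, 300L)   # 100 + 200 bp exons
  expect_equal(c(minus$start, minus$end, minus$tss), c(100, 500, 499))
  expect_equal(minus$biotype, "protein_coding")
})

test_that("generated annotations round-trip through the GTF parser", {
  fx <- shared_small_fixture()
  tx <- read_gtf_transcripts(file.path(fx$dir, "annotation.gtf"))
  cfg <- small_synth_config()
  expect_equal(nrow(tx), cfg$n_lnc + cfg$n_pcg)
  expect_equal(sum(tx$biotype == "lncRNA"), cfg$n_lnc)
  expect_true(all(tx$start < tx$end))
  expect_true(all(tx$exon_count >= 1))
  expect_true(all(tx$length >= 1 & tx$length <= tx$end - tx$start))
  expect_true(all(ifelse(tx$strand == "+", tx$tss == tx$start,
                         tx$tss == tx$end - 1)))
  # parsing twice gives identical records
  expect_identical(tx, read_gtf_transcripts(file.path(fx$dir, "annotation.gtf")))
})

test_that("tf_peak_height applies the inclusive 10% cutoff and max rule", {
  prom <- data.frame(chrom = "chr1", start = 0, end = 400)
  pk <- function(s, e, sig) data.frame(chrom = "chr1", start = s, end = e,
                                       tf = "TF1", cell_line = "K562",
                                       signal = sig)
  # no overlapping peaks -> absence encoded as 0
  expect_equal(tf_peak_height(prom, pk(1000, 1200, 9)), 0)
  # exactly 40 bp of a 400 bp promoter: cutoff met at equality
  expect_equal(tf_peak_height(prom, pk(360, 500, 6.2)), 6.2)
  # one bp short of the cutoff -> rejected
  expect_equal(tf_peak_height(prom, pk(361, 500, 6.2)), 0)
  # two qualifying peaks -> the maximum height wins
  two <- rbind(pk(0, 100, 5.0), pk(200, 400, 7.5))
  expect_equal(tf_peak_height(prom, two), 7.5)
  # mixed (tf, cell line) input is a contract violation
  mixed <- rbind(pk(0, 100, 5), transform(pk(0, 100, 5), tf = "TF2"))
  expect_error(tf_peak_height(prom, mixed), "single")
})

test_that("feature matrix has the documented shape and column families", {
  fx <- shared_small_fixture()
  m <- fx$matrix
  cfg <- small_synth_config()
  # per-(TF, cell) binding + 5 genomic (incl. enhancer_distance) + 2 expression
  expect_equal(dim(m), c(cfg$n_lnc, cfg$n_tfs * cfg$n_cell_lines + 5 + 2))
  prov <- attr(m, "provenance")
  expect_equal(sum(prov == "tf_binding"), cfg$n_tfs * cfg$n_cell_lines)
  expect_equal(sum(prov == "expression"), cfg$n_cell_lines)
  expect_true(all(m[, prov == "tf_binding"] >= 0))
  expect_false(anyDuplicated(rownames(m)) > 0)
  expect_false(anyDuplicated(colnames(m)) > 0)
  expect_true(all(is.finite(m)))
  # n_tfs_bound counts positive binding columns of the scoring cell line
  sc_cols <- grep("\\.CL1$", colnames(m), value = TRUE)
  expect_equal(unname(m[, "n_tfs_bound"]),
               unname(rowSums(m[, sc_cols, drop = FALSE] > 0)))
})

test_that("omitting enhancers drops exactly the enhancer_distance column", {
  fx <- shared_small_fixture()
  m <- featurize_bundle(fx$dir, use_enhancers = FALSE)
  expect_equal(setdiff(colnames(fx$matrix), colnames(m)), "enhancer_distance")
})

test_that("feature assembly is invariant to peak row order", {
  fx <- shared_small_fixture()
  tx <- read_gtf_transcripts(file.path(fx$dir, "annotation.gtf"))
  peaks <- read_peaks_dir(file.path(fx$dir, "peaks"))
  expr <- read_expression_table(file.path(fx$dir, "expression.tsv"))
  enh <- read_enhancers(file.path(fx$dir, "enhancers.bed"))
  lnc <- tx[tx$biotype == "lncRNA", ]
  pcg <- tx[tx$biotype == "protein_coding", ]
  m1 <- assemble_features(lnc, peaks, expr, pcg, enhancers = enh,
                          cell_lines = c("CL1", "CL2"))
  set.seed(3)
  m2 <- assemble_features(lnc, peaks[sample(nrow(peaks)), ], expr, pcg,
                          enhancers = enh, cell_lines = c("CL1", "CL2"))
  expect_identical(m1, m2)
})

test_that("bulk overlap assembly agrees with the scalar per-promoter contract", {
  fx <- shared_small_fixture()
  tx <- read_gtf_transcripts(file.path(fx$dir, "annotation.gtf"))
  peaks <- read_peaks_dir(file.path(fx$dir, "peaks"))
  lnc <- tx[tx$biotype == "lncRNA", ][1:25, ]
  win <- promoter_window(lnc$tss, lnc$strand, 1e6)
  for (i in seq_len(nrow(lnc))) {
    prom <- data.frame(chrom = lnc$chrom[i], start = win$start[i],
                       end = win$end[i])
    for (key in c("TF01.CL1", "TF03.CL2")) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      sub <- peaks[peaks$tf == parts[1] & peaks$cell_line == parts[2], ]
      col <- paste0("tf_", key)
      expect_equal(unname(fx$matrix[lnc$transcript_id[i], col]),
                   tf_peak_height(prom, sub))
    }
  }
})

test_that("missing expression entries raise an error naming the transcripts", {
  fx <- shared_small_fixture()
  tx <- read_gtf_transcripts(file.path(fx$dir, "annotation.gtf"))
  peaks <- read_peaks_dir(file.path(fx$dir, "peaks"))
  expr <- read_expression_table(file.path(fx$dir, "expression.tsv"))
  lnc <- tx[tx$biotype == "lncRNA", ]
  dropped <- lnc$transcript_id[1]
  expect_error(
    assemble_features(lnc, peaks, expr[expr$transcript_id != dropped, ],
                      tx[tx$biotype == "protein_coding", ],
                      cell_lines = c("CL1", "CL2")),
    dropped, fixed = TRUE)
})

test_that("feature matrix TSV output is byte-identical across writes", {
  fx <- shared_small_fixture()
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_feature_matrix(fx$matrix, f1)
  write_feature_matrix(fx$matrix, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- read_feature_matrix(f1)
  expect_equal(back, fx$matrix, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(attr(back, "provenance"), attr(fx$matrix, "provenance"))
})
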