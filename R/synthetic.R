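## Synthetic fixture generator. Emulates the structure of the real training
## data — GTF annotation, per-(TF, cell line) narrowPeak files, expression
## table, enhancer BED and CRISPRi hit labels — with a planted signal:
## a subset of TFs is informative, hit status is drawn from a logistic model
## on their standardized promoter peak heights, and expression is coupled to
## the same latent signal so that transcription correlates with
## functionality. A truth JSON records the planted structure for assertions.

#' Configuration of the synthetic dataset
#'
#' Defaults mirror a desk-scale version of the real training regime:
#' 2,000 lncRNAs with a 1:55 hit:non-hit imbalance, 25 TFs over 2 cell
#' lines of which 5 are informative, 500 protein-coding transcripts for the
#' proximity feature, 4 chromosomes of 10 Mb.
#'
#' @param n_lnc,n_pcg Number of lncRNA / protein-coding transcripts.
#' @param n_tfs,n_cell_lines TF-binding feature grid.
#' @param n_chroms,chrom_length Genome layout.
#' @param hit_fraction Expected fraction of lncRNA hits (default 1/56).
#' @param n_informative_tfs TFs whose peak heights carry the signal.
#' @param effect_size Logit units per standardized informative peak height.
#' @param noise_sd SD of the latent logit noise.
#' @param p_bind Probability a TF binds a given promoter.
#' @param height_meanlog,height_sdlog Log-normal peak-height parameters.
#' @param height_jitter_sdlog Per-cell-line log-scale height jitter.
#' @param expr_sd SD of baseline log2 FPKM.
#' @param expr_coupling Coupling of expression to the mean standardized
#'   informative peak height (log2 FPKM units).
#' @param expr_jitter_sd Per-cell-line expression jitter.
#' @param n_background_peaks Background peaks per narrowPeak file.
#' @param n_enhancers Enhancer intervals.
#' @param seed Root seed; the bundle is byte-identical for a fixed config.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_lnc = 2000, n_pcg = 500, n_tfs = 25,
                             n_cell_lines = 2, n_chroms = 4,
                             chrom_length = 1e7, hit_fraction = 1/56,
                             n_informative_tfs = 5, effect_size = 1.5,
                             noise_sd = 0.5, p_bind = 0.35,
                             height_meanlog = 1.0, height_sdlog = 0.6,
                             height_jitter_sdlog = 0.25,
                             expr_sd = 1.5, expr_coupling = 0.75,
                             expr_jitter_sd = 0.3,
                             n_background_peaks = 40, n_enhancers = 200,
                             seed = 0) {
  if (hit_fraction <= 0 || hit_fraction >= 0.5)
    stop_validation("hit_fraction must lie in (0, 0.5)")
  if (n_informative_tfs > n_tfs)
    stop_validation("n_informative_tfs cannot exceed n_tfs")
  structure(as.list(environment()), class = "synthetic_config")
}

## Place transcripts on a per-chromosome jittered grid: slots are wide
## enough that promoter windows of neighboring transcripts never collide,
## while jitter keeps TSS spacings variable for the distance features.
place_transcripts <- function(cfg) {
  n_total <- cfg$n_lnc + cfg$n_pcg
  chrom_of <- rep_len(seq_len(cfg$n_chroms), n_total)
  rows <- list()
  margin <- 2000
  for (ch in seq_len(cfg$n_chroms)) {
    n_ch <- sum(chrom_of == ch)
    w <- floor(cfg$chrom_length / n_ch)
    if (w < 2 * margin + 600)
      stop_validation("chrom_length too small for the transcript count")
    span_max <- min(10000, w - 2 * margin - 1)
    span <- sample(500:span_max, n_ch, replace = TRUE)
    offset <- floor(stats::runif(n_ch) * (w - span - 2 * margin))
    start <- (seq_len(n_ch) - 1L) * w + margin + offset
    rows[[ch]] <- data.frame(chrom = sprintf("chr%d", ch),
                             start = start, end = start + span,
                             strand = sample(c("+", "-"), n_ch, replace = TRUE),
                             stringsAsFactors = FALSE)
  }
  tx <- do.call(rbind, rows)
  is_lnc <- sample(rep(c(TRUE, FALSE), c(cfg$n_lnc, cfg$n_pcg)))
  tx$biotype <- ifelse(is_lnc, "lncRNA", "protein_coding")
  tx$transcript_id <- ifelse(is_lnc,
                             sprintf("LNC%05d", cumsum(is_lnc)),
                             sprintf("PCG%05d", cumsum(!is_lnc)))
  tx$gene_id <- sub("^(LNC|PCG)", "G\\1", tx$transcript_id)
  tx$tss <- ifelse(tx$strand == "+", tx$start, tx$end - 1L)
  tx
}

## Random exon structure: boundaries are strictly increasing cuts inside the
## transcript span; exon blocks alternate with introns.
make_exons <- function(start, end, n_exons) {
  if (n_exons == 1L) return(cbind(start, end))
  cuts <- sort(sample((start + 1L):(end - 1L), 2L * (n_exons - 1L)))
  s <- c(start, cuts[seq(2, length(cuts), by = 2)])
  e <- c(cuts[seq(1, length(cuts), by = 2)], end)
  cbind(s, e)
}

write_gtf <- function(tx, exons_by_tx, path) {
  lines <- character(0)
  for (i in seq_len(nrow(tx))) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
                     tx$gene_id[i], tx$transcript_id[i], tx$biotype[i])
    ## 0-based half-open -> GTF 1-based inclusive
    lines <- c(lines, sprintf("%s\tsynth\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              tx$chrom[i], tx$start[i] + 1L, tx$end[i],
                              tx$strand[i], attrs))
    ex <- exons_by_tx[[i]]
    lines <- c(lines, sprintf("%s\tsynth\texon\t%d\t%d\t.\t%s\t.\t%s",
                              tx$chrom[i], ex[, 1] + 1L, ex[, 2],
                              tx$strand[i], attrs))
  }
  writeLines(lines, path)
}

#' Generate a synthetic fixture bundle
#'
#' Writes `annotation.gtf`, `peaks/<TF>.<cell>.narrowPeak`,
#' `expression.tsv`, `enhancers.bed`, `labels.tsv` and `truth.json` into
#' `out_dir`. Hit labels are drawn from a logistic model on the
#' standardized true peak heights of the informative TFs (intercept
#' calibrated so the expected hit fraction matches the configuration);
#' expression is coupled to the same standardized heights, so at
#' `effect_size = 0` neither peaks nor expression carry label information.
#' The bundle is byte-identical for a fixed configuration and seed.
#'
#' @param config [synthetic_config()].
#' @param out_dir Output directory.
#' @param force Overwrite a non-empty `out_dir`?
#' @return `out_dir`, invisibly.
#' @export
generate_dataset <- function(config = synthetic_config(), out_dir,
                             force = FALSE) {
  if (!inherits(config, "synthetic_config"))
    stop_validation("config must be a synthetic_config")
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop_validation("out_dir %s exists and is non-empty (use force = TRUE)", out_dir)
  dir.create(file.path(out_dir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  with_seed(cfg$seed, {
    tx <- place_transcripts(cfg)
    n_total <- nrow(tx)
    exon_counts <- sample(1:6, n_total, replace = TRUE)
    exons_by_tx <- lapply(seq_len(n_total), function(i)
      make_exons(tx$start[i], tx$end[i], exon_counts[i]))
    write_gtf(tx, exons_by_tx, file.path(out_dir, "annotation.gtf"))

    tfs <- sprintf("TF%02d", seq_len(cfg$n_tfs))
    cells <- sprintf("CL%d", seq_len(cfg$n_cell_lines))
    informative <- tfs[seq_len(cfg$n_informative_tfs)]

    ## True (latent) binding and heights shared across cell lines
    bound <- matrix(stats::runif(n_total * cfg$n_tfs) < cfg$p_bind,
                    n_total, cfg$n_tfs, dimnames = list(tx$transcript_id, tfs))
    logh <- matrix(stats::rnorm(n_total * cfg$n_tfs, cfg$height_meanlog,
                                cfg$height_sdlog),
                   n_total, cfg$n_tfs, dimnames = dimnames(bound))
    h_true <- ifelse(bound, exp(logh), 0)

    ## Latent functionality and hit labels for lncRNAs
    lnc_idx <- which(tx$biotype == "lncRNA")
    z <- scale(h_true[lnc_idx, informative, drop = FALSE])
    z[is.nan(z)] <- 0
    eta <- cfg$effect_size * rowSums(z) +
      stats::rnorm(length(lnc_idx), 0, cfg$noise_sd)
    intercept <- stats::uniroot(
      function(c0) mean(stats::plogis(eta - c0)) - cfg$hit_fraction,
      interval = c(-60, 60), tol = 1e-10)$root
    p_hit <- stats::plogis(eta - intercept)
    hit <- as.integer(stats::runif(length(lnc_idx)) < p_hit)

    ## Expression coupled to the planted signal (not to the labels directly)
    zbar_all <- stats::setNames(numeric(n_total), tx$transcript_id)
    zbar_all[lnc_idx] <- rowMeans(z)
    expr_base <- stats::rnorm(n_total, 0, cfg$expr_sd) +
      cfg$expr_coupling * zbar_all
    expr <- vapply(cells, function(cl)
      expr_base + stats::rnorm(n_total, 0, cfg$expr_jitter_sd),
      numeric(n_total))
    colnames(expr) <- paste0("log2_fpkm_", cells)

    ## Promoter-anchored peaks per (TF, cell line), plus background peaks
    win <- promoter_window(tx$tss, tx$strand, cfg$chrom_length)
    for (j in seq_along(tfs)) {
      for (cl in cells) {
        bi <- which(bound[, j])
        s <- pmax(0, win$start[bi] - sample(0:100, length(bi), replace = TRUE))
        e <- pmin(cfg$chrom_length, win$end[bi] + sample(0:100, length(bi), replace = TRUE))
        sig <- exp(logh[bi, j] + stats::rnorm(length(bi), 0, cfg$height_jitter_sdlog))
        chrom <- tx$chrom[bi]
        nb <- cfg$n_background_peaks
        if (nb > 0) {
          bw <- sample(150:400, nb, replace = TRUE)
          bs <- floor(stats::runif(nb) * (cfg$chrom_length - max(bw)))
          chrom <- c(chrom, sprintf("chr%d", sample(cfg$n_chroms, nb, replace = TRUE)))
          s <- c(s, bs); e <- c(e, bs + bw)
          sig <- c(sig, exp(stats::rnorm(nb, cfg$height_meanlog, cfg$height_sdlog)))
        }
        o <- order(chrom, s)
        lines <- sprintf("%s\t%d\t%d\tpk%d\t0\t.\t%.4f\t-1\t-1\t%d",
                         chrom[o], s[o], e[o], seq_along(o), sig[o],
                         floor((e[o] - s[o]) / 2))
        writeLines(lines, file.path(out_dir, "peaks",
                                    sprintf("%s.%s.narrowPeak", tfs[j], cl)))
      }
    }

    ## Enhancers
    ew <- sample(500:2000, cfg$n_enhancers, replace = TRUE)
    es <- floor(stats::runif(cfg$n_enhancers) * (cfg$chrom_length - max(ew)))
    ec <- sprintf("chr%d", sample(cfg$n_chroms, cfg$n_enhancers, replace = TRUE))
    o <- order(ec, es)
    writeLines(sprintf("%s\t%d\t%d\tenh%d\t0\t.", ec[o], es[o], es[o] + ew[o],
                       seq_len(cfg$n_enhancers)),
               file.path(out_dir, "enhancers.bed"))

    ## Expression and labels tables
    writeLines(c(paste(c("transcript_id", colnames(expr)), collapse = "\t"),
                 vapply(seq_len(n_total), function(i)
                   paste(c(tx$transcript_id[i], sprintf("%.6f", expr[i, ])),
                         collapse = "\t"), character(1))),
               file.path(out_dir, "expression.tsv"))
    writeLines(c("transcript_id\thit",
                 sprintf("%s\t%d", tx$transcript_id[lnc_idx], hit)),
               file.path(out_dir, "labels.tsv"))

    truth <- list(
      informative_tfs = informative,
      informative_feature_columns = as.vector(
        t(outer(informative, cells, function(a, b) paste0("tf_", a, ".", b)))),
      cell_lines = cells, tf_names = tfs,
      hit_ids = tx$transcript_id[lnc_idx][hit == 1],
      n_lnc = cfg$n_lnc, n_pcg = cfg$n_pcg,
      hit_fraction_config = cfg$hit_fraction,
      n_hits = sum(hit),
      hit_fraction_realized = mean(hit),
      effect_size = cfg$effect_size, noise_sd = cfg$noise_sd,
      intercept = intercept, seed = cfg$seed,
      eta = stats::setNames(as.list(round(eta, 8)),
                            tx$transcript_id[lnc_idx]))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(out_dir)
}

#' Planted-structure summary of a synthetic bundle
#'
#' Reads the bundle's truth JSON and cross-checks it against the written
#' label file (the reported hit fraction must equal the file's fraction
#' exactly).
#'
#' @param out_dir Bundle directory.
#' @return Named list: informative feature names, hit ids, latent
#'   parameters, realized hit fraction.
#' @export
truth_report <- function(out_dir) {
  tf <- file.path(out_dir, "truth.json")
  if (!file.exists(tf)) stop_io("truth file not found: %s", tf)
  truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  labels <- read_labels(file.path(out_dir, "labels.tsv"))
  ## recompute from integer counts so the identity with the labels file is
  ## exact, immune to JSON float round-tripping
  truth$hit_fraction_realized <- truth$n_hits / truth$n_lnc
  if (!identical(truth$hit_fraction_realized, mean(labels$hit)))
    stop_validation("truth.json hit fraction disagrees with labels.tsv")
  truth
}
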