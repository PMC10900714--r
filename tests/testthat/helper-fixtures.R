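# Shared fixtures and independent oracles. Fixtures are generated in code at
# test time; the desk-scale bundle is memoized because several files use it.

small_synth_config <- function(seed = 0, ...) {
  synthetic_config(n_lnc = 150, n_pcg = 60, n_tfs = 6, n_cell_lines = 2,
                   n_chroms = 2, chrom_length = 1e6, hit_fraction = 0.15,
                   n_informative_tfs = 3, n_background_peaks = 5,
                   n_enhancers = 30, seed = seed, ...)
}

make_bundle <- function(cfg = small_synth_config()) {
  d <- tempfile("bundle")
  generate_dataset(cfg, d)
  d
}

.fixtures <- new.env(parent = emptyenv())

shared_small_fixture <- function() {
  if (is.null(.fixtures$dir)) {
    .fixtures$dir <- make_bundle()
    .fixtures$matrix <- featurize_bundle(.fixtures$dir)
    .fixtures$labels <- read_labels(file.path(.fixtures$dir, "labels.tsv"))
    .fixtures$truth <- truth_report(.fixtures$dir)
  }
  .fixtures
}

shared_small_model <- function() {
  if (is.null(.fixtures$model)) {
    fx <- shared_small_fixture()
    .fixtures$model <- lncboost(fx$matrix, fx$labels,
                                boost_config(n_trees = 50))
  }
  .fixtures$model
}

# Two well-separated Gaussian clouds in two features: a linearly separable
# toy classification problem.
separable_toy <- function(n = 200, seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(f1 = stats::rnorm(n, mean = 6 * y), f2 = stats::rnorm(n))
  rownames(x) <- sprintf("T%03d", seq_len(n))
  list(x = x, y = y)
}

# --- Independent oracles -------------------------------------------------

# Per-base counting oracle for interval overlap (integer coordinates).
overlap_fraction_bruteforce <- function(as, ae, bs, be) {
  a_bases <- seq.int(as, ae - 1L)
  sum(a_bases >= bs & a_bases < be) / length(a_bases)
}

# Exhaustive pairwise-comparison oracle for AUROC (half credit for ties).
auroc_bruteforce <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# Threshold-enumeration oracle for step-integrated AUPRC: recount precision
# and recall from scratch at every distinct score.
auprc_bruteforce <- function(y, p) {
  ths <- sort(unique(p), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in ths) {
    yhat <- p >= t
    tp <- sum(yhat & y == 1)
    prec <- tp / sum(yhat)
    rec <- tp / sum(y == 1)
    area <- area + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  area
}

dir_bytes <- function(d) {
  files <- sort(list.files(d, recursive = TRUE))
  lapply(file.path(d, files), function(f) readBin(f, "raw", file.size(f)))
}
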