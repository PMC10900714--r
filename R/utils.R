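#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Condition helpers: validation errors (bad arguments / malformed content)
## and I/O errors (missing or unreadable files) carry distinct classes so the
## command-line front-end can map them to exit codes 1 and 2.
stop_validation <- function(msg, ...) {
  stop(structure(
    class = c("lncboost_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_io <- function(msg, ...) {
  stop(structure(
    class = c("lncboost_io_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_file_exists <- function(path, what = "input file") {
  if (!is.character(path) || length(path) != 1L || is.na(path))
    stop_validation("%s path must be a single string", what)
  if (!file.exists(path))
    stop_io("%s not found: %s", what, path)
  invisible(path)
}

## Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
## caller's RNG afterwards so library functions never perturb user randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic numeric formatting for TSV output: plain decimal notation,
## up to 10 significant digits, no trailing-zero drift across platforms.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    sub("0+$", "", sprintf("%.10f", v))
  }, character(1))
  out
}
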