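# Internal helpers shared across modules.

# Conditional progress/log messages; silenced via options(mircascade.verbose = FALSE).
mc_msg <- function(...) {
  if (isTRUE(getOption("mircascade.verbose", TRUE))) message(...)
  invisible(NULL)
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state afterwards.
# Used so generators are pure functions of their config and never perturb the
# session RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic fan-out of one global seed into per-generator substreams.
# Kept below 2^31 - 1 so the result is always a valid R integer seed.
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 1103L + stream * 7919L + 17L) %% 2147483647)
}

stop_mc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == floor(x)

# Numeric matrix sanity check used by the count/RPM table contracts.
check_table_matrix <- function(m, what = "table", integral = FALSE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop_mc("%s must be a numeric matrix (miRNAs x samples)", what)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_mc("%s must carry miRNA row names and sample column names", what)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop_mc("%s has duplicated row or column names", what)
  if (any(!is.finite(m)) || any(m < 0))
    stop_mc("%s must be finite and non-negative", what)
  if (integral && any(m != floor(m)))
    stop_mc("%s must contain integral counts", what)
  invisible(m)
}
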