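# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so no global state leaks.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Coerce an ECGRecord or numeric vector to samples; used so low-level signal
# operations accept either.
asSamples <- function(x) {
  if (is(x, "ECGRecord")) x@samples else as.numeric(x)
}

# Rebuild a record with new samples, preserving metadata.
replaceSamples <- function(record, samples, note = NULL) {
  stopifnot(is(record, "ECGRecord"))
  meta <- record@meta
  if (!is.null(note)) meta$processing <- c(meta$processing, note)
  new("ECGRecord", samples = as.numeric(samples), fs = record@fs,
      channelId = record@channelId, t0 = record@t0, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
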