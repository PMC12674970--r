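# Shared internal helpers.

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stage label, kept below 2^31.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000000L) * 1000L + (h %% 1000L)
}

# Encode / decode integer sets stored in a single CSV field.
encode_int_set <- function(x) {
  vapply(x, function(v) paste(sort(unique(as.integer(v))), collapse = ";"), character(1))
}

decode_int_set <- function(s) {
  lapply(s, function(v) {
    if (is.na(v) || !nzchar(v)) integer(0) else as.integer(strsplit(v, ";", fixed = TRUE)[[1]])
  })
}

# ICU day index for an hour offset: day 1 covers [0, 24), day 2 covers [24, 48), ...
hour_to_day <- function(t_hours) {
  as.integer(floor(t_hours / 24)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
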