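# Internal helpers shared across modules.

TIME_FMT <- "%Y-%m-%dT%H:%M:%S"

# Parse ISO 8601 "YYYY-MM-DDTHH:MM:SS" as naive local clock time. All
# analyses work on the local diel cycle, so timestamps carry no timezone;
# UTC is used internally purely to avoid DST arithmetic.
parse_timestamp <- function(x) {
  as.POSIXct(as.character(x), format = TIME_FMT, tz = "UTC")
}

format_timestamp <- function(x) {
  format(x, TIME_FMT, tz = "UTC")
}

parse_date <- function(x) {
  as.Date(as.character(x), format = "%Y-%m-%d")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Used wherever per-unit reproducibility must
# not depend on evaluation order (e.g. control sampling keyed by stratum).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash of a character key, mixed with a base seed.
# Gives each stratum / chain / replicate its own reproducible substream.
seed_from_key <- function(seed, key) {
  bytes <- utf8ToInt(paste0(key))
  h <- as.double(seed %% 2147483647L)
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Numerically stable log(1 + exp(x)).
log1pexp <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

stop_fearscape <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "fearscape_error")))
}
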