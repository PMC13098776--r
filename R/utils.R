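# Internal helpers: time arithmetic and derived random seeds.

# Convert POSIXct (or numeric hours) to numeric hours. POSIXct is measured
# from the epoch; numeric input is passed through. All internal duration
# arithmetic is done in fractional hours at minute resolution.
.as_hours <- function(x) {
  if (inherits(x, "POSIXct")) as.numeric(x) / 3600 else as.numeric(x)
}

.hours_between <- function(later, earlier) {
  .as_hours(later) - .as_hours(earlier)
}

.parse_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

.fmt_time <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

# Deterministic per-id seed stream: hashing (id, purpose) keeps one
# admission's draws stable when unrelated admissions are added or removed.
.derive_seed <- function(seed, id, purpose = "") {
  key <- paste(id, purpose, sep = "|")
  vapply(key, function(k) {
    h <- 0
    for (ch in utf8ToInt(k)) h <- (h * 31 + ch) %% 2147483647
    as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
  }, integer(1), USE.NAMES = FALSE)
}

# Run expr with a local RNG state so callers' streams are untouched.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    .stopf("%s is missing required column(s): %s", what,
           paste(miss, collapse = ", "))
  invisible(df)
}
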