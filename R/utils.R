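# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards. Keeps the package free of silent global
# side effects on .Random.seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based seed fan-out: stage i of a run with master seed s always
# receives the same substream seed, independent of other stages. Arithmetic
# stays exact in doubles (< 2^53) and the result fits a 32-bit integer.
derive_seed <- function(master, index) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 48271 + as.numeric(index) * 1009) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, len = NULL) {
  if (!is.numeric(x) || anyNA(x)) stop_field(field, "must be numeric without NA")
  if (!is.null(len) && length(x) != len) {
    stop_field(field, sprintf("must have length %d", len))
  }
  if (any(x < 0 | x > 1)) stop_field(field, "must lie in [0, 1]")
  invisible(x)
}

check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop_field(field, "must be a positive integer")
  }
  as.integer(x)
}

# Round half away from zero, the convention used in printed clinical tables
# (base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

pct <- function(num, denom, digits = 2) round_half_up(100 * num / denom, digits)
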