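# Internal helpers shared across modules.

# Disjoint generative categories: Missed, Prior-Visible and Prior-Invisible
# are the three visibility grades of a prior mammogram taken two years before
# a cancer-detecting screen; together they constitute "Prior-1". Prior-2 and
# Prior-3 are priors from four and six years before; Prior-3 is too rare to
# form its own model and only ever appears inside "All".
BASE_CATEGORIES <- c("Normal", "Cancer", "Missed", "Prior-Visible",
                     "Prior-Invisible", "Prior-2", "Prior-3")

# The eight per-category classification datasets.
MODEL_CATEGORIES <- c("All", "Normal", "Cancer", "Prior-1", "Prior-2",
                      "Missed", "Prior-Visible", "Prior-Invisible")

PRIOR1_MEMBERS <- c("Missed", "Prior-Visible", "Prior-Invisible")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bad <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min) {
    stop_bad(name, " must be a single finite number >= ", min)
  }
  invisible(x)
}

# x * log(x) with the 0 log 0 = 0 convention, in a configurable base.
xlogx <- function(x, base = exp(1)) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log(x[pos], base = base)
  out
}

# Stable seed derivation for stage-level reproducibility: offsets keep every
# derived seed a valid 32-bit integer.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}
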