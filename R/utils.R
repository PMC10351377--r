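#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats rnorm runif rbinom rexp rgamma median predict
#'   pchisq coef quantile approx sd cor
#' @importFrom utils head
#' @importFrom Rcpp evalCpp
#' @useDynLib mirimmune, .registration = TRUE
NULL

# Deterministic per-stage sub-stream seed, derived from the global seed and a
# stage name so that stages can be regenerated independently.  Kept below
# 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != floor(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %s", field, min),
          class = "mirimmune_validation_error")
  }
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", field, lo, hi),
          class = "mirimmune_validation_error")
  }
  as.numeric(x)
}
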