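#' @useDynLib mrfepi, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rpois runif setNames
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All seeded operations in the package go
# through this so that global RNG state is never disturbed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-stage seed from a global seed and a stage label, keeping the
# result in the 31-bit positive-integer range R's set.seed() accepts.
derive_seed <- function(seed, label) {
  bytes <- utf8ToInt(label)
  h <- as.double(seed %% .Machine$integer.max)
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1)
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}
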