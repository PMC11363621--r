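# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a locally-set RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG untouched (draws from the ambient stream).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

vec3 <- function(x, what = "point") {
  x <- as.numeric(x)
  if (length(x) != 3 || any(!is.finite(x))) {
    stop(what, " must be a finite numeric vector of length 3", call. = FALSE)
  }
  x
}

unit3 <- function(x, what = "direction") {
  x <- vec3(x, what)
  n <- sqrt(sum(x^2))
  if (n < 1e-12) stop(what, " has (near-)zero norm", call. = FALSE)
  x / n
}

norm3 <- function(x) sqrt(sum(x^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Deterministic subsample of n indices down to at most k (even stride).
stride_sample <- function(n, k) {
  if (n <= k) return(seq_len(n))
  unique(round(seq(1, n, length.out = k)))
}
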