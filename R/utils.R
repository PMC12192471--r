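# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# DC-centred frequency axis (1/mm) for an n-sample axis with spacing `delta` mm.
# Even n yields -n/2 .. n/2 - 1 bins; bin spacing is 1/(n * delta).
freq_axis <- function(n, delta) {
  df <- 1 / (n * delta)
  (seq_len(n) - 1 - floor(n / 2)) * df
}

# fftshift for matrices: move the DC bin to (floor(n/2)+1, floor(m/2)+1).
fftshift2 <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  i <- c(seq(floor(n / 2) + 1, n), seq_len(floor(n / 2)))
  j <- c(seq(floor(m / 2) + 1, m), seq_len(floor(m / 2)))
  x[i, j, drop = FALSE]
}

ifftshift2 <- function(x) {
  n <- nrow(x)
  m <- ncol(x)
  i <- c(seq(n - floor(n / 2) + 1, n), seq_len(n - floor(n / 2)))
  j <- c(seq(m - floor(m / 2) + 1, m), seq_len(m - floor(m / 2)))
  x[i, j, drop = FALSE]
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
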