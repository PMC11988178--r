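# RNG plumbing: a single master seed, per-stage streams derived
# deterministically from it so that chunked and unchunked runs are
# reproducible and independent stages never share a stream.

derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- rlang::hash(key)
  # fold the first 8 hex digits into [0, 2^31 - 2]
  as.integer(
    (strtoi(substr(h, 1, 7), base = 16L) * 16 +
      strtoi(substr(h, 8, 8), base = 16L)) %% 2147483646
  )
}

with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

unit_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  m / n
}

# orthonormal transverse basis for a unit axis vector
transverse_basis <- function(axis) {
  axis <- axis / sqrt(sum(axis^2))
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- ref - sum(ref * axis) * axis
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(
    axis[2] * t1[3] - axis[3] * t1[2],
    axis[3] * t1[1] - axis[1] * t1[3],
    axis[1] * t1[2] - axis[2] * t1[1]
  )
  list(axis = axis, t1 = t1, t2 = t2)
}
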