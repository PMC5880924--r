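# internal helpers shared across modules

# lower-triangle vector of a square matrix, column-major (matches dist order)
lowerTri <- function(m) m[lower.tri(m)]

# site-pair index table for n sites: one row per unordered pair, i < j,
# ordered to match lower.tri() vectorization (column-major)
pairIndex <- function(n) {
  small <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  large <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  data.frame(i = small, j = large)
}

stopIfNot01 <- function(m, what = "matrix") {
  bad <- !(m %in% c(0, 1))
  if (any(bad))
    stop(sprintf("%s contains non-binary value(s): %s", what,
                 paste(utils::head(unique(m[bad]), 3), collapse = ", ")),
         call. = FALSE)
  invisible(m)
}

# deterministic seed handling: run expr with a local RNG seeded from `seed`;
# NULL seed uses (and advances) the caller's RNG stream
withSeed <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

#' Build a symmetric matrix from a lower-triangle vector
#'
#' Expands a per-pair vector in the order of [pairwiseBeta()] /
#' [pairIndex()] (column-major lower triangle) into a full symmetric matrix
#' with zero diagonal — the form [mantelTest()] and [mrm()] expect.
#'
#' @param v numeric vector of length n(n-1)/2.
#' @param labels site labels (length n).
#' @return n x n symmetric matrix.
#' @export
symmetricFromLower <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m + t(m)
}
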