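#' @keywords internal
"_PACKAGE"

## Centered, unitary 2D FFT helpers. With these conventions the pixel at
## 1-based index n/2 + 1 along each (even-length) dimension is the origin,
## both in image space and in k-space.

fftshift2 <- function(x) {
  d <- dim(x)
  x[c((d[1L] / 2 + 1):d[1L], 1:(d[1L] / 2)),
    c((d[2L] / 2 + 1):d[2L], 1:(d[2L] / 2)), drop = FALSE]
}

#' Centered unitary 2D discrete Fourier transform
#'
#' Computes the orthonormal 2D DFT with the zero-frequency sample at the
#' array centre (1-based index `n/2 + 1` in each dimension). `cifft2()` is
#' both the inverse and the adjoint. Only even side lengths are supported,
#' for which the centering shifts are involutions.
#'
#' @param x complex (or real) matrix with even dimensions.
#' @return complex matrix of the same dimensions.
#' @export
cfft2 <- function(x) {
  stopifnot(is.matrix(x), all(dim(x) %% 2 == 0))
  fftshift2(stats::fft(fftshift2(x))) / sqrt(length(x))
}

#' @rdname cfft2
#' @export
cifft2 <- function(x) {
  stopifnot(is.matrix(x), all(dim(x) %% 2 == 0))
  fftshift2(stats::fft(fftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

## Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Inner products used by the adjoint tests: real inner product of the
## real-vector-space embedding of complex arrays.
re_inner <- function(a, b) {
  sum(Re(Conj(as.vector(a)) * as.vector(b)))
}

## l2 norm over any numeric/complex structure (lists of blocks allowed)
block_norm <- function(x) {
  if (is.list(x)) sqrt(sum(vapply(x, function(b) sum(abs(b)^2), numeric(1))))
  else sqrt(sum(abs(x)^2))
}

block_axpy <- function(a, x, y) {
  ## a * x + y elementwise over matching (possibly nested) list structures
  if (is.list(x)) {
    out <- mapply(function(xi, yi) block_axpy(a, xi, yi), x, y, SIMPLIFY = FALSE)
    names(out) <- names(x)
    out
  } else a * x + y
}

block_scale <- function(a, x) {
  if (is.list(x)) lapply(x, function(xi) block_scale(a, xi)) else a * x
}
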