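## Non-uniform FFT (type 2: image -> off-grid k-space samples) by
## Kaiser-Bessel gridding: apodization correction in image space, zero-pad
## to a 2x oversampled grid, FFT, then sparse interpolation with a width-4
## Kaiser-Bessel kernel. The adjoint is the exact transpose of this chain.
## Conventions: image pixel coordinates are centered integers
## (x = index - n/2, 0-based), trajectories are in cycles/pixel in
## [-0.5, 0.5), and the forward transform matches the unitary direct sum
##   m(v) = (1/n) * sum_x img(x) exp(-2i*pi*(vx*x + vy*y)).

kb_kernel <- function(u, J, beta) {
  t <- 1 - (2 * u / J)^2
  w <- numeric(length(u))
  ok <- t > 0
  w[ok] <- besselI(beta * sqrt(t[ok]), 0) / besselI(beta, 0)
  w
}

kb_fourier <- function(f, J, beta) {
  ## continuous Fourier transform of the width-J Kaiser-Bessel kernel,
  ## evaluated at frequency f (cycles per oversampled-grid sample)
  z2 <- beta^2 - (pi * J * f)^2
  out <- numeric(length(f))
  pos <- z2 > 0
  out[pos] <- sinh(sqrt(z2[pos])) / sqrt(z2[pos])
  out[!pos] <- sinc_safe(sqrt(-z2[!pos]))
  out * J / besselI(beta, 0)
}

sinc_safe <- function(z) ifelse(abs(z) < 1e-8, 1, sin(z) / z)

#' Build a NUFFT plan
#'
#' Precomputes the sparse Kaiser-Bessel interpolation matrix and the image
#' apodization for a fixed trajectory. Kernel parameters follow the min-max
#' Kaiser-Bessel design: neighbourhood size 4 and grid oversampling factor 2,
#' with the Beatty shape parameter.
#'
#' @param traj numeric matrix `M x 2` of k-space coordinates `(kx, ky)` in
#'   cycles/pixel within `[-0.5, 0.5)`; `kx` is conjugate to the column
#'   coordinate and `ky` to the row coordinate of the image.
#' @param n image side in pixels (even).
#' @param J interpolation neighbourhood size (samples per dimension).
#' @param osf grid oversampling factor.
#' @return an object of class `nufft_plan`.
#' @export
nufft_plan <- function(traj, n, J = 4L, osf = 2) {
  stopifnot(is.matrix(traj), ncol(traj) == 2L, n %% 2 == 0,
            all(abs(traj) <= 0.5))
  K <- as.integer(osf * n)
  beta <- pi * sqrt((J / osf)^2 * (osf - 0.5)^2 - 0.8)
  M <- nrow(traj)

  ## sparse interpolation matrix: rows = samples, cols = oversampled grid
  half <- J %/% 2L
  offs <- (-half + 1L):half
  build_1d <- function(t) {
    ## t: centered grid coordinate (traj * K); returns J x M indices/weights
    base <- floor(t)
    gs <- outer(offs, base, `+`)                      # J x M centered indices
    w <- kb_kernel(sweep(gs, 2L, t, `-`), J, beta)
    idx <- ((gs + K %/% 2L) %% K) + 1L                # wrap, 1-based
    list(idx = idx, w = matrix(w, nrow = J))
  }
  cx <- build_1d(traj[, 1L] * K)   # columns
  ry <- build_1d(traj[, 2L] * K)   # rows

  rows <- rep(seq_len(M), each = J * J)
  ridx <- ry$idx[rep(seq_len(J), times = J), ]        # row index varies fast
  cidx <- cx$idx[rep(seq_len(J), each = J), ]
  wgt <- ry$w[rep(seq_len(J), times = J), ] * cx$w[rep(seq_len(J), each = J), ]
  P <- Matrix::sparseMatrix(i = rows,
                            j = as.integer(ridx + (cidx - 1L) * K),
                            x = as.numeric(wgt), dims = c(M, K * K))

  x <- (0:(n - 1)) - n / 2
  ap <- kb_fourier(x / K, J, beta)
  apod <- outer(ap, ap)                                # rows x cols

  ## Fold the centering fftshifts into the chain: for even K,
  ## fftshift(fft(fftshift(x))) = CB * fft(CB * x) with the checkerboard
  ## CB[i, j] = (-1)^(i + j) (0-based). The input-side CB is absorbed into
  ## the apodization block, the output-side CB into the columns of P, so
  ## each transform is a plain fft plus one sparse product.
  cb1 <- rep_len(c(1, -1), K)
  P <- P %*% Matrix::Diagonal(x = as.vector(outer(cb1, cb1)))
  blk <- cb1[(K - n) %/% 2 + seq_len(n)]
  apod_cb <- outer(blk, blk) / apod

  dens <- sqrt(traj[, 1L]^2 + traj[, 2L]^2)
  if (any(dens == 0)) dens[dens == 0] <- min(dens[dens > 0], 0.5) / 2

  structure(list(n = as.integer(n), K = K, J = as.integer(J), beta = beta,
                 M = M, P = P, Pt = Matrix::t(P), apod = apod,
                 apod_cb = apod_cb, traj = traj, dcomp = dens),
            class = "nufft_plan")
}

sparse_cmult <- function(P, v) {
  ## one sparse product for both components; the dense result stores its
  ## two columns (real, imaginary) contiguously in @x
  ri <- (P %*% cbind(Re(v), Im(v)))@x
  M <- length(ri) %/% 2L
  complex(real = ri[seq_len(M)], imaginary = ri[M + seq_len(M)])
}

#' Apply a NUFFT plan
#'
#' `nufft_forward()` maps an `n x n` complex image to `M` off-grid k-space
#' samples; `nufft_adjoint()` is its exact adjoint.
#'
#' @param plan a [nufft_plan()].
#' @param img complex (or real) `n x n` matrix.
#' @return complex vector of length `M`.
#' @export
nufft_forward <- function(plan, img) {
  n <- plan$n; K <- plan$K
  pad <- matrix(0i, K, K)
  idx <- (K - n) %/% 2 + seq_len(n)
  pad[idx, idx] <- img * plan$apod_cb
  sparse_cmult(plan$P, as.vector(stats::fft(pad))) / n
}

#' @rdname nufft_forward
#' @param y complex vector of `M` k-space samples.
#' @export
nufft_adjoint <- function(plan, y) {
  n <- plan$n; K <- plan$K
  g <- matrix(sparse_cmult(plan$Pt, y), K, K)
  full <- stats::fft(g, inverse = TRUE)
  idx <- (K - n) %/% 2 + seq_len(n)
  (full[idx, idx] * plan$apod_cb) / n
}

#' Direct non-uniform discrete Fourier sum
#'
#' Brute-force evaluation of the type-2 transform; the reference the NUFFT
#' approximates. Quadratic cost, for validation on small grids only.
#' @inheritParams nufft_forward
#' @param traj `M x 2` trajectory in cycles/pixel.
#' @export
ndft_direct <- function(img, traj) {
  n <- nrow(img)
  xc <- (0:(n - 1)) - n / 2
  out <- complex(nrow(traj))
  for (i in seq_len(nrow(traj))) {
    ph <- outer(exp(-2i * pi * traj[i, 2L] * xc),
                exp(-2i * pi * traj[i, 1L] * xc))
    out[i] <- sum(img * ph) / n
  }
  out
}
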