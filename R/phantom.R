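#' Phantom specification
#'
#' Describes the numerical relaxometry phantom: a Shepp-Logan head phantom
#' of side `base_size` pixels, zero-filled (centred) into a
#' `matrix_size` x `matrix_size` grid, with per-ellipse T1rho values spread
#' over `t1rho_range` and a linear phase ramp along the horizontal (column)
#' direction.
#'
#' @param matrix_size integer, side of the padded image grid (pixels, even).
#' @param base_size integer, side of the unpadded phantom (pixels,
#'   `<= matrix_size`).
#' @param t1rho_range length-2 numeric, increasing positive T1rho range (ms).
#' @param s0_max peak baseline signal intensity (arbitrary units, > 0 for a
#'   usable phantom; 0 is accepted and yields an all-zero S0 map).
#' @param phase_slope phase ramp in radians per pixel column; default
#'   `2 * pi / matrix_size`.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = 192L, base_size = 128L,
                         t1rho_range = c(20, 120), s0_max = 1,
                         phase_slope = 2 * pi / matrix_size) {
  matrix_size <- as.integer(matrix_size)
  base_size <- as.integer(base_size)
  stopifnot(matrix_size >= 2L, matrix_size %% 2L == 0L,
            base_size >= 2L, base_size <= matrix_size,
            length(t1rho_range) == 2L, all(t1rho_range > 0),
            t1rho_range[2L] > t1rho_range[1L], s0_max >= 0,
            is.finite(phase_slope))
  structure(list(matrix_size = matrix_size, base_size = base_size,
                 t1rho_range = as.numeric(t1rho_range),
                 s0_max = as.numeric(s0_max),
                 phase_slope = as.numeric(phase_slope)),
            class = "phantom_spec")
}

#' Parameter maps container
#'
#' Bundles the three real-valued maps estimated by the embedded model: the
#' baseline signal `s0` (>= 0), the rotating-frame relaxation time `t1rho`
#' in ms (> 0), and the image `phase` in radians. All three must share one
#' matrix shape.
#'
#' @param s0,t1rho,phase numeric matrices of identical dimensions.
#' @return an object of class `parameter_maps`.
#' @export
parameter_maps <- function(s0, t1rho, phase) {
  stopifnot(is.matrix(s0), identical(dim(s0), dim(t1rho)),
            identical(dim(s0), dim(phase)),
            all(is.finite(s0)), all(is.finite(t1rho)), all(is.finite(phase)),
            all(s0 >= 0), all(t1rho > 0))
  structure(list(s0 = s0, t1rho = t1rho, phase = phase),
            class = "parameter_maps")
}

## Modified (Toft) Shepp-Logan ellipse table: additive intensity, semi-axes
## a, b, centre (x0, y0) and rotation phi (degrees) on the [-1, 1]^2 square.
shepp_logan_ellipses <- function() {
  data.frame(
    A   = c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1),
    a   = c(0.69, 0.6624, 0.11, 0.16, 0.21, 0.046, 0.046, 0.046, 0.023, 0.023),
    b   = c(0.92, 0.874, 0.31, 0.41, 0.25, 0.046, 0.046, 0.023, 0.023, 0.046),
    x0  = c(0, 0, 0.22, -0.22, 0, 0, 0, -0.08, 0, 0.06),
    y0  = c(0, -0.0184, 0, 0, 0.35, 0.1, -0.1, -0.605, -0.606, -0.605),
    phi = c(0, 0, -18, 18, 0, 0, 0, 0, 0, 0)
  )
}

#' Generate ground-truth phantom parameter maps
#'
#' Builds the S0, T1rho and phase maps of the simulation target. S0 is the
#' (modified) Shepp-Logan intensity phantom rescaled to peak `s0_max` and
#' zero-filled into the padded grid; T1rho is piecewise constant with a
#' distinct, evenly spaced value per ellipse across `t1rho_range`
#' (background pixels, where S0 = 0, carry the lower bound so the map stays
#' strictly positive); the phase is `phase_slope * x` with `x` the 0-based
#' column index of the full padded grid.
#'
#' @param spec a [phantom_spec()].
#' @return a [parameter_maps()] object of side `spec$matrix_size`.
#' @export
make_phantom_maps <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$base_size
  N <- spec$matrix_size
  ell <- shepp_logan_ellipses()

  ## pixel centres of the unpadded phantom on [-1, 1]^2; x along columns
  x <- ((0:(n - 1)) - (n - 1) / 2) / (n / 2)
  y <- -((0:(n - 1)) - (n - 1) / 2) / (n / 2)   # row 1 = top of the head
  X <- matrix(x, n, n, byrow = TRUE)
  Y <- matrix(y, n, n)

  s0 <- matrix(0, n, n)
  t1r <- matrix(spec$t1rho_range[1L], n, n)
  t1_values <- seq(spec$t1rho_range[1L], spec$t1rho_range[2L],
                   length.out = nrow(ell))
  for (j in seq_len(nrow(ell))) {
    phi <- ell$phi[j] * pi / 180
    xr <- (X - ell$x0[j]) * cos(phi) + (Y - ell$y0[j]) * sin(phi)
    yr <- -(X - ell$x0[j]) * sin(phi) + (Y - ell$y0[j]) * cos(phi)
    inside <- (xr / ell$a[j])^2 + (yr / ell$b[j])^2 <= 1
    s0[inside] <- s0[inside] + ell$A[j]
    t1r[inside] <- t1_values[j]            # later ellipses overwrite
  }
  s0 <- pmax(s0, 0)
  if (max(s0) > 0) s0 <- s0 * (spec$s0_max / max(s0)) else s0[] <- 0
  t1r[s0 == 0] <- spec$t1rho_range[1L]

  ## zero-fill into the padded grid, centred
  S0 <- matrix(0, N, N)
  T1 <- matrix(spec$t1rho_range[1L], N, N)
  off <- (N - n) %/% 2
  idx <- (off + 1):(off + n)
  S0[idx, idx] <- s0
  T1[idx, idx] <- t1r

  phase <- matrix(spec$phase_slope * (0:(N - 1)), N, N, byrow = TRUE)
  parameter_maps(s0 = S0, t1rho = T1, phase = phase)
}
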