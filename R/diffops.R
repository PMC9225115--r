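## Discrete difference operators used by the TV regularizers.
##
## Spatial gradients are forward differences with Neumann (replicate)
## boundary: the last difference in each direction is zero, so a constant
## image maps to zero and the adjoint is the negative divergence with the
## matching boundary rows.

#' Spatial forward-difference gradient
#'
#' @param m numeric or complex matrix.
#' @return array `dim(m) x 2`; slice 1 holds the x-differences (along
#'   columns), slice 2 the y-differences (along rows); Neumann boundary.
#' @export
spatial_grad <- function(m) {
  d <- dim(m)
  g <- array(if (is.complex(m)) 0i else 0, c(d, 2L))
  if (d[2L] > 1L) g[, -d[2L], 1L] <- m[, -1L] - m[, -d[2L]]
  if (d[1L] > 1L) g[-d[1L], , 2L] <- m[-1L, ] - m[-d[1L], ]
  g
}

#' Adjoint of [spatial_grad()]
#'
#' @param g array `nr x nc x 2` of difference fields.
#' @return matrix `nr x nc` with `re_inner(spatial_grad(m), g) ==
#'   re_inner(m, spatial_grad_adj(g))` for all `m`.
#' @export
spatial_grad_adj <- function(g) {
  d <- dim(g)
  nr <- d[1L]; nc <- d[2L]
  out <- matrix(if (is.complex(g)) 0i else 0, nr, nc)
  if (nc > 1L) {
    gx <- g[, , 1L, drop = TRUE]
    gx <- matrix(gx, nr, nc)
    gx[, nc] <- 0
    out[, 1L] <- out[, 1L] - gx[, 1L]
    if (nc > 2L) out[, 2:(nc - 1L)] <- out[, 2:(nc - 1L)] +
        gx[, 1:(nc - 2L)] - gx[, 2:(nc - 1L)]
    out[, nc] <- out[, nc] + gx[, nc - 1L]
  }
  if (nr > 1L) {
    gy <- matrix(g[, , 2L, drop = TRUE], nr, nc)
    gy[nr, ] <- 0
    out[1L, ] <- out[1L, ] - gy[1L, ]
    if (nr > 2L) out[2:(nr - 1L), ] <- out[2:(nr - 1L), ] +
        gy[1:(nr - 2L), ] - gy[2:(nr - 1L), ]
    out[nr, ] <- out[nr, ] + gy[nr - 1L, ]
  }
  out
}

#' First-order difference along the contrast dimension
#'
#' Forward differences `u[,,c+1] - u[,,c]` with a zero last slice (Neumann
#' boundary), applied to an `nr x nc x C` image series.
#' @param u 3D array (contrasts along the third dimension).
#' @return array of the same shape; slice `C` is zero.
#' @export
contrast_diff1 <- function(u) {
  d <- dim(u)
  out <- array(if (is.complex(u)) 0i else 0, d)
  C <- d[3L]
  if (C > 1L) out[, , -C] <- u[, , -1L, drop = FALSE] - u[, , -C, drop = FALSE]
  out
}

#' @rdname contrast_diff1
#' @param g difference array as produced by `contrast_diff1`.
#' @export
contrast_diff1_adj <- function(g) {
  d <- dim(g)
  C <- d[3L]
  out <- array(if (is.complex(g)) 0i else 0, d)
  if (C > 1L) {
    g[, , C] <- 0
    out[, , 1L] <- -g[, , 1L]
    if (C > 2L) out[, , 2:(C - 1L)] <- g[, , 1:(C - 2L), drop = FALSE] -
        g[, , 2:(C - 1L), drop = FALSE]
    out[, , C] <- g[, , C - 1L]
  }
  out
}

#' Second-order difference along the contrast dimension
#'
#' The interior stencil `u[,,c-1] - 2 u[,,c] + u[,,c+1]` for
#' `c = 2, ..., C-1`; no boundary rows are produced, so the output has
#' `C - 2` slices. Requires at least three contrasts.
#' @param u 3D array with `dim(u)[3] >= 3`.
#' @return array `nr x nc x (C-2)`.
#' @export
contrast_diff2 <- function(u) {
  d <- dim(u)
  C <- d[3L]
  if (C < 3L) stop("second-order contrast differences require at least 3 contrasts")
  u[, , 1:(C - 2L), drop = FALSE] - 2 * u[, , 2:(C - 1L), drop = FALSE] +
    u[, , 3:C, drop = FALSE]
}

#' @rdname contrast_diff2
#' @param g difference array with `C - 2` slices.
#' @param C number of contrasts of the primal series.
#' @export
contrast_diff2_adj <- function(g, C) {
  d <- dim(g)
  stopifnot(d[3L] == C - 2L)
  out <- array(if (is.complex(g)) 0i else 0, c(d[1L], d[2L], C))
  for (j in seq_len(C - 2L)) {
    out[, , j] <- out[, , j] + g[, , j]
    out[, , j + 1L] <- out[, , j + 1L] - 2 * g[, , j]
    out[, , j + 2L] <- out[, , j + 2L] + g[, , j]
  }
  out
}
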