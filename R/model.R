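## The non-linear signal model: parameter maps -> k-space.
##
## Decay map D:   r_c = S0 * exp(-TSL_c / T1rho)            (per contrast)
## Phase map B:   u_c = r_c * exp(i * theta)
## Encoding:      m_c = A_c u_c
## Composite:     K(S0, T1rho, theta) = A B(D(S0, T1rho, theta))

#' Mono-exponential decay images
#'
#' Applies the rotating-frame relaxation decay to the baseline map:
#' `r_c = s0 * exp(-tsl[c] / t1rho)` elementwise; the phase map is not
#' touched by this stage.
#'
#' @param maps a [parameter_maps()] object (requires `t1rho > 0`).
#' @param tsl spin-lock times in ms.
#' @return real array `n x n x C` of per-contrast magnitude images.
#' @export
decay_images <- function(maps, tsl) {
  stopifnot(inherits(maps, "parameter_maps"), all(maps$t1rho > 0))
  d <- dim(maps$s0)
  r <- array(0, c(d, length(tsl)))
  for (c in seq_along(tsl)) r[, , c] <- maps$s0 * exp(-tsl[c] / maps$t1rho)
  r
}

#' Embed magnitudes into complex images with a shared phase
#'
#' `u_c = r_c * exp(i * phase)`; the real part is `r_c * cos(phase)` and
#' the imaginary part `r_c * sin(phase)`.
#'
#' @param r real array `n x n x C` of magnitudes.
#' @param phase real `n x n` phase map (radians).
#' @return complex array `n x n x C`.
#' @export
phase_embed <- function(r, phase) {
  stopifnot(identical(dim(r)[1:2], dim(phase)))
  ph <- exp(1i * phase)
  out <- array(0i, dim(r))
  for (c in seq_len(dim(r)[3L])) out[, , c] <- r[, , c] * ph
  out
}

#' Non-linear forward model K
#'
#' Maps the parameter triple to the acquired k-space samples through decay,
#' phase embedding and the (normalized) Fourier encoding.
#'
#' @param maps a [parameter_maps()].
#' @param tsl spin-lock times (ms), one per contrast.
#' @param enc an [encoding_operator()] with matching size and contrast count.
#' @return list of complex sample vectors, one per contrast.
#' @export
forward_model <- function(maps, tsl, enc) {
  stopifnot(length(tsl) == enc$n_contrasts,
            identical(dim(maps$s0), c(enc$n, enc$n)))
  enc$forward(phase_embed(decay_images(maps, tsl), maps$phase))
}

## Directional derivative of B(D(.)) at `maps` in direction d = (ds0, dt1rho,
## dphase): complex per-contrast image perturbations.
model_jvp_images <- function(maps, tsl, d) {
  E <- decay_images(parameter_maps(maps$s0 * 0 + 1, maps$t1rho,
                                   maps$phase), tsl)    # exp(-tsl/T1rho)
  ph <- exp(1i * maps$phase)
  out <- array(0i, dim(E))
  for (c in seq_along(tsl)) {
    r <- maps$s0 * E[, , c]
    out[, , c] <- (d$s0 * E[, , c] +
                   d$t1rho * r * tsl[c] / (maps$t1rho^2) +
                   1i * d$phase * r) * ph
  }
  out
}

#' Apply the Jacobian of the forward model
#'
#' `jacobian_apply()` computes the directional derivative of `K` at `maps`
#' in the direction `d = list(s0, t1rho, phase)`; `jacobian_adjoint()`
#' applies the adjoint to a k-space dual vector, returning a direction in
#' parameter space. Together they provide the gradient machinery of the
#' non-linear solver.
#'
#' @param maps a [parameter_maps()] (linearization point, `t1rho > 0`).
#' @param tsl spin-lock times (ms).
#' @param enc an [encoding_operator()].
#' @param d list with real matrices `s0`, `t1rho`, `phase`.
#' @return `jacobian_apply`: list of complex sample vectors;
#'   `jacobian_adjoint`: list of three real matrices.
#' @export
jacobian_apply <- function(maps, tsl, enc, d) {
  enc$forward(model_jvp_images(maps, tsl, d))
}

#' @rdname jacobian_apply
#' @param y list of complex k-space dual vectors, one per contrast.
#' @export
jacobian_adjoint <- function(maps, tsl, enc, y) {
  w <- enc$adjoint(y)
  q <- array(0i, dim(w))
  phc <- exp(-1i * maps$phase)
  ds0 <- maps$s0 * 0
  dt1 <- ds0
  dth <- ds0
  for (c in seq_along(tsl)) {
    E <- exp(-tsl[c] / maps$t1rho)
    r <- maps$s0 * E
    qc <- w[, , c] * phc
    ds0 <- ds0 + E * Re(qc)
    dt1 <- dt1 + (r * tsl[c] / maps$t1rho^2) * Re(qc)
    dth <- dth + r * Im(qc)
  }
  list(s0 = ds0, t1rho = dt1, phase = dth)
}

#' Squared block sup-norms of the model Jacobian
#'
#' The per-block squared sup-norms of the Jacobian of the magnitude/phase
#' model (encoding excluded, as it is normalized to unit norm):
#' `L1^2 = sum_c max(exp(-tsl_c/t1rho))^2`,
#' `L2^2 = sum_c max(r_c * tsl_c / t1rho^2)^2`,
#' `L3^2 = sum_c max(s0 * exp(-tsl_c/t1rho))^2`,
#' with `r_c = s0 * exp(-tsl_c/t1rho)`. These drive the per-block primal
#' step sizes of the embedded solver.
#'
#' @param maps a [parameter_maps()] with `t1rho > 0`.
#' @param tsl spin-lock times (ms).
#' @return numeric vector `c(L1sq, L2sq, L3sq)`.
#' @export
compute_block_norms <- function(maps, tsl) {
  stopifnot(all(maps$t1rho > 0))
  L1 <- L2 <- L3 <- 0
  for (c in seq_along(tsl)) {
    E <- exp(-tsl[c] / maps$t1rho)
    r <- maps$s0 * E
    L1 <- L1 + max(E)^2
    L2 <- L2 + max(r * tsl[c] / maps$t1rho^2)^2
    L3 <- L3 + max(r)^2
  }
  c(L1sq = L1, L2sq = L2, L3sq = L3)
}
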