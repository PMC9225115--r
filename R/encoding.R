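#' Multi-contrast Fourier encoding operator
#'
#' Builds the block-diagonal encoding `A = diag(A_1, ..., A_C)` mapping a
#' complex image series to the acquired k-space samples. For cartesian
#' sampling each block is the centered unitary 2D DFT followed by row
#' selection; for radial sampling each block is a Kaiser-Bessel NUFFT along
#' that contrast's spokes. The whole operator is rescaled by its spectral
#' norm (power-iteration estimate) so that the returned operator has unit
#' norm.
#'
#' @param schedule a [golden_angle_schedule()] / [radial_subsample()] or
#'   [cartesian_schedule()] sampling schedule with per-contrast sample sets.
#' @param matrix_size image side in pixels (even).
#' @param n_contrasts number of contrasts; must match the schedule.
#' @return an object of class `encoding_operator` with fields
#'   `forward(u)` (complex `n x n x C` array -> list of complex sample
#'   vectors), `adjoint(y)` (the exact adjoint), `norm_factor` (the raw
#'   operator norm divided out), `M` (samples per contrast),
#'   `dual_weights` (per-sample density weights in (0, 1] used by the
#'   solvers as a diagonal dual preconditioner; identically 1 for
#'   cartesian schedules) and, for radial schedules, the per-contrast
#'   `plans` and trajectories.
#' @export
encoding_operator <- function(schedule, matrix_size, n_contrasts) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  n <- as.integer(matrix_size)
  C <- as.integer(n_contrasts)

  if (schedule$scheme == "radial") {
    stopifnot(length(schedule$spokes) == C)
    plans <- lapply(seq_len(C), function(c) {
      ang <- schedule$angles[schedule$spokes[[c]]]
      traj <- cbind(kx = as.vector(outer(schedule$radii, cos(ang))),
                    ky = as.vector(outer(schedule$radii, sin(ang))))
      nufft_plan(traj, n)
    })
    forward_raw <- function(u)
      lapply(seq_len(C), function(c) nufft_forward(plans[[c]], u[, , c]))
    adjoint_raw <- function(y) {
      out <- array(0i, c(n, n, C))
      for (c in seq_len(C)) out[, , c] <- nufft_adjoint(plans[[c]], y[[c]])
      out
    }
    M <- vapply(plans, function(p) p$M, integer(1))
    ## ramp (sample-density) dual weights: diagonal preconditioner for the
    ## data term compensating the centre-heavy radial sampling density;
    ## normalized to max 1 so it only ever shrinks a dual step
    wmax <- max(vapply(plans, function(p) max(p$dcomp), numeric(1)))
    dual_weights <- lapply(plans, function(p) p$dcomp / wmax)
  } else {
    stopifnot(length(schedule$rows) == C)
    rowidx <- lapply(schedule$rows, function(r) as.integer(r) + 1L)
    forward_raw <- function(u)
      lapply(seq_len(C), function(c) {
        F <- cfft2(u[, , c])
        as.vector(F[rowidx[[c]], , drop = FALSE])
      })
    adjoint_raw <- function(y) {
      out <- array(0i, c(n, n, C))
      for (c in seq_len(C)) {
        G <- matrix(0i, n, n)
        G[rowidx[[c]], ] <- matrix(y[[c]], length(rowidx[[c]]), n)
        out[, , c] <- cifft2(G)
      }
      out
    }
    plans <- NULL
    M <- vapply(rowidx, function(r) length(r) * n, integer(1))
    dual_weights <- lapply(M, function(k) rep(1, k))   # uniform density
  }

  ## Lanczos estimate of ||A_raw|| (top eigenvalue of A^H A)
  nrm <- with_seed(20231L,
    sqrt(lanczos_top_eig(function(x) adjoint_raw(forward_raw(x)),
                         c(n, n, C))))

  structure(list(scheme = schedule$scheme, n = n, n_contrasts = C, M = M,
                 norm_factor = nrm, plans = plans, schedule = schedule,
                 dual_weights = dual_weights,
                 forward = function(u) lapply(forward_raw(u), `/`, nrm),
                 adjoint = function(y) adjoint_raw(lapply(y, `/`, nrm)),
                 forward_raw = forward_raw, adjoint_raw = adjoint_raw),
            class = "encoding_operator")
}

## Lanczos iteration (with full reorthogonalization) for the top eigenvalue
## of a Hermitian PSD operator op acting on complex arrays of dim `dims`.
lanczos_top_eig <- function(op, dims, m = 40L, tol = 1e-10,
                            complex_start = TRUE) {
  ntot <- prod(dims)
  v <- if (complex_start)
    array(complex(real = stats::rnorm(ntot),
                  imaginary = stats::rnorm(ntot)), dims)
  else array(stats::rnorm(ntot), dims)
  v <- v / block_norm(v)
  V <- list(v)
  alpha <- beta <- numeric(0)
  lam_prev <- 0
  for (j in seq_len(m)) {
    w <- op(V[[j]])
    a <- re_inner(V[[j]], w)
    w <- w - a * V[[j]]
    if (j > 1L) w <- w - beta[j - 1L] * V[[j - 1L]]
    for (vi in V) w <- w - re_inner(vi, w) * vi   # reorthogonalize
    alpha <- c(alpha, a)
    b <- block_norm(w)
    Tm <- diag(alpha, nrow = j)
    if (j > 1L) for (i in seq_len(j - 1L))
      Tm[i, i + 1L] <- Tm[i + 1L, i] <- beta[i]
    lam <- max(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values)
    if (b < 1e-12 || abs(lam - lam_prev) < tol * max(lam, 1)) return(lam)
    lam_prev <- lam
    beta <- c(beta, b)
    V[[j + 1L]] <- w / b
  }
  lam
}

#' Power-iteration spectral-norm estimate of the (normalized) encoding
#'
#' @param enc an [encoding_operator()].
#' @param iters maximum Krylov dimension.
#' @param seed RNG seed for the start vector.
#' @return estimated operator norm of `enc$forward` (should be 1 within
#'   1e-3 after normalization).
#' @export
encoding_norm <- function(enc, iters = 40L, seed = 7L) {
  n <- enc$n; C <- enc$n_contrasts
  with_seed(seed,
    sqrt(lanczos_top_eig(function(x) enc$adjoint(enc$forward(x)),
                         c(n, n, C), m = iters)))
}
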