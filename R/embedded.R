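#' Configuration of the embedded reconstruction
#'
#' Tuning parameters of the direct parameter-map reconstruction: the
#' minimization of
#' `||K(S0,T1rho,theta) - m||^2 + alpha1 TV(S0) + alpha2 TV(T1rho)
#'  + alpha3 ||grad(theta)||^2` subject to `S0 >= a1`, `T1rho >= a2`.
#'
#' @param alpha1,alpha2 total-variation weights for the S0 and T1rho maps.
#' @param alpha3 squared-gradient (Tikhonov) weight for the phase map
#'   (0.01 for the radial study setting, 1e-4 for the cartesian one).
#' @param a1,a2 lower box bounds on S0 and T1rho (small positive).
#' @param tau2_multiplier extra factor on the T1rho primal step (50 in the
#'   radial simulation setting, 1 otherwise).
#' @param omega over-relaxation parameter of the primal extrapolation.
#' @param max_iters iteration cap.
#' @param rel_tol stopping tolerance on the relative primal change.
#' @param t1rho_init constant initial T1rho value (ms).
#' @param check_every interval (iterations) at which the step-size criterion
#'   is re-estimated and step sizes are refreshed.
#' @param step_scale dimensionless primal step scale `c` in
#'   `tau_i = c / L_i^2` (see [derive_steps()]).
#' @return an object of class `embedded_config`.
#' @export
embedded_config <- function(alpha1 = 1e-3, alpha2 = 1e-1, alpha3 = 0.01,
                            a1 = 1e-6, a2 = 1e-6, tau2_multiplier = 1,
                            omega = 1, max_iters = 10000L, rel_tol = 1e-6,
                            t1rho_init = 20, check_every = 100L,
                            step_scale = 0.45) {
  stopifnot(alpha1 >= 0, alpha2 >= 0, alpha3 >= 0, a1 > 0, a2 > 0,
            tau2_multiplier > 0, omega >= 0, max_iters >= 1, rel_tol > 0,
            t1rho_init > 0, step_scale > 0)
  structure(list(alpha1 = alpha1, alpha2 = alpha2, alpha3 = alpha3,
                 a1 = a1, a2 = a2, tau2_multiplier = tau2_multiplier,
                 omega = omega, max_iters = as.integer(max_iters),
                 rel_tol = rel_tol, t1rho_init = t1rho_init,
                 check_every = as.integer(check_every),
                 step_scale = step_scale),
            class = "embedded_config")
}

#' Initial iterate of the embedded solver
#'
#' S0 and the phase are initialized from the (for radial data,
#' ramp-density-compensated) adjoint reconstruction of the TSL = 0
#' contrast, rescaled by a least-squares fit of its forward projection to
#' the data; T1rho starts from the constant `t1rho_init` and the dual
#' variable from zero. A TSL = 0 contrast is required.
#'
#' @param data a `kspace_data` object.
#' @param enc the [encoding_operator()] used for reconstruction.
#' @param config an [embedded_config()].
#' @return list with `maps` (initial [parameter_maps()]) and `y` (zero dual
#'   blocks).
#' @export
initialize_embedded <- function(data, enc, config) {
  tsl <- data$protocol$tsl
  c0 <- which(tsl == 0)
  if (length(c0) == 0L)
    stop("embedded initialization requires a TSL = 0 contrast")
  c0 <- c0[1L]
  n <- enc$n
  m0 <- data$samples[[c0]]
  if (enc$scheme == "radial") {
    pl <- enc$plans[[c0]]
    z <- nufft_adjoint(pl, pl$dcomp * m0)
  } else {
    ridx <- as.integer(enc$schedule$rows[[c0]]) + 1L
    G <- matrix(0i, n, n)
    G[ridx, ] <- matrix(m0, length(ridx), n)
    z <- cifft2(G)
  }
  ## least-squares amplitude calibration of the adjoint image
  fz <- if (enc$scheme == "radial") nufft_forward(enc$plans[[c0]], z)
        else {
          Fz <- cfft2(z)
          as.vector(Fz[as.integer(enc$schedule$rows[[c0]]) + 1L, , drop = FALSE])
        }
  s <- re_inner(fz, m0) / sum(abs(fz)^2)
  z <- s * z

  maps <- parameter_maps(s0 = pmax(Mod(z), config$a1),
                         t1rho = matrix(config$t1rho_init, n, n),
                         phase = Arg(z))
  y <- list(data = lapply(enc$M, function(m) complex(m)),
            g1 = array(0, c(n, n, 2L)), g2 = array(0, c(n, n, 2L)),
            g3 = array(0, c(n, n, 2L)))
  list(maps = maps, y = y)
}

#' Per-block primal steps and dual step from the Jacobian block norms
#'
#' Diagonal preconditioning: each primal step is inversely proportional to
#' the squared sup-norm of its Jacobian block (encoding normalized to unit
#' norm), `tau_i = step_scale / L_i^2`, with the T1rho step additionally
#' multiplied by `tau2_multiplier`. The dual step starts at
#' `1 / max(tau_i)` and is subsequently reduced by the solver whenever the
#' convergence criterion `||sqrt(sigma) gradH sqrt(T)||^2 < 1` requires it,
#' so the product `tau_2 * sigma` stays well below one even with the
#' multiplier. When previous steps are supplied the new steps never exceed
#' them (monotone non-increasing).
#'
#' @param norms vector `c(L1sq, L2sq, L3sq)` from [compute_block_norms()].
#' @param config an [embedded_config()].
#' @param prev optional list with previous `tau` and `sigma`.
#' @return list with `tau` (length 3) and `sigma`.
#' @export
derive_steps <- function(norms, config, prev = NULL) {
  if (all(norms <= 0)) stop("all Jacobian block norms are zero")
  norms <- pmax(unname(norms), 1e-12 * max(norms))  # inactive block: tiny norm
  tau <- config$step_scale / norms
  tau[2L] <- config$tau2_multiplier * tau[2L]
  if (!is.null(prev)) tau <- pmin(tau, prev$tau)
  ## provisional dual steps, balanced against the primal metric: the data
  ## block against the Jacobian block products tau_i * L_i^2, each spatial
  ## TV block against its own operator (norm^2 <= 8); the solver rescales
  ## all of them together to meet the convergence criterion and keeps them
  ## non-increasing.
  sigma <- c(data = 1 / max(tau * norms),
             g1 = 1 / (8 * tau[1L]), g2 = 1 / (8 * tau[2L]),
             g3 = 1 / (8 * tau[3L]))
  if (!is.null(prev)) sigma <- pmin(sigma, prev$sigma)
  list(tau = unname(tau), sigma = sigma)
}

#' Projection onto the box constraints (resolvent of G)
#'
#' Clamps `S0` to `>= a1` and `T1rho` to `>= a2`; the phase is unchanged.
#' Idempotent.
#' @param maps a [parameter_maps()]-like list.
#' @param config an [embedded_config()].
#' @export
prox_primal <- function(maps, config) {
  parameter_maps(pmax(maps$s0, config$a1), pmax(maps$t1rho, config$a2),
                 maps$phase)
}

#' Dual proximal step (resolvent of sigma * dF*)
#'
#' Blockwise resolvents of the convex conjugates: the data block is the
#' conjugate prox of the squared distance to the measurements,
#' `(v - sigma m) / (1 + sigma / 2)`; the S0/T1rho TV blocks are pointwise
#' projections of the difference 2-vectors onto discs of radius `alpha1` /
#' `alpha2`; the phase block is the linear shrinkage
#' `v / (1 + sigma / (2 alpha3))` (zero when `alpha3 = 0`).
#'
#' @param y dual blocks (list `data`, `g1`, `g2`, `g3`).
#' @param Hx forward values `H(x_bar)` with the same block structure.
#' @param sigma dual step: a positive scalar, or a named vector with
#'   per-block entries `data`, `g1`, `g2`, `g3`.
#' @param m measurement list on the normalized encoding scale.
#' @param config an [embedded_config()].
#' @param weights optional per-contrast list of per-sample density weights
#'   in (0, 1] multiplying the data-block dual step (diagonal dual
#'   preconditioning; all-ones when omitted).
#' @export
prox_dual <- function(y, Hx, sigma, m, config, weights = NULL) {
  stopifnot(all(sigma > 0))
  if (length(sigma) == 1L)
    sigma <- c(data = sigma, g1 = sigma, g2 = sigma, g3 = sigma)
  proj_disc <- function(v, radius) {
    if (radius <= 0) return(v * 0)
    nrm <- sqrt(v[, , 1L]^2 + v[, , 2L]^2)
    f <- radius / pmax(nrm, radius)
    v * as.vector(f)
  }
  sd <- sigma[["data"]]
  if (is.null(weights)) weights <- lapply(m, function(mc) 1)
  shrink <- function(v, alpha, s) if (alpha <= 0) v * 0 else v / (1 + s / (2 * alpha))
  list(data = mapply(function(yc, hc, mc, wc) {
         s <- sd * wc
         (yc + s * (hc - mc)) / (1 + s / 2)
       }, y$data, Hx$data, m, weights, SIMPLIFY = FALSE),
       g1 = proj_disc(y$g1 + sigma[["g1"]] * Hx$g1, config$alpha1),
       g2 = proj_disc(y$g2 + sigma[["g2"]] * Hx$g2, config$alpha2),
       g3 = shrink(y$g3 + sigma[["g3"]] * Hx$g3, config$alpha3, sigma[["g3"]]))
}

## H(x): forward model plus the stacked spatial differences
embedded_H <- function(maps, tsl, enc) {
  list(data = forward_model(maps, tsl, enc),
       g1 = spatial_grad(maps$s0),
       g2 = spatial_grad(maps$t1rho),
       g3 = spatial_grad(maps$phase))
}

## [grad H(x)]^* y
embedded_Ht <- function(maps, tsl, enc, y) {
  jk <- jacobian_adjoint(maps, tsl, enc, y$data)
  list(s0 = jk$s0 + spatial_grad_adj(y$g1),
       t1rho = jk$t1rho + spatial_grad_adj(y$g2),
       phase = jk$phase + spatial_grad_adj(y$g3))
}

## directional derivative of H at maps
embedded_Hd <- function(maps, tsl, enc, d) {
  list(data = jacobian_apply(maps, tsl, enc, d),
       g1 = spatial_grad(d$s0), g2 = spatial_grad(d$t1rho),
       g3 = spatial_grad(d$phase))
}

## lambda_max of sqrt(T) gradH^* Sigma gradH sqrt(T): the step-size
## criterion quantity; must stay < 1 for convergence of the splitting.
embedded_step_criterion <- function(maps, tsl, enc, tau, sigma, m = 25L,
                                    weights = NULL) {
  n <- nrow(maps$s0)
  st <- sqrt(tau)
  if (length(sigma) == 1L)
    sigma <- c(data = sigma, g1 = sigma, g2 = sigma, g3 = sigma)
  if (is.null(weights)) weights <- as.list(rep(1, enc$n_contrasts))
  op <- function(d) {
    dm <- list(s0 = st[1L] * d$s0, t1rho = st[2L] * d$t1rho,
               phase = st[3L] * d$phase)
    h <- embedded_Hd(maps, tsl, enc, dm)
    h <- list(data = mapply(function(hc, wc) sigma[["data"]] * wc * hc,
                            h$data, weights, SIMPLIFY = FALSE),
              g1 = sigma[["g1"]] * h$g1, g2 = sigma[["g2"]] * h$g2,
              g3 = sigma[["g3"]] * h$g3)
    z <- embedded_Ht(maps, tsl, enc, h)
    list(s0 = st[1L] * z$s0, t1rho = st[2L] * z$t1rho,
         phase = st[3L] * z$phase)
  }
  ## generic Lanczos on the 3N-dimensional real parameter space
  opr <- function(v) {
    d <- list(s0 = matrix(v[, , 1L], n), t1rho = matrix(v[, , 2L], n),
              phase = matrix(v[, , 3L], n))
    z <- op(d)
    array(c(z$s0, z$t1rho, z$phase), c(n, n, 3L))
  }
  with_seed(4999L, lanczos_top_eig(opr, c(n, n, 3L), m = m,
                                   complex_start = FALSE))
}

#' Solve the embedded T1rho reconstruction
#'
#' Non-linear primal-dual proximal splitting applied to the direct
#' parameter-map problem: primal projection step with per-block steps
#' `tau`, over-relaxation with `omega`, and blockwise dual resolvents with
#' step `sigma`. Step sizes follow the Jacobian block sup-norms (the T1rho
#' step optionally boosted by `tau2_multiplier`), are refreshed every
#' `check_every` iterations, never increase, and `sigma` is reduced
#' whenever the estimated criterion
#' `||sqrt(sigma) gradH(x) sqrt(T)||^2 < 1` would be violated.
#'
#' @param data a `kspace_data` object (must contain a TSL = 0 contrast and
#'   at least one positive TSL).
#' @param config an [embedded_config()].
#' @param enc optional prebuilt [encoding_operator()].
#' @param init optional warm start: a [parameter_maps()] object (dual
#'   restarted at zero) or a list with `maps` and dual blocks `y`, e.g. a
#'   previous solve's state. The default is the cold start of
#'   [initialize_embedded()].
#' @return list with `maps` (the reconstructed [parameter_maps()]), `y`
#'   (final dual blocks) and `report`: iterations run, relative-change
#'   trace, step-size and criterion traces, and the final objective value.
#' @export
solve_embedded <- function(data, config = embedded_config(), enc = NULL,
                           init = NULL) {
  prot <- data$protocol
  stopifnot(any(prot$tsl > 0))
  if (is.null(enc))
    enc <- encoding_operator(data$schedule, prot$matrix_size, prot$n_contrasts)
  tsl <- prot$tsl
  m <- normalized_samples(data, enc)
  w <- enc$dual_weights

  if (is.null(init)) {
    init <- initialize_embedded(data, enc, config)
  } else if (inherits(init, "parameter_maps")) {
    n <- enc$n
    init <- list(maps = init,
                 y = list(data = lapply(enc$M, function(k) complex(k)),
                          g1 = array(0, c(n, n, 2L)),
                          g2 = array(0, c(n, n, 2L)),
                          g3 = array(0, c(n, n, 2L))))
  }
  x <- prox_primal(init$maps, config)
  y <- init$y

  ## the dual steps are rescaled jointly so that the convergence criterion
  ## ||Sigma^1/2 gradH(x) T^1/2||^2 < 1 holds at the current iterate
  steps <- derive_steps(compute_block_norms(x, tsl), config)
  lam <- embedded_step_criterion(x, tsl, enc, steps$tau, steps$sigma,
                                 weights = w)
  steps$sigma <- steps$sigma * (0.99 / lam)
  crit_hist <- 0.99
  tau_hist <- list(steps$tau)
  sigma_hist <- list(steps$sigma)

  rel_hist <- numeric(0)
  xprev_norm <- block_norm(list(x$s0, x$t1rho, x$phase))
  iters <- 0L
  for (i in seq_len(config$max_iters)) {
    iters <- i
    g <- embedded_Ht(x, tsl, enc, y)
    x_new <- prox_primal(list(s0 = x$s0 - steps$tau[1L] * g$s0,
                              t1rho = x$t1rho - steps$tau[2L] * g$t1rho,
                              phase = x$phase - steps$tau[3L] * g$phase),
                         config)
    xbar <- list(s0 = x_new$s0 + config$omega * (x_new$s0 - x$s0),
                 t1rho = x_new$t1rho + config$omega * (x_new$t1rho - x$t1rho),
                 phase = x_new$phase + config$omega * (x_new$phase - x$phase))
    ## xbar may step outside the box; the model only needs t1rho > 0
    xbar$t1rho <- pmax(xbar$t1rho, config$a2 / 2)
    xbar$s0 <- pmax(xbar$s0, 0)
    class(xbar) <- "parameter_maps"
    y <- prox_dual(y, embedded_H(xbar, tsl, enc), steps$sigma, m, config,
                   weights = w)

    dx <- block_norm(list(x_new$s0 - x$s0, x_new$t1rho - x$t1rho,
                          x_new$phase - x$phase))
    xn <- block_norm(list(x_new$s0, x_new$t1rho, x_new$phase))
    if (!is.finite(xn) || xn > 1e12 * max(1, xprev_norm))
      stop("embedded solver diverged (primal norm overflow) at iteration ", i)
    rel <- dx / max(xn, .Machine$double.eps)
    x <- x_new
    xprev_norm <- xn

    if (i %% 10L == 0L || i == 1L) rel_hist <- c(rel_hist, rel)
    if (i == 1L || i %% config$check_every == 0L) {
      steps_new <- derive_steps(compute_block_norms(x, tsl), config,
                                prev = list(tau = steps$tau,
                                            sigma = steps$sigma))
      lam <- embedded_step_criterion(x, tsl, enc, steps_new$tau,
                                     steps_new$sigma, weights = w)
      if (lam >= 1) steps_new$sigma <- steps_new$sigma * (0.99 / lam)
      steps <- steps_new
      crit_hist <- c(crit_hist, min(lam, 0.99))
      tau_hist <- c(tau_hist, list(steps$tau))
      sigma_hist <- c(sigma_hist, list(steps$sigma))
    }
    if (rel < config$rel_tol && i > 1L) break
  }

  obj <- embedded_objective(x, data, enc, config)
  list(maps = x, y = y,
       report = list(iterations = iters, rel_change = rel_hist,
                     tau = do.call(rbind, tau_hist),
                     sigma = do.call(rbind, sigma_hist),
                     criterion = crit_hist, objective = obj,
                     converged = iters < config$max_iters))
}

#' Objective value of the embedded problem
#'
#' @param maps candidate [parameter_maps()].
#' @param data the `kspace_data`.
#' @param enc the [encoding_operator()].
#' @param config an [embedded_config()].
#' @return the (finite part of the) objective; box violations make it `Inf`.
#' @export
embedded_objective <- function(maps, data, enc, config) {
  if (any(maps$s0 < config$a1) || any(maps$t1rho < config$a2)) return(Inf)
  m <- normalized_samples(data, enc)
  r <- forward_model(maps, data$protocol$tsl, enc)
  tv <- function(mm) {
    g <- spatial_grad(mm)
    sum(sqrt(g[, , 1L]^2 + g[, , 2L]^2))
  }
  sum(vapply(seq_along(m), function(c) sum(abs(r[[c]] - m[[c]])^2),
             numeric(1))) +
    config$alpha1 * tv(maps$s0) + config$alpha2 * tv(maps$t1rho) +
    config$alpha3 * sum(spatial_grad(maps$phase)^2)
}
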