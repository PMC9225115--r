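#' Configuration of the compressed-sensing reference reconstructions
#'
#' Two total-variation models for the per-contrast complex images `u`:
#' `"s1c1"` minimizes `||Au - m||^2 + alpha TVS(u) + beta TVC(u)`
#' (isotropic spatial TV per contrast plus the 1-norm of first differences
#' along the contrast dimension), and `"s1c2"` minimizes
#' `||Au - m||^2 + alpha TVSC(u)` where the spatial differences and the
#' second-order contrast differences share a single pointwise root.
#'
#' @param model `"s1c1"` or `"s1c2"`.
#' @param alpha spatial-TV weight (and the joint weight for `"s1c2"`).
#' @param beta contrast-TV weight (`"s1c1"` only; ignored otherwise).
#' @param max_iters iteration cap of the Chambolle-Pock solver.
#' @param rel_tol stopping tolerance on the relative primal change.
#' @return an object of class `cs_config`.
#' @export
cs_config <- function(model = c("s1c1", "s1c2"), alpha = 1e-3, beta = 1e-3,
                      max_iters = 2000L, rel_tol = 1e-7) {
  model <- match.arg(model)
  stopifnot(alpha >= 0, beta >= 0, max_iters >= 1, rel_tol > 0)
  structure(list(model = model, alpha = alpha, beta = beta,
                 max_iters = as.integer(max_iters), rel_tol = rel_tol),
            class = "cs_config")
}

## stacked regularization operator and its adjoint for the CS models
cs_reg_ops <- function(model, C) {
  use_c2 <- model == "s1c2" && C >= 3L
  list(
    forward = function(u) {
      d <- dim(u)
      gs <- array(0i, c(d, 2L))
      for (c in seq_len(d[3L])) gs[, , c, ] <- spatial_grad(u[, , c])
      gc <- if (model == "s1c1") contrast_diff1(u)
            else if (use_c2) contrast_diff2(u) else NULL
      list(gs = gs, gc = gc)
    },
    adjoint = function(g, d) {
      out <- array(0i, d)
      for (c in seq_len(d[3L]))
        out[, , c] <- spatial_grad_adj(g$gs[, , c, ])
      if (!is.null(g$gc)) {
        out <- out + if (model == "s1c1") contrast_diff1_adj(g$gc)
                     else contrast_diff2_adj(g$gc, d[3L])
      }
      out
    },
    use_c2 = use_c2)
}

#' Compressed-sensing reconstruction (Chambolle-Pock)
#'
#' Solves the selected TV-regularized least-squares problem with the
#' primal-dual proximal splitting of Chambolle and Pock with diagonal dual
#' preconditioning of the data block by the sampling-density weights (a
#' change of metric only; the minimizer is untouched): steps
#' `tau = sigma = 0.99 / L` with `L` the norm of the weighted stacked
#' operator `[W^1/2 A; differences]` estimated by Lanczos iteration,
#' over-relaxation 1, zero-filled-adjoint initialization and zero initial
#' duals.
#'
#' @param data a `kspace_data` object.
#' @param config a [cs_config()].
#' @param enc optional prebuilt [encoding_operator()].
#' @return list with `images` (complex `n x n x C` array) and `report`
#'   (iterations, relative-change trace, objective).
#' @export
solve_cs <- function(data, config = cs_config(), enc = NULL) {
  prot <- data$protocol
  if (is.null(enc))
    enc <- encoding_operator(data$schedule, prot$matrix_size, prot$n_contrasts)
  n <- enc$n; C <- enc$n_contrasts
  m <- normalized_samples(data, enc)
  reg <- cs_reg_ops(config$model, C)
  w <- enc$dual_weights

  ## diagonal dual preconditioning of the data block with the sampling
  ## density weights: same minimizer, far better conditioning for radial
  ## trajectories; the steps obey tau * sigma * ||Sigma^1/2 K||^2 < 1 via
  ## a Lanczos estimate of the weighted normal operator
  L <- with_seed(911L, sqrt(lanczos_top_eig(function(u) {
    au <- enc$adjoint(mapply(`*`, w, enc$forward(u), SIMPLIFY = FALSE))
    g <- reg$forward(u)
    au + reg$adjoint(g, dim(u))
  }, c(n, n, C))))
  tau <- sigma <- 0.99 / L

  u <- enc$adjoint(m)                       # zero-filled adjoint start
  y_d <- lapply(enc$M, function(k) complex(k))
  y_g <- reg$forward(u * 0)

  proj_iso <- function(gs, gc, alpha, joint) {
    ## pointwise projection: spatial 2-vector (plus, jointly, the
    ## second-order contrast difference) onto the ball of radius alpha
    if (alpha <= 0) {
      gs <- gs * 0
      if (!is.null(gc)) gc <- gc * 0
      return(list(gs = gs, gc = gc))
    }
    nrm2 <- Mod(gs[, , , 1L])^2 + Mod(gs[, , , 2L])^2      # n x n x C
    if (joint && !is.null(gc)) {
      Ci <- dim(gc)[3L]
      nrm2[, , 1L + seq_len(Ci)] <- nrm2[, , 1L + seq_len(Ci), drop = FALSE] +
        Mod(gc)^2
      f <- alpha / pmax(sqrt(nrm2), alpha)
      gc <- gc * as.vector(f[, , 1L + seq_len(Ci), drop = FALSE])
    } else {
      f <- alpha / pmax(sqrt(nrm2), alpha)
    }
    gs[, , , 1L] <- gs[, , , 1L] * as.vector(f)
    gs[, , , 2L] <- gs[, , , 2L] * as.vector(f)
    list(gs = gs, gc = gc)
  }

  rel_hist <- numeric(0)
  iters <- 0L
  for (i in seq_len(config$max_iters)) {
    iters <- i
    grad <- enc$adjoint(y_d) + reg$adjoint(y_g, dim(u))
    u_new <- u - tau * grad
    ubar <- 2 * u_new - u
    fu <- enc$forward(ubar)
    y_d <- mapply(function(yc, fc, mc, wc) {
      s <- sigma * wc
      (yc + s * (fc - mc)) / (1 + s / 2)
    }, y_d, fu, m, w, SIMPLIFY = FALSE)
    g <- reg$forward(ubar)
    if (config$model == "s1c1") {
      pr <- proj_iso(y_g$gs + sigma * g$gs, NULL, config$alpha, FALSE)
      y_g$gs <- pr$gs
      vc <- y_g$gc + sigma * g$gc
      y_g$gc <- if (config$beta <= 0) vc * 0 else
        vc * as.vector(config$beta / pmax(Mod(vc), config$beta))
    } else {
      pr <- proj_iso(y_g$gs + sigma * g$gs,
                     if (reg$use_c2) y_g$gc + sigma * g$gc else NULL,
                     config$alpha, TRUE)
      y_g$gs <- pr$gs
      if (reg$use_c2) y_g$gc <- pr$gc
    }
    rel <- block_norm(u_new - u) / max(block_norm(u_new), .Machine$double.eps)
    if (!is.finite(rel)) stop("CS solver diverged at iteration ", i)
    u <- u_new
    if (i %% 10L == 0L || i == 1L) rel_hist <- c(rel_hist, rel)
    if (rel < config$rel_tol && i > 1L) break
  }
  list(images = u,
       report = list(iterations = iters, rel_change = rel_hist,
                     objective = cs_objective(u, data, enc, config),
                     converged = iters < config$max_iters))
}

#' Objective value of a CS reconstruction problem
#'
#' @param u complex `n x n x C` image series.
#' @param data the `kspace_data`.
#' @param enc the [encoding_operator()].
#' @param config a [cs_config()].
#' @export
cs_objective <- function(u, data, enc, config) {
  m <- normalized_samples(data, enc)
  fu <- enc$forward(u)
  fid <- sum(vapply(seq_along(m), function(c) sum(abs(fu[[c]] - m[[c]])^2),
                    numeric(1)))
  C <- dim(u)[3L]
  reg <- cs_reg_ops(config$model, C)
  g <- reg$forward(u)
  nrm2 <- Mod(g$gs[, , , 1L])^2 + Mod(g$gs[, , , 2L])^2
  if (config$model == "s1c1") {
    fid + config$alpha * sum(sqrt(nrm2)) +
      config$beta * sum(Mod(g$gc))
  } else {
    if (reg$use_c2) {
      Ci <- dim(g$gc)[3L]
      nrm2[, , 1L + seq_len(Ci)] <- nrm2[, , 1L + seq_len(Ci), drop = FALSE] +
        Mod(g$gc)^2
    }
    fid + config$alpha * sum(sqrt(nrm2))
  }
}

#' Zero-filled inverse FFT reference reconstruction
#'
#' Per-contrast inverse unitary DFT with unacquired rows set to zero;
#' defined for cartesian data only.
#'
#' @param data a cartesian `kspace_data` object.
#' @param enc optional prebuilt [encoding_operator()].
#' @return complex `n x n x C` image array.
#' @export
solve_ifft <- function(data, enc = NULL) {
  if (data$schedule$scheme != "cartesian")
    stop("the zero-filled iFFT reference is defined for cartesian data only")
  n <- data$protocol$matrix_size
  C <- data$protocol$n_contrasts
  out <- array(0i, c(n, n, C))
  for (c in seq_len(C)) {
    ridx <- as.integer(data$schedule$rows[[c]]) + 1L
    G <- matrix(0i, n, n)
    G[ridx, ] <- matrix(data$samples[[c]], length(ridx), n)
    out[, , c] <- cifft2(G)
  }
  out
}
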