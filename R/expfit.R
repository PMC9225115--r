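#' Configuration of the pixel-wise mono-exponential fit
#'
#' @param t1rho_bounds lower/upper box bounds on the relaxation time (ms).
#' @param s0_min lower bound on the amplitude.
#' @param intensity_threshold fraction of the series-wide maximum magnitude
#'   below which a pixel is flagged as background and assigned the bound
#'   values instead of being fitted.
#' @param max_fit_iters Levenberg-Marquardt iteration cap.
#' @param tsl_max contrasts with spin-lock time above this value (ms) are
#'   excluded from the fit (`Inf` keeps all).
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(t1rho_bounds = c(0.1, 1000), s0_min = 0,
                       intensity_threshold = 1e-3, max_fit_iters = 50L,
                       tsl_max = Inf) {
  stopifnot(length(t1rho_bounds) == 2L, t1rho_bounds[1] > 0,
            t1rho_bounds[2] > t1rho_bounds[1], s0_min >= 0,
            intensity_threshold >= 0, max_fit_iters >= 1, tsl_max > 0)
  structure(list(t1rho_bounds = as.numeric(t1rho_bounds),
                 s0_min = as.numeric(s0_min),
                 intensity_threshold = intensity_threshold,
                 max_fit_iters = as.integer(max_fit_iters),
                 tsl_max = tsl_max),
            class = "fit_config")
}

#' Vectorized bounded mono-exponential least-squares fit
#'
#' Bounded Levenberg-Marquardt for `y ~ s0 * exp(-t / T1rho)`, run
#' simultaneously over the rows of `Y` (P pixels x C contrasts). Box
#' bounds are enforced by clamping after each accepted step; steps that do
#' not decrease the residual are rejected and the damping increased, so
#' the final residual never exceeds the initializer's. Rows whose maximum
#' intensity falls below the configured threshold are flagged and assigned
#' the bound values. This is the computational core behind [fit_pixel()]
#' and [fit_map()].
#'
#' @param Y numeric `P x C` matrix of magnitudes.
#' @param tsl spin-lock times (ms), length `C`.
#' @param config a [fit_config()].
#' @return list of length-`P` vectors `s0`, `t1rho`, `residual` and the
#'   integer vector `flag` (1 for below-threshold rows).
#' @export
fit_exp_core <- function(Y, tsl, config) {
  P <- nrow(Y); C <- ncol(Y)
  lo <- config$t1rho_bounds[1]; hi <- config$t1rho_bounds[2]
  thr <- config$intensity_threshold * max(Y)
  flagged <- rowSums(Y > thr) == 0L

  ## log-linear initializer per pixel over the above-threshold samples
  logY <- suppressWarnings(log(Y))
  W <- (Y > thr) & is.finite(logY)
  few <- rowSums(W) < 2L
  if (any(few)) W[few, ] <- is.finite(logY[few, , drop = FALSE])
  W[rowSums(W) < 2L, ] <- FALSE
  sw  <- pmax(rowSums(W), 1L)
  st  <- as.vector(W %*% tsl) / sw
  logs <- logY; logs[!W] <- 0
  sy  <- rowSums(logs) / sw
  stt <- as.vector(W %*% tsl^2) / sw - st^2
  sty <- rowSums(logs * matrix(tsl, P, C, byrow = TRUE)) / sw - st * sy
  slope <- ifelse(stt > 0, sty / stt, 0)
  T0 <- ifelse(slope < -1e-12, -1 / slope, hi)
  T0 <- pmin(pmax(T0, lo), hi)
  S0 <- pmax(exp(sy + slope * st), config$s0_min)
  S0[!is.finite(S0)] <- config$s0_min
  T0[rowSums(W) == 0L] <- lo
  S0[rowSums(W) == 0L] <- config$s0_min

  resid2 <- function(s0, tt) {
    E <- exp(-outer(1 / tt, tsl))
    rowSums((Y - s0 * E)^2)
  }

  s0 <- S0; tt <- T0
  r2 <- resid2(s0, tt)
  lam <- rep(1e-3, P)
  active <- !flagged
  for (it in seq_len(config$max_fit_iters)) {
    if (!any(active)) break
    E <- exp(-outer(1 / tt, tsl))                  # P x C
    R <- Y - s0 * E
    Jt <- s0 * E * matrix(tsl, P, C, byrow = TRUE) / tt^2  # dmodel/dT
    a11 <- rowSums(E * E)
    a12 <- rowSums(E * Jt)
    a22 <- rowSums(Jt * Jt)
    b1 <- rowSums(E * R)
    b2 <- rowSums(Jt * R)
    d11 <- a11 * (1 + lam) + 1e-12
    d22 <- a22 * (1 + lam) + 1e-12
    det <- d11 * d22 - a12^2
    det[abs(det) < 1e-300] <- 1e-300
    ds0 <- (d22 * b1 - a12 * b2) / det
    dtt <- (d11 * b2 - a12 * b1) / det
    s0_try <- pmax(s0 + ds0, config$s0_min)
    tt_try <- pmin(pmax(tt + dtt, lo), hi)
    r2_try <- resid2(s0_try, tt_try)
    better <- active & (r2_try < r2)
    s0[better] <- s0_try[better]
    tt[better] <- tt_try[better]
    step <- abs(ds0) / pmax(abs(s0), 1e-12) + abs(dtt) / pmax(abs(tt), 1e-12)
    lam[better] <- pmax(lam[better] / 3, 1e-12)
    lam[active & !better] <- pmin(lam[active & !better] * 10, 1e12)
    r2[better] <- r2_try[better]
    active <- active & !(better & step < 1e-10) & lam < 1e11
  }
  tt[flagged] <- lo
  s0[flagged] <- config$s0_min
  list(t1rho = tt, s0 = s0, flag = as.integer(flagged),
       residual = sqrt(r2))
}

#' Fit a mono-exponential decay to one pixel's intensity series
#'
#' Least-squares fit of `|u_c| ~ S0 * exp(-TSL_c / T1rho)` with box bounds,
#' initialized by a log-linear regression over above-threshold samples and
#' refined by damped Gauss-Newton steps.
#'
#' @param intensities numeric (or complex, magnitudes are taken) vector, one
#'   value per spin-lock time.
#' @param tsl spin-lock times in ms, same length.
#' @param config a [fit_config()].
#' @return list with `t1rho`, `s0`, `flag` (1 if the pixel was below the
#'   intensity threshold and received the bound values) and `residual`.
#' @export
fit_pixel <- function(intensities, tsl, config = fit_config()) {
  y <- if (is.complex(intensities)) Mod(intensities) else as.numeric(intensities)
  stopifnot(length(y) == length(tsl), length(y) >= 2L)
  keep <- tsl <= config$tsl_max
  out <- fit_exp_core(matrix(y[keep], 1L), as.numeric(tsl[keep]), config)
  lapply(out, function(v) v[1L])
}

#' Pixel-wise T1rho and amplitude maps from an image series
#'
#' Applies the bounded mono-exponential fit of [fit_pixel()] to every pixel
#' of a complex contrast series. The phase map is read from the first
#' contrast (the spin-lock-free image when `tsl[1] == 0`). Pixels whose
#' magnitude stays below `intensity_threshold * max |u|` in every contrast
#' are not fitted: they are flagged and given the bound values.
#'
#' @param images complex (or numeric) `n x n x C` array.
#' @param tsl spin-lock times in ms (length `C`).
#' @param config a [fit_config()].
#' @return list with `maps` (a [parameter_maps()] object), `flags`
#'   (integer matrix, 1 = below threshold) and `residual` matrix.
#' @export
fit_map <- function(images, tsl, config = fit_config()) {
  stopifnot(length(dim(images)) == 3L, dim(images)[3L] == length(tsl))
  n1 <- dim(images)[1L]; n2 <- dim(images)[2L]
  keep <- tsl <= config$tsl_max
  stopifnot(sum(keep) >= 2L)
  Y <- matrix(Mod(images[, , keep, drop = FALSE]), n1 * n2, sum(keep))
  out <- fit_exp_core(Y, as.numeric(tsl[keep]), config)
  phase <- if (is.complex(images)) Arg(images[, , 1L]) else matrix(0, n1, n2)
  maps <- parameter_maps(s0 = matrix(out$s0, n1, n2),
                         t1rho = matrix(out$t1rho, n1, n2),
                         phase = phase)
  list(maps = maps, flags = matrix(out$flag, n1, n2),
       residual = matrix(out$residual, n1, n2))
}
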