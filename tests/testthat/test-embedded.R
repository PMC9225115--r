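embedded_setup <- function(n = 16, scheme = "cartesian", af = 1,
                           tsl = c(0, 16, 64), noise = 0, seed = 2) {
  spec <- phantom_spec(matrix_size = n, base_size = n - 4)
  maps <- make_phantom_maps(spec)
  sched <- if (scheme == "cartesian") cartesian_schedule(n, af, length(tsl), seed = 5)
           else radial_subsample(golden_angle_schedule(nyquist_spokes(n), n),
                                 af, length(tsl))
  prot <- acquisition_protocol(tsl, n, scheme, af)
  data <- simulate_kspace(maps, prot, sched, noise_fraction = noise, seed = seed)
  enc <- encoding_operator(sched, n, length(tsl))
  list(maps = maps, data = data, enc = enc, tsl = tsl)
}

test_that("initialization calibrates S0 and phase from the spin-lock-free contrast", {
  s <- embedded_setup()
  cfg <- embedded_config()
  init <- initialize_embedded(s$data, s$enc, cfg)
  expect_s3_class(init$maps, "parameter_maps")
  ## full noiseless cartesian: the TSL = 0 adjoint is exact, so the starting
  ## S0/phase match the truth on the support
  supp <- s$maps$s0 > 0.05
  expect_lt(max(abs(init$maps$s0[supp] - s$maps$s0[supp])), 1e-8)
  dphi <- (init$maps$phase[supp] - s$maps$phase[supp] + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi)), 1e-8)
  expect_true(all(init$maps$t1rho == cfg$t1rho_init))
  expect_true(all(vapply(init$y$data, function(v) all(v == 0), logical(1))))

  ## a TSL = 0 contrast is mandatory
  s2 <- embedded_setup(tsl = c(10, 30, 50))
  expect_error(initialize_embedded(s2$data, s2$enc, cfg),
               "TSL = 0")
})

test_that("derived steps are inversely tied to block norms and honour the T1rho multiplier", {
  cfg <- embedded_config()
  norms <- c(L1sq = 2, L2sq = 0.004, L3sq = 0.5)
  st <- derive_steps(norms, cfg)
  expect_equal(st$tau, cfg$step_scale / unname(norms))
  ## multiplier scales tau2 only
  cfg50 <- embedded_config(tau2_multiplier = 50)
  st50 <- derive_steps(norms, cfg50)
  expect_equal(st50$tau[2], 50 * st$tau[2])
  expect_equal(st50$tau[c(1, 3)], st$tau[c(1, 3)])
  ## steps never increase when previous steps are supplied
  prev <- list(tau = st$tau / 2, sigma = st$sigma / 2)
  st2 <- derive_steps(norms * 0.1, cfg, prev = prev)
  expect_true(all(st2$tau <= prev$tau + 1e-15))
  expect_true(all(st2$sigma <= prev$sigma + 1e-15))
  expect_error(derive_steps(c(0, 0, 0), cfg))
})

test_that("the step criterion holds throughout a solve, also with the T1rho multiplier", {
  s <- embedded_setup(n = 12, noise = 0.05)
  for (mult in c(1, 50)) {
    cfg <- embedded_config(alpha1 = 1e-3, alpha2 = 1e-4, max_iters = 250L,
                           check_every = 50L, tau2_multiplier = mult)
    fit <- solve_embedded(s$data, cfg, enc = s$enc)
    expect_true(all(fit$report$criterion < 1))
    ## tau2 * sigma stays small even with the multiplier
    tau2 <- fit$report$tau[, 2]
    sig <- fit$report$sigma[, "g2"]
    expect_true(all(tau2 * sig < 1 / 8 + 1e-12))
    ## step sizes are monotone non-increasing
    expect_true(all(diff(fit$report$tau[, 1]) <= 1e-15))
    expect_true(all(diff(fit$report$tau[, 2]) <= 1e-15))
    expect_true(all(apply(fit$report$sigma, 2, function(s) all(diff(s) <= 1e-15))))
    ## iterates satisfy the box constraints
    expect_true(all(fit$maps$s0 >= cfg$a1))
    expect_true(all(fit$maps$t1rho >= cfg$a2))
  }
})

test_that("primal projection is idempotent and dual resolvents match numerical proxes", {
  cfg <- embedded_config(alpha1 = 0.3, alpha2 = 0.7, alpha3 = 0.2)
  maps <- list(s0 = matrix(c(-1, 0.5, 2, 1e-9), 2),
               t1rho = matrix(c(-5, 10, 1e-9, 50), 2),
               phase = matrix(c(-9, 0, 2, 9), 2))
  p <- prox_primal(maps, cfg)
  expect_true(all(p$s0 >= cfg$a1) && all(p$t1rho >= cfg$a2))
  expect_equal(p$phase, maps$phase)
  expect_equal(prox_primal(p, cfg), p)

  ## data block: prox of the conjugate of F(z) = ||z - m||^2 via Moreau,
  ## checked against a 1-D numerical minimization
  sigma <- 0.8; m <- 0.6; v <- 1.7
  y0 <- list(data = list(complex(real = v)), g1 = array(0, c(1, 1, 2)),
             g2 = array(0, c(1, 1, 2)), g3 = array(0, c(1, 1, 2)))
  Hx <- list(data = list(complex(real = 0)), g1 = array(0, c(1, 1, 2)),
             g2 = array(0, c(1, 1, 2)), g3 = array(0, c(1, 1, 2)))
  out <- prox_dual(y0, Hx, sigma, list(complex(real = m)), cfg)
  fstar <- function(y) y^2 / 4 + m * y       # conjugate of (z - m)^2
  num <- stats::optimize(function(y) fstar(y) + (y - v)^2 / (2 * sigma),
                         c(-10, 10), tol = 1e-10)$minimum
  expect_equal(Re(out$data[[1]]), num, tolerance = 1e-6)

  ## TV blocks: projection onto the alpha-radius disc
  big <- array(c(3, 4), c(1, 1, 2))           # norm 5 -> scaled to alpha
  y1 <- list(data = list(0i), g1 = big, g2 = big, g3 = big * 0)
  Hx0 <- list(data = list(0i), g1 = big * 0, g2 = big * 0, g3 = big * 0)
  out2 <- prox_dual(y1, Hx0, 1, list(0i), cfg)
  expect_equal(sqrt(sum(out2$g1^2)), cfg$alpha1, tolerance = 1e-12)
  expect_equal(sqrt(sum(out2$g2^2)), cfg$alpha2, tolerance = 1e-12)
  small <- array(c(0.01, 0.02), c(1, 1, 2))   # inside the disc: untouched
  y2 <- list(data = list(0i), g1 = small, g2 = small, g3 = small)
  out3 <- prox_dual(y2, Hx0, 1, list(0i), cfg)
  expect_equal(out3$g1, small)

  ## phase block: linear shrinkage, against a numerical prox of the
  ## conjugate of alpha3 * z^2
  v3 <- 0.9; s3 <- 1.3
  y3 <- list(data = list(0i), g1 = small * 0, g2 = small * 0,
             g3 = array(c(v3, 0), c(1, 1, 2)))
  out4 <- prox_dual(y3, Hx0, s3, list(0i), cfg)
  gstar <- function(y) y^2 / (4 * cfg$alpha3)
  num3 <- stats::optimize(function(y) gstar(y) + (y - v3)^2 / (2 * s3),
                          c(-10, 10), tol = 1e-10)$minimum
  expect_equal(out4$g3[1, 1, 1], num3, tolerance = 1e-6)
})

test_that("noiseless fully sampled data is recovered to sub-percent accuracy", {
  s <- embedded_setup(n = 16, noise = 0)
  cfg <- embedded_config(alpha1 = 1e-9, alpha2 = 1e-9, alpha3 = 1e-9,
                         max_iters = 4000L, check_every = 500L,
                         rel_tol = 1e-9)
  fit <- solve_embedded(s$data, cfg, enc = s$enc)
  supp <- s$maps$s0 > 0
  relT1 <- rmse(fit$maps$t1rho[supp], s$maps$t1rho[supp]) /
    mean(s$maps$t1rho[supp])
  relS0 <- rmse(fit$maps$s0[supp], s$maps$s0[supp]) / mean(s$maps$s0[supp])
  expect_lt(relT1, 0.01)
  expect_lt(relS0, 0.01)
  ## the fitted objective is no worse than at the (clamped) ground truth
  truth <- parameter_maps(pmax(s$maps$s0, cfg$a1), pmax(s$maps$t1rho, cfg$a2),
                          s$maps$phase)
  expect_lte(embedded_objective(fit$maps, s$data, s$enc, cfg),
             embedded_objective(truth, s$data, s$enc, cfg) * 1.01 + 1e-5)
})

test_that("a global phase offset in the data shifts only the phase estimate", {
  s <- embedded_setup(n = 12, noise = 0)
  cfg <- embedded_config(alpha1 = 1e-6, alpha2 = 1e-6, alpha3 = 1e-6,
                         max_iters = 600L, check_every = 200L, rel_tol = 1e-10)
  fit0 <- solve_embedded(s$data, cfg, enc = s$enc)
  phi <- 0.7
  rot <- s$data
  rot$samples <- lapply(rot$samples, `*`, exp(1i * phi))
  fit1 <- solve_embedded(rot, cfg, enc = s$enc)
  supp <- s$maps$s0 > 0.05
  expect_equal(fit1$maps$s0[supp], fit0$maps$s0[supp], tolerance = 1e-6)
  expect_equal(fit1$maps$t1rho[supp], fit0$maps$t1rho[supp], tolerance = 1e-5)
  dphi <- (fit1$maps$phase[supp] - fit0$maps$phase[supp] - phi + pi) %%
    (2 * pi) - pi
  ## equivariance is exact except where the wrapped phase ramp crosses
  ## +-pi, where the (tiny) phase regularizer sees different gradients
  expect_lt(max(abs(dphi)), 1e-3)
})

test_that("a heavy T1rho TV weight drives the map towards a constant", {
  s <- embedded_setup(n = 12, noise = 0.05)
  loose <- solve_embedded(s$data,
                          embedded_config(alpha1 = 1e-6, alpha2 = 1e-8,
                                          alpha3 = 1e-4, max_iters = 800L,
                                          check_every = 200L, rel_tol = 1e-10),
                          enc = s$enc)
  tight <- solve_embedded(s$data,
                          embedded_config(alpha1 = 1e-6, alpha2 = 0.1,
                                          alpha3 = 1e-4, max_iters = 800L,
                                          check_every = 200L, rel_tol = 1e-10),
                          enc = s$enc)
  expect_lt(sd(tight$maps$t1rho), sd(loose$maps$t1rho) / 5)
})
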