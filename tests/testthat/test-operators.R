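rand_img <- function(n, seed) {
  set.seed(seed)
  matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
}

inner_c <- function(a, b) sum(Re(Conj(a) * b))

test_that("centred unitary FFT is unitary with zero frequency at n/2 + 1", {
  x <- rand_img(16, 1)
  expect_equal(cifft2(cfft2(x)), x, tolerance = 1e-12)
  expect_equal(sum(Mod(cfft2(x))^2), sum(Mod(x)^2), tolerance = 1e-12)
  ## a constant image concentrates at the zero-frequency bin (9, 9) for n=16
  F <- cfft2(matrix(1 + 0i, 16, 16))
  expect_equal(which(Mod(F) > 1e-8), 8 * 16 + 9)
})

test_that("spatial and contrast difference operators match explicit matrices and adjoints", {
  n <- 4
  set.seed(2)
  u <- matrix(rnorm(n * n), n, n)
  g <- spatial_grad(u)
  ## forward differences with Neumann boundary
  expect_equal(g[1, 1, 1], u[1, 2] - u[1, 1])
  expect_equal(g[1, 1, 2], u[2, 1] - u[1, 1])
  expect_equal(g[3, n, 1], 0)
  expect_equal(g[n, 3, 2], 0)
  v <- array(rnorm(n * n * 2), c(n, n, 2))
  expect_equal(sum(g * v), sum(u * spatial_grad_adj(v)), tolerance = 1e-12)

  a <- array(rnorm(n * n * 3), c(n, n, 3))
  d1 <- contrast_diff1(a)
  expect_equal(d1[, , 1], a[, , 2] - a[, , 1])
  expect_equal(d1[, , 3], matrix(0, n, n))
  b <- array(rnorm(n * n * 3), c(n, n, 3))
  expect_equal(sum(d1 * b), sum(a * contrast_diff1_adj(b)), tolerance = 1e-12)

  d2 <- contrast_diff2(a)
  expect_equal(dim(d2), c(n, n, 1))
  expect_equal(d2[, , 1], a[, , 1] - 2 * a[, , 2] + a[, , 3])
  b2 <- array(rnorm(n * n), c(n, n, 1))
  expect_equal(sum(d2 * b2), sum(a * contrast_diff2_adj(b2, 3)),
               tolerance = 1e-12)
  expect_error(contrast_diff2(array(0, c(n, n, 2))))
})

test_that("NUFFT agrees with the direct Fourier sum and its adjoint is exact", {
  n <- 16
  sch <- golden_angle_schedule(8, n)
  ang <- sch$angles
  traj <- cbind(as.vector(outer(sch$radii, cos(ang))),
                as.vector(outer(sch$radii, sin(ang))))
  plan <- nufft_plan(traj, n)
  img <- rand_img(n, 3)
  fast <- nufft_forward(plan, img)
  slow <- ndft_direct(img, traj)
  expect_lt(sqrt(sum(Mod(fast - slow)^2) / sum(Mod(slow)^2)), 1e-3)

  set.seed(4)
  y <- complex(real = rnorm(plan$M), imaginary = rnorm(plan$M))
  lhs <- inner_c(nufft_forward(plan, img), y)
  rhs <- inner_c(img, nufft_adjoint(plan, y))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("encoding operators have exact adjoints and unit spectral norm", {
  n <- 16; C <- 2
  for (kind in c("cartesian", "radial")) {
    sched <- if (kind == "cartesian") cartesian_schedule(n, 2, C, seed = 5)
             else radial_subsample(golden_angle_schedule(25, n), 2, C)
    enc <- encoding_operator(sched, n, C)
    set.seed(6)
    u <- array(complex(real = rnorm(n * n * C), imaginary = rnorm(n * n * C)),
               c(n, n, C))
    y <- lapply(enc$M, function(m)
      complex(real = rnorm(m), imaginary = rnorm(m)))
    fu <- enc$forward(u)
    lhs <- sum(vapply(seq_len(C), function(c) inner_c(fu[[c]], y[[c]]),
                      numeric(1)))
    rhs <- inner_c(u, enc$adjoint(y))
    tol <- if (kind == "cartesian") 1e-10 else 1e-6
    expect_equal(lhs, rhs, tolerance = tol)
    expect_equal(encoding_norm(enc), 1, tolerance = 1e-3)
    expect_true(all(unlist(enc$dual_weights) > 0))
    expect_true(all(unlist(enc$dual_weights) <= 1))
  }
})

test_that("model Jacobian passes finite-difference and adjoint consistency checks", {
  n <- 8; tsl <- c(0, 15, 45)
  sched <- cartesian_schedule(n, 1, 3, seed = 7)
  enc <- encoding_operator(sched, n, 3)
  set.seed(8)
  maps <- parameter_maps(s0 = matrix(runif(n * n, 0.5, 1.5), n),
                         t1rho = matrix(runif(n * n, 30, 90), n),
                         phase = matrix(runif(n * n, -1, 1), n))
  d <- list(s0 = matrix(rnorm(n * n), n), t1rho = matrix(rnorm(n * n), n),
            phase = matrix(rnorm(n * n), n))

  ## first-order convergence of the linearization error
  err <- vapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    pert <- parameter_maps(maps$s0 + eps * d$s0, maps$t1rho + eps * d$t1rho,
                           maps$phase + eps * d$phase)
    f0 <- forward_model(maps, tsl, enc)
    f1 <- forward_model(pert, tsl, enc)
    jd <- jacobian_apply(maps, tsl, enc, d)
    sqrt(sum(vapply(1:3, function(c)
      sum(Mod(f1[[c]] - f0[[c]] - eps * jd[[c]])^2), numeric(1)))) / eps
  }, numeric(1))
  expect_lt(err[2], err[1] / 3)
  expect_lt(err[3], err[2] / 3)

  ## adjoint identity <J d, y> = <d, J* y>
  y <- lapply(enc$M, function(m)
    complex(real = rnorm(m), imaginary = rnorm(m)))
  jd <- jacobian_apply(maps, tsl, enc, d)
  lhs <- sum(vapply(1:3, function(c) inner_c(jd[[c]], y[[c]]), numeric(1)))
  jt <- jacobian_adjoint(maps, tsl, enc, y)
  rhs <- sum(d$s0 * jt$s0) + sum(d$t1rho * jt$t1rho) + sum(d$phase * jt$phase)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("Jacobian block norms follow the decay model", {
  maps <- parameter_maps(s0 = matrix(c(1, 0.5, 0.2, 0.8), 2),
                         t1rho = matrix(c(40, 60, 80, 100), 2),
                         phase = matrix(0, 2, 2))
  ## single TSL = 0 contrast: E = 1 everywhere, no T1rho sensitivity
  nrm <- compute_block_norms(maps, 0)
  expect_equal(unname(nrm[1]), 1)
  expect_equal(unname(nrm[2]), 0)
  ## with decay, L1^2 sums the per-contrast max of E^2 and L3^2 of r^2
  tsl <- c(0, 30)
  nrm2 <- compute_block_norms(maps, tsl)
  E2 <- exp(-30 / maps$t1rho)
  r2 <- maps$s0 * E2
  expect_equal(unname(nrm2[1]), 1 + max(E2)^2)
  expect_equal(unname(nrm2[2]), max(r2 * 30 / maps$t1rho^2)^2)
  expect_equal(unname(nrm2[3]), max(maps$s0)^2 + max(r2)^2)
})
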