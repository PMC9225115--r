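test_that("golden-angle increment and Nyquist spoke counts match theory", {
  expect_equal(golden_angle() * 180 / pi, 111.2461, tolerance = 1e-6)
  expect_equal(nyquist_spokes(192), 302L)
  sch <- golden_angle_schedule(302, 192)
  expect_equal(sch$n_spokes, 302L)
  expect_true(all(sch$angles >= 0 & sch$angles < pi))
  ## successive spokes differ by the golden angle modulo pi
  d <- diff(sch$angles) %% pi
  expect_true(all(abs(d - golden_angle() %% pi) < 1e-12 |
                  abs(d - (golden_angle() %% pi) + pi) < 1e-12))
  expect_equal(length(sch$radii), 192L)
  expect_true(all(sch$radii >= -0.5 & sch$radii < 0.5))
})

test_that("complementary radial subsampling assigns disjoint consecutive blocks", {
  sch <- golden_angle_schedule(302, 192)
  sub <- radial_subsample(sch, af = 10, n_contrasts = 7)
  expect_equal(sub$spokes[[1]], 1:30)
  expect_equal(sub$spokes[[2]], 31:60)
  expect_equal(length(unlist(sub$spokes)), 7 * 30)
  expect_equal(anyDuplicated(unlist(sub$spokes)), 0L)

  ## AF 101: 3 spokes per contrast, 21 in total over 7 contrasts
  sub2 <- radial_subsample(sch, af = 101, n_contrasts = 7)
  expect_true(all(lengths(sub2$spokes) == 3L))
  expect_equal(length(unlist(sub2$spokes)), 21L)

  ## AF 1 keeps the full set for every contrast
  sub3 <- radial_subsample(sch, af = 1, n_contrasts = 3)
  expect_true(all(vapply(sub3$spokes, identical, logical(1), 1:302)))

  expect_error(radial_subsample(sch, af = 1000, n_contrasts = 7),
               "fewer than one spoke")

  ## blocks past the base spoke count continue the golden-angle sequence
  ## (AF 2, 7 contrasts needs 151 * 7 = 1057 > 302 spokes)
  sub2 <- radial_subsample(sch, af = 2, n_contrasts = 7)
  expect_identical(sub2$n_spokes, 151L * 7L)
  expect_identical(anyDuplicated(unlist(sub2$spokes)), 0L)
  expect_equal(sub2$angles[303], (302 * golden_angle()) %% pi)
  expect_equal(diff(sub2$angles[400:401]) %% pi, golden_angle() %% pi,
               tolerance = 1e-12)
})

test_that("cartesian schedules keep a centre block and draw outer rows without replacement", {
  sch <- cartesian_schedule(192, af = 4, n_contrasts = 5, seed = 3)
  expect_equal(sch$rows_per_contrast, 48L)
  expect_equal(sch$n_centre, 12L)
  for (r in sch$rows) {
    expect_equal(length(r), 48L)
    expect_true(96 %in% r)                     # zero-frequency row (0-based)
    expect_true(all(sch$centre_rows %in% r))
    expect_true(all(r >= 0 & r < 192))
    expect_equal(anyDuplicated(r), 0L)
  }
  ## outer rows are complementary across contrasts until a half-pool is
  ## exhausted: the bottom pool holds 89 candidates (the centre block sits
  ## asymmetrically), so 4 contrasts (4 x 18 = 72 draws per half) fit
  ## without any reuse while the 5th forces exactly one repeat
  outer_rows <- lapply(sch$rows, setdiff, sch$centre_rows)
  expect_equal(anyDuplicated(unlist(outer_rows[1:4])), 0L)
  dup_all <- sum(duplicated(unlist(outer_rows)))
  expect_lte(dup_all, 1L)
})

test_that("cartesian schedules are seed-reproducible and exhaust tiny pools gracefully", {
  a <- cartesian_schedule(32, af = 2, n_contrasts = 4, seed = 11)
  b <- cartesian_schedule(32, af = 2, n_contrasts = 4, seed = 11)
  expect_identical(a$rows, b$rows)
  c <- cartesian_schedule(32, af = 2, n_contrasts = 4, seed = 12)
  expect_false(identical(a$rows, c$rows))

  ## a matrix-8 schedule at AF 2 with 2 contrasts has no duplicated rows
  tiny <- cartesian_schedule(8, af = 2, n_contrasts = 2, seed = 1)
  for (r in tiny$rows) expect_equal(anyDuplicated(r), 0L)

  ## full sampling takes every row once
  fullc <- cartesian_schedule(16, af = 1, n_contrasts = 2, seed = 1)
  for (r in fullc$rows) expect_equal(sort(r), 0:15)
})

test_that("acquisition protocols validate their inputs", {
  p <- acquisition_protocol(c(0, 20, 40), 64, "radial", 5)
  expect_equal(p$n_contrasts, 3L)
  expect_error(acquisition_protocol(c(20, 0), 64, "radial", 5))   # not sorted
  expect_error(acquisition_protocol(c(0, 0, 40), 64, "radial", 5)) # duplicate
  expect_error(acquisition_protocol(0, 64, "radial", 5))           # no decay
  expect_error(acquisition_protocol(c(0, 40), 63, "radial", 5))    # odd size
  expect_error(acquisition_protocol(c(0, 40), 64, "radial", 0.5))  # af < 1
})
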