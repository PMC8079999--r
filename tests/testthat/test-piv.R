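small_piv <- function(...) {
  piv_config(window_px = 65, overlap_fraction = 0.5, border_px = 32,
             ground_sample_distance = 0.1, ...)
}

test_that("identical frames give zero displacement and unit correlation", {
  fr <- piv_texture(200, 260, seed = 3)
  f <- correlate_pair(fr, fr, small_piv())
  expect_true(all(abs(f$u) < 1e-9))
  expect_true(all(abs(f$v) < 1e-9))
  expect_true(all(f$corr > 0.999))
})

test_that("integer circular shifts are recovered exactly on interior windows", {
  fr <- piv_texture(260, 260, seed = 5)
  shifted <- fr[, c(258:260, 1:257)]   # content moves +3 columns
  f <- correlate_pair(fr, shifted, small_piv())
  expect_true(all(abs(f$u - 3) < 0.05))
  expect_true(all(abs(f$v) < 0.05))
})

test_that("sub-pixel shifts are recovered within 0.1 px", {
  fr <- piv_texture(260, 300, seed = 11)
  shifted <- shift_image(fr, dx = 2.5, dy = -1.25)
  f <- correlate_pair(fr, shifted, small_piv())
  # interior windows only: resampling at the frame edge extrapolates
  u_in <- f$u[2:(length(f$x) - 1), 2:(length(f$y) - 1), 1]
  v_in <- f$v[2:(length(f$x) - 1), 2:(length(f$y) - 1), 1]
  expect_lt(max(abs(u_in - 2.5)), 0.1)
  # dy = -1.25 moves content up, i.e. +y displacement of +1.25
  expect_lt(max(abs(v_in - 1.25)), 0.1)
})

test_that("flat windows are flagged with zero correlation", {
  fr <- piv_texture(200, 200, seed = 2)
  flat_a <- matrix(0.5, 200, 200)
  f <- correlate_pair(flat_a, flat_a, small_piv())
  expect_true(all(f$corr == 0))
  expect_true(all(is.na(f$u)))
})

test_that("median merge equals a brute-force 27-value median everywhere", {
  set.seed(42)
  nx <- 7; ny <- 5
  mk <- function() {
    flow_stack(seq_len(nx) * 32, seq_len(ny) * 32, 0,
               array(rnorm(nx * ny), c(nx, ny, 1)),
               array(rnorm(nx * ny), c(nx, ny, 1)),
               array(runif(nx * ny), c(nx, ny, 1)), units = "px/frame")
  }
  fields <- list(mk(), mk(), mk())
  merged <- merge_fields(fields)
  U3 <- array(c(fields[[1]]$u, fields[[2]]$u, fields[[3]]$u), c(nx, ny, 3))
  expect_equal(merged$u[, , 1], brute_merge_oracle(U3), tolerance = 1e-12)
  V3 <- array(c(fields[[1]]$v, fields[[2]]$v, fields[[3]]$v), c(nx, ny, 3))
  expect_equal(merged$v[, , 1], brute_merge_oracle(V3), tolerance = 1e-12)
})

test_that("median merge suppresses a single spurious vector", {
  nx <- 5; ny <- 5
  mk <- function(spike = FALSE) {
    u <- array(1, c(nx, ny, 1))
    if (spike) u[3, 3, 1] <- 10
    flow_stack(seq_len(nx), seq_len(ny), 0, u, array(0, c(nx, ny, 1)),
               units = "px/frame")
  }
  merged <- merge_fields(list(mk(TRUE), mk(), mk()))
  expect_equal(merged$u[3, 3, 1], 1)
})

test_that("median merge is idempotent on constant fields and symmetric", {
  u <- array(1.7, c(5, 4, 1))
  mk <- function() flow_stack(1:5, 1:4, 0, u, u, units = "px/frame")
  m1 <- merge_fields(list(mk(), mk(), mk()))
  expect_equal(m1$u, u, tolerance = 1e-12)
  # permutation invariance over the three fields
  mka <- function(k) {
    uu <- u + k
    flow_stack(1:5, 1:4, 0, uu, uu, units = "px/frame")
  }
  ma <- merge_fields(list(mka(0), mka(1), mka(2)))
  mb <- merge_fields(list(mka(2), mka(0), mka(1)))
  expect_equal(ma$u, mb$u, tolerance = 1e-12)
})

test_that("scaling converts px/frame to m/s linearly in the GSD", {
  st <- flow_stack(1:4, 1:3, 0, array(1, c(4, 3, 1)),
                   array(0, c(4, 3, 1)), units = "px/frame")
  cfg <- piv_config(ground_sample_distance = 0.06, frame_rate = 30)
  sc <- scale_field(st, cfg)
  expect_true(all(abs(sc$u - 1.8) < 1e-12))  # 1 px/frame * 0.06 m/px * 30 Hz
  expect_identical(sc$units, "m/s")
  cfg2 <- piv_config(ground_sample_distance = 0.12, frame_rate = 30)
  sc2 <- scale_field(st, cfg2)
  expect_equal(sc2$u, 2 * sc$u)
  expect_error(scale_field(sc, cfg), "already")
  expect_error(scale_field(st, piv_config()), "ground_sample_distance")
})

linear_stack <- function(fun_u, fun_v, h = 1, n = 21) {
  xs <- seq(0, by = h, length.out = n)
  ys <- seq(0, by = h, length.out = n)
  X <- matrix(xs, n, n); Y <- matrix(ys, n, n, byrow = TRUE)
  flow_stack(xs, ys, 0, array(fun_u(X, Y), c(n, n, 1)),
             array(fun_v(X, Y), c(n, n, 1)), units = "m/s")
}

test_that("solid-body rotation yields curl 2*Omega and zero divergence", {
  om <- 0.1
  st <- linear_stack(function(x, y) -om * y, function(x, y) om * x)
  dt <- derive_turbulence(st, piv_config())
  expect_true(all(abs(dt$curl - 0.2) < 1e-8))
  expect_true(all(abs(dt$div) < 1e-8))
})

test_that("pure straining flow yields the configured divergence", {
  a <- 0.05
  st <- linear_stack(function(x, y) a * x, function(x, y) a * y)
  dt <- derive_turbulence(st, piv_config())
  expect_true(all(abs(dt$div - 0.1) < 1e-8))
  expect_true(all(abs(dt$curl) < 1e-8))
})

test_that("low-correlation vectors mask their whole difference stencil", {
  st <- linear_stack(function(x, y) 0 * x, function(x, y) 0 * y, n = 9)
  st$corr[5, 5, 1] <- 0.5
  dt <- derive_turbulence(st, piv_config(corr_threshold = 0.6))
  expect_true(is.na(dt$curl[5, 5, 1]))
  expect_true(is.na(dt$curl[4, 5, 1]) && is.na(dt$curl[6, 5, 1]))
  expect_true(is.na(dt$curl[5, 4, 1]) && is.na(dt$curl[5, 6, 1]))
  expect_false(is.na(dt$curl[4, 4, 1]))   # diagonal neighbours unaffected
  expect_false(is.na(dt$curl[2, 2, 1]))
})

test_that("a whole-field bias leaves curl and divergence unchanged", {
  om <- 0.07
  st <- linear_stack(function(x, y) -om * y + 0.8, function(x, y) om * x + 0.3)
  st0 <- linear_stack(function(x, y) -om * y, function(x, y) om * x)
  d1 <- derive_turbulence(st, piv_config())
  d0 <- derive_turbulence(st0, piv_config())
  expect_equal(d1$curl, d0$curl, tolerance = 1e-10)
  expect_equal(d1$div, d0$div, tolerance = 1e-10)
})

test_that("PIV on advected texture recovers a uniform translation", {
  # 0.8 px/frame imposed by shifting the same texture progressively
  fr0 <- piv_texture(280, 280, seed = 21)
  frames <- lapply(0:3, function(k) shift_image(fr0, dx = 0.8 * k, dy = 0))
  cfg <- small_piv(frame_rate = 30, field_interval = 4 / 30)
  st <- piv_sequence(frames, cfg)
  # 0.8 px/frame * 0.1 m/px * 30 Hz = 2.4 m/s
  u_in <- st$u[2:(length(st$x) - 1), 2:(length(st$y) - 1), 1]
  expect_lt(abs(median(u_in) - 2.4), 0.1 * 0.1 * 30)  # 0.1 px/frame slack
})
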