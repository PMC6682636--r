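small_cfg <- function(n = 32, spacing = 1, duration = 0.1, q = 0.52,
                      noise = noise_spec(0), ...) {
  sim_config(n = n, spacing = spacing, dt = 0.01, duration = duration,
             stride = 5L, kernel = regime_kernel(q), model = model_params(),
             noise = noise, ...)
}

test_that("FFT synaptic input matches direct O(N^2) summation", {
  cfg <- small_cfg(n = 32)
  kg <- kernel_grid(cfg)
  set.seed(3)
  f <- matrix(stats::runif(32 * 32), 32)
  u <- synaptic_input(f, kg)
  # brute-force circular convolution oracle
  u_direct <- matrix(0, 32, 32)
  for (a in 0:31) for (b in 0:31) {
    if (f[a + 1, b + 1] == 0) next
    rows <- ((0:31 - a) %% 32) + 1
    cols <- ((0:31 - b) %% 32) + 1
    u_direct <- u_direct + f[a + 1, b + 1] * kg$k[rows, cols]
  }
  expect_lt(max(abs(u - u_direct)) / max(abs(u_direct)), 1e-10)
})

test_that("synaptic input of simple fields follows the convolution identities", {
  cfg <- small_cfg(n = 32)
  kg <- kernel_grid(cfg)
  u <- synaptic_input(matrix(0.3, 32, 32), kg)
  expect_equal(u, matrix(0.3 * sum(kg$k), 32, 32), tolerance = 1e-10)
  delta <- matrix(0, 32, 32); delta[5, 9] <- 1
  ud <- synaptic_input(delta, kg)
  expect_equal(ud[5, 9], kg$k[1, 1], tolerance = 1e-12)
  expect_equal(ud[6, 9], kg$k[2, 1], tolerance = 1e-12)
  expect_error(synaptic_input(matrix(0, 8, 8), kg), "mismatch")
})

test_that("bump interior is stationary under a Runge-Kutta step", {
  cfg <- small_cfg(n = 128, spacing = 0.5, duration = 0)
  m <- cfg$model
  b <- Filter(function(z) z$branch == "larger",
              solve_bump_radii(cfg$kernel, m))[[1]]
  st <- make_initial("bump", cfg, bump = b)
  kg <- kernel_grid(cfg)
  st2 <- rk4_step(st, cfg, kg)
  interior <- st$f == b$f_in  # strictly interior cells
  expect_lt(max(abs(st2$f[interior] - b$f_in)), 1e-6)
  expect_lt(max(abs(st2$h[interior] - b$h_in)), 1e-6)
})

test_that("clamping keeps the probabilistic bounds under strong noise", {
  cfg <- small_cfg(n = 32, duration = 0.2,
                   noise = noise_spec(1, seed = 4, mode = "continuous"))
  set.seed(1)
  f0 <- matrix(stats::runif(32^2, 0, 0.5), 32)
  h0 <- matrix(stats::runif(32^2, 0, 0.4), 32)
  mv <- simulate_field(field_state(f0, h0), cfg)
  k <- dim(mv$f)[3]
  expect_true(all(mv$f >= 0 & mv$f <= 1))
  expect_true(all(mv$h >= 0 & mv$h <= 1))
  expect_true(all(mv$f[, , k] + mv$h[, , k] <= 1 + 1e-12))
  # the clamp itself restores every invariant and counts violations
  cl <- nfwaves:::clamp_state(matrix(c(-0.2, 0.6, 1.4, 0.5), 2),
                              matrix(c(0.1, 0.7, 0.3, -0.1), 2))
  expect_true(all(cl$f >= 0 & cl$f <= 1))
  expect_true(all(cl$h >= 0 & cl$f + cl$h <= 1))
  expect_equal(cl$clamped, 4)
})

test_that("zero-duration simulation returns the initial state bit-identically", {
  cfg <- small_cfg(n = 32, duration = 0)
  set.seed(2)
  f0 <- matrix(stats::runif(32^2, 0, 0.5), 32)
  st <- field_state(f0, f0 / 2)
  mv <- simulate_field(st, cfg)
  expect_identical(dim(mv$f)[3], 1L)
  expect_identical(mv$f[, , 1], st$f)
  expect_identical(mv$h[, , 1], st$h)
})

test_that("simulations are bit-reproducible under a fixed seed", {
  cfg <- small_cfg(n = 32, duration = 0.3,
                   noise = noise_spec(0.2, seed = 11, mode = "continuous"))
  st <- field_state(bump_field(32, c(16, 16), 6), bump_field(32, c(16, 16), 6))
  m1 <- simulate_field(st, cfg)
  m2 <- simulate_field(st, cfg)
  expect_identical(m1$f, m2$f)
  cfg2 <- cfg; cfg2$noise$seed <- 12L
  m3 <- simulate_field(st, cfg2)
  expect_false(identical(m1$f, m3$f))
})

test_that("degenerate noise modes reduce to the noise-free run", {
  st <- field_state(bump_field(32, c(16, 16), 6), bump_field(32, c(16, 16), 6))
  cfg_off <- small_cfg(n = 32, duration = 0.2)
  cfg_kick0 <- small_cfg(n = 32, duration = 0.2,
                         noise = noise_spec(0, seed = 3, mode = "single_kick"))
  expect_identical(simulate_field(st, cfg_off)$f,
                   simulate_field(st, cfg_kick0)$f)
})

test_that("quiescence is absorbing without noise", {
  cfg <- small_cfg(n = 32, duration = 0.3)
  z <- matrix(0, 32, 32)
  mv <- simulate_field(field_state(z, z), cfg)
  expect_true(all(mv$f == 0) && all(mv$h == 0))
})

test_that("halving the time step barely changes a smooth solution", {
  pt <- regime_point("traveling")
  st <- NULL
  mk <- function(dt) sim_config(n = 128, spacing = 0.5, dt = dt, duration = 1,
                                stride = 1000L, kernel = pt$kernel,
                                model = pt$model, store_h = FALSE)
  cfg1 <- mk(0.01); cfg2 <- mk(0.005)
  st <- seed_wave_state(cfg1)
  f1 <- simulate_field(st, cfg1)$f
  f2 <- simulate_field(st, cfg2)$f
  k1 <- dim(f1)[3]; k2 <- dim(f2)[3]
  rms <- sqrt(mean((f1[, , k1] - f2[, , k2])^2))
  # the moving threshold front is not smooth, so step-halving agreement is
  # limited by front-cell switching times rather than the RK4 order
  expect_lt(rms, 1e-4)
})

test_that("initial-condition builders honor their contracts", {
  cfg <- small_cfg(n = 128, spacing = 0.5, duration = 0)
  m <- cfg$model
  b <- Filter(function(z) z$branch == "larger",
              solve_bump_radii(cfg$kernel, m))[[1]]
  st <- make_initial("bump", cfg, bump = b)
  expect_setequal(unique(as.vector(st$f)), c(0, b$f_in))
  # matches an independent rasterization
  expect_identical(st$f, bump_field(128, c(32, 32), b$rho, b$f_in, 0.5))

  sh <- wave2d_shape(1.5, 5, 5, 2.5, 0.5)
  r1 <- make_initial("random_waves", cfg, shape = sh, n_waves = 4, seed = 1)
  comps <- label_patterns(r1, 0.5, f_in = m$p / (1 + 2 * m$p))
  expect_length(comps, 4)
  r2 <- make_initial("random_waves", cfg, shape = sh, n_waves = 4, seed = 2)
  expect_false(identical(r1$f, r2$f))
  expect_length(label_patterns(r2, 0.5, f_in = m$p / (1 + 2 * m$p)), 4)
  # too many patterns cannot be packed
  expect_error(make_initial("random_waves", cfg, shape = sh, n_waves = 60),
               "packing")
})

test_that("solved 1D waves propagate at their solved speed on a line", {
  m <- model_params(p = 0.3)
  kp <- wave_kernel_1d()
  sols <- solve_wave1d(kp, m, n_starts = 10, seed = 1)
  w <- sols[[length(sols)]]
  n <- 1024; sp <- 0.25
  x <- ((seq_len(n) - 1) - round(0.7 * n)) * sp
  pr <- wave1d_profile(x, w, m)
  cut <- x > 0 | x < -0.25 * n * sp
  pr$F[cut] <- 0; pr$H[cut] <- 0
  ln <- simulate_line(pr$F, pmax(pr$H, 0), kp, m, spacing = sp,
                      dt = 0.01, duration = 20, stride = 50)
  measured <- line_speed(ln)
  expect_equal(measured, w$c, tolerance = 0.05)
})
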