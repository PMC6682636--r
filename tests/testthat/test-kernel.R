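test_that("kernel value at the origin equals the analytic Bessel limit", {
  kp <- reference_kernel()
  expect_equal(eval_kernel(0, kp),
               (144.4 - 73.7) * 2 / (3 * pi) * log(2), tolerance = 1e-12)
  # limit is approached continuously
  expect_equal(eval_kernel(1e-8, kp), eval_kernel(0, kp), tolerance = 1e-4)
  expect_error(eval_kernel(-1, kp), "non-negative")
})

test_that("kernel without inhibition never changes sign", {
  kp <- kernel_params(100, 1e-8, 2, 4, check = FALSE)
  r <- seq(0.01, 50, length.out = 500)
  expect_true(all(eval_kernel(r, kp) > 0))
  expect_error(zero_crossing_radius(kp), "no inhibitory region")
})

test_that("degenerate equal-parameter kernel is rejected", {
  expect_error(kernel_params(50, 50, 2, 2), "Mexican-hat")
})

test_that("zero crossing matches a dense-scan bracketing oracle", {
  kp <- reference_kernel()
  r0 <- zero_crossing_radius(kp)
  expect_lt(abs(eval_kernel(r0, kp)), 1e-8)
  # independent oracle: dense radial evaluation + sign change bracket
  r <- seq(0.05, 30, by = 0.001)
  w <- eval_kernel(r, kp)
  i <- which(diff(sign(w)) != 0)[1]
  expect_gt(r0, r[i] - 1e-3)
  expect_lt(r0, r[i + 1] + 1e-3)
  # excitatory inside, inhibitory outside
  expect_true(all(eval_kernel(seq(0.01, r0 - 0.01, length.out = 50), kp) > 0))
  expect_true(all(eval_kernel(seq(r0 + 0.01, 30, length.out = 50), kp) < 0))
})

test_that("transition radius of the reference kernel is 2.79 in axis units", {
  expect_equal(zero_crossing_radius(reference_kernel()), 2.79, tolerance = 0.01 / 2.79)
})

test_that("zero crossing scales exactly with the spatial scales", {
  kp <- reference_kernel()
  r0 <- zero_crossing_radius(kp)
  for (k in c(0.5, 3)) {
    kps <- kernel_params(kp$W_E, kp$W_I, k * kp$sigma_E, k * kp$sigma_I)
    expect_equal(zero_crossing_radius(kps), k * r0, tolerance = 1e-8)
  }
})

test_that("E/I integrals match an independent composite-Simpson oracle", {
  simpson <- function(f, a, b, n = 4001) {
    x <- seq(a, b, length.out = n)
    h <- x[2] - x[1]
    w <- c(1, rep(c(4, 2), (n - 3) / 2), 4, 1)
    sum(w * f(x)) * h / 3
  }
  for (kp in list(reference_kernel(), kernel_params(40, 20, 4, 6.93))) {
    ei <- ei_integrals(kp)
    r0 <- ei$r0
    f <- function(r) 2 * pi * r * eval_kernel(r, kp)
    gp_o <- simpson(f, 1e-9, r0)
    gm_o <- simpson(f, r0, 25 * kp$sigma_I)
    expect_equal(ei$g_plus, gp_o, tolerance = 1e-6)
    expect_equal(ei$g_minus, gm_o, tolerance = 1e-6)
    expect_gt(ei$g_plus, 0)
    expect_lt(ei$g_minus, 0)
  }
})

test_that("E/I integrals are linear in the coupling strengths", {
  kp <- reference_kernel()
  ei <- ei_integrals(kp)
  kp2 <- kernel_params(2 * kp$W_E, 2 * kp$W_I, kp$sigma_E, kp$sigma_I)
  ei2 <- ei_integrals(kp2)
  expect_equal(ei2$g_plus, 2 * ei$g_plus, tolerance = 1e-9)
  expect_equal(ei2$g_minus, 2 * ei$g_minus, tolerance = 1e-9)
  expect_equal(ei2$r0, ei$r0, tolerance = 1e-9)
})

test_that("excitatory integral increases with W_E", {
  kp <- reference_kernel()
  g1 <- ei_integrals(kp)$g_plus
  kp2 <- kernel_params(kp$W_E * 1.05, kp$W_I, kp$sigma_E, kp$sigma_I)
  expect_gt(ei_integrals(kp2)$g_plus, g1)
})

test_that("inverting E/I coordinates reproduces them to tolerance", {
  kp <- reference_kernel()
  ei <- ei_integrals(kp)
  inv <- invert_ei(ei$g_plus, ei$g_minus, seed = 1)
  ach <- ei_integrals(inv)
  expect_equal(ach$g_plus, ei$g_plus, tolerance = 1e-6 / abs(ei$g_plus))
  expect_equal(ach$g_minus, ei$g_minus, tolerance = 1e-6 / abs(ei$g_minus))
  expect_lt(attr(inv, "residual"), 1e-6)
})

test_that("the inversion is not unique but every solution matches the target", {
  target <- list(g_plus = 50, g_minus = -200)
  a <- invert_ei(target$g_plus, target$g_minus, seed = 2)
  b <- invert_ei(target$g_plus, target$g_minus,
                 init = kernel_params(40, 20, 4, 6.93), seed = 3)
  for (kp in list(a, b)) {
    ach <- ei_integrals(kp)
    expect_equal(ach$g_plus, target$g_plus, tolerance = 1e-7)
    expect_equal(ach$g_minus, target$g_minus, tolerance = 1e-8)
  }
  # distinct parameter sets for the same coordinates
  expect_false(isTRUE(all.equal(c(a$W_E, a$sigma_E), c(b$W_E, b$sigma_E),
                                tolerance = 1e-3)))
})

test_that("inversion rejects infeasible sign conventions", {
  expect_error(invert_ei(-5, -10), "g_plus")
  expect_error(invert_ei(5, 10), "g_minus")
})

test_that("Monte-Carlo kernel sampling respects its contracts", {
  s1 <- sample_kernels_mc(20, seed = 42)
  expect_equal(nrow(s1), 20)
  expect_true(all(s1$g_plus > 0 & s1$g_minus < 0 & s1$r0 > 0))
  raw <- as.matrix(s1[, c("W_E", "W_I", "sigma_E", "sigma_I")])
  expect_true(all(raw > 0 & raw < 150))
  for (i in 1:5) {
    kp <- kernel_params(s1$W_E[i], s1$W_I[i], s1$sigma_E[i], s1$sigma_I[i],
                        check = FALSE)
    expect_true(is_mexican_hat(kp))
  }
  s2 <- sample_kernels_mc(20, seed = 42)
  expect_identical(s1, s2)
  s3 <- sample_kernels_mc(20, seed = 43)
  expect_false(identical(s1$W_E, s3$W_E))
})
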