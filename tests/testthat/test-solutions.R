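test_that("bump interior values are the exact fixed point", {
  for (p in c(0.3, 0.42, 1.7)) {
    m <- model_params(p = p)
    b <- bump_profile(5, m)
    expect_equal(b$f_in, p / (1 + 2 * p))
    expect_equal(b$h_in, 1 / (1 + 2 * p))
    expect_equal(b$f_in + b$h_in, (1 + p) / (1 + 2 * p))
    # field equations with the firing indicator active vanish identically
    expect_equal(-b$f_in + (1 - b$f_in - b$h_in), 0, tolerance = 1e-14)
    expect_equal(-p * b$h_in + b$f_in, 0, tolerance = 1e-14)
  }
})

test_that("existence residual has the analytic small-radius limit", {
  m <- model_params(p = 0.42)
  res <- bump_existence_residual(1e-4, reference_kernel(), m)
  expect_equal(as.numeric(res), -m$kappa * (1 + 2 * m$p / (1 + 2 * m$p)),
               tolerance = 1e-4)
})

test_that("boundary input curve is concave with one interior maximum", {
  m <- model_params(p = 0.42)
  for (kp in list(reference_kernel(), regime_kernel(0.52))) {
    rho <- exp(seq(log(0.3), log(15 * kp$sigma_E), length.out = 60))
    u <- attr(bump_existence_residual(rho, kp, m), "u")
    i_max <- which.max(u)
    expect_gt(i_max, 1); expect_lt(i_max, length(u))
    expect_true(all(diff(u[1:i_max]) > 0))
    expect_true(all(diff(u[i_max:length(u)]) < 0))
  }
})

test_that("bump radii are the residual roots and agree with the u-curve crossings", {
  m <- model_params(p = 0.42)
  kp <- reference_kernel()
  bb <- solve_bump_radii(kp, m)
  expect_lte(length(bb), 2)
  expect_equal(length(bb), 2)
  for (b in bb) {
    res <- bump_existence_residual(b$rho, kp, m)
    expect_lt(abs(as.numeric(res)), 1e-8)
    # the root is where u(rho) crosses the effective level u*
    expect_equal(attr(res, "u"), attr(res, "u_star"), tolerance = 1e-7)
  }
  expect_identical(vapply(bb, `[[`, character(1), "branch"),
                   c("smaller", "larger"))
})

test_that("no bump solutions exist above the maximal boundary input", {
  kp <- reference_kernel()
  bb <- solve_bump_radii(kp, model_params(p = 0.42, kappa = 50))
  expect_length(bb, 0)
})

test_that("larger-branch radius grows with excitation", {
  m <- model_params(p = 0.42)
  r1 <- solve_bump_radii(regime_kernel(0.52), m)
  kp2 <- kernel_params(40 * 1.1, 40 * 0.52, 4, 6.93)  # W_E up, W_I fixed
  r2 <- solve_bump_radii(kp2, m)
  big <- function(x) Filter(function(b) b$branch == "larger", x)[[1]]$rho
  expect_gt(big(r2), big(r1))
})

test_that("wave profile coefficients obey their defining relations", {
  for (p in c(0.3, 0.42, 2)) {
    co <- wave1d_coeffs(p)
    expect_equal(co$alpha, (2 + p) / 2)
    expect_equal(co$beta, sqrt(p * (4 - p)) / 2)
    expect_equal(co$A, (2 - co$alpha + 1 / p) / co$beta)
    expect_equal(co$B, (co$alpha - 2 - p * ((co$alpha - 2)^2 + co$beta^2)) / co$beta)
    # (alpha-2)^2 + beta^2 = 1 identically
    expect_equal((co$alpha - 2)^2 + co$beta^2, 1, tolerance = 1e-12)
  }
  expect_error(wave1d_coeffs(4), "p < 4")
})

test_that("wave profile solves the comoving-frame equations exactly", {
  m <- model_params(p = 0.3)
  w <- wave1d(c = 2.5, L = 8, m)
  hstep <- 1e-3
  check_ode <- function(x, active) {
    pr0 <- wave1d_profile(x - hstep / 2, w, m)
    pr1 <- wave1d_profile(x + hstep / 2, w, m)
    prm <- wave1d_profile(x, w, m)
    dF <- (pr1$F - pr0$F) / hstep
    dH <- (pr1$H - pr0$H) / hstep
    ind <- as.numeric(active)
    r1 <- -w$c * dF - (-prm$F + (1 - prm$F - prm$H) * ind)
    r2 <- -w$c * dH - (-m$p * prm$H + prm$F)
    max(abs(c(r1, r2)))
  }
  expect_lt(check_ode(seq(-7.9, -0.1, by = 0.01), active = TRUE), 1e-5)
  expect_lt(check_ode(seq(-25, -8.1, by = 0.01), active = FALSE), 1e-5)
})

test_that("wave profile is continuous and has the right limits", {
  m <- model_params(p = 0.3)
  w <- wave1d(c = 1.2, L = 7, m)
  expect_equal(wave1d_profile(0, w, m)$F, 0)
  expect_equal(wave1d_profile(0, w, m)$H, 0)
  left <- wave1d_profile(-7 - 1e-9, w, m)
  right <- wave1d_profile(-7 + 1e-9, w, m)
  expect_equal(left$F, right$F, tolerance = 1e-6)
  expect_equal(left$H, right$H, tolerance = 1e-6)
  # ahead of the front the medium is quiescent; far behind it recovers
  expect_equal(wave1d_profile(3, w, m)$F, 0)
  far <- wave1d_profile(-200, w, m)
  expect_lt(abs(far$F), 1e-10)
  expect_lt(abs(far$H), 1e-6)
  # the oscillation decays toward the interior fixed point
  mid <- wave1d_profile(-6.9, w, m)
  expect_equal(mid$F, m$p / (1 + 2 * m$p), tolerance = 0.05)
})

test_that("1D wave solver meets the boundary threshold conditions", {
  m <- model_params(p = 0.3)
  kp <- wave_kernel_1d()
  sols <- solve_wave1d(kp, m, n_starts = 10, seed = 1)
  expect_gte(length(sols), 1)
  best <- sols[[length(sols)]]
  # solutions sorted by (c, L), largest last
  cs <- vapply(sols, `[[`, numeric(1), "c")
  expect_true(all(diff(cs) >= 0))
  u <- nfwaves:::wave1d_boundary_inputs(best$c, best$L, kp, m)
  expect_lt(abs(u[["u0"]] - m$kappa), 1e-4 * m$kappa)
  expect_lt(abs(u[["uL"]] - m$kappa), 1e-4 * m$kappa)
  expect_lt(best$objective, 1e-10 * m$kappa^2)
})

test_that("wave speed and length grow with excitation", {
  m <- model_params(p = 0.3)
  kp1 <- wave_kernel_1d()
  s1 <- solve_wave1d(kp1, m, n_starts = 8, seed = 2)
  b1 <- s1[[length(s1)]]
  # raise the integrated excitation (both couplings up, g_plus up 10%)
  kp2 <- kernel_params(kp1$W_E * 1.1, kp1$W_I * 1.1, kp1$sigma_E,
                       kp1$sigma_I)
  s2 <- solve_wave1d(kp2, m, init = c(b1$c, b1$L), n_starts = 8, seed = 2)
  b2 <- s2[[length(s2)]]
  expect_gt(b2$c, b1$c)
  expect_gt(b2$L, b1$L)
})

test_that("growth-rate fit recovers a manufactured exponent", {
  lambda <- 0.8
  t <- seq(0, 10, by = 0.05)
  d <- 1e-3 * exp(lambda * t)
  expect_equal(fit_growth_rate(t, d), lambda, tolerance = 0.05)
  # sub-floor displacement flags as indistinguishable from zero
  flat <- fit_growth_rate(t, rep(1e-4, length(t)))
  expect_true(is.na(flat))
  expect_identical(attr(flat, "flag"), "indistinguishable from zero")
})

test_that("shift instability orders with inhibition strength", {
  m <- model_params(p = 0.42)
  rate <- function(q) {
    kp <- regime_kernel(q)
    b <- Filter(function(z) z$branch == "larger", solve_bump_radii(kp, m))[[1]]
    shift_growth_rate(b, kp, m, n = 128, spacing = 0.5, dt = 0.02,
                      t_max = 6, shift = 0.4)
  }
  r_weak <- rate(0.50)   # weaker inhibition: more unstable
  r_strong <- rate(0.56)
  expect_true(is.na(r_strong) || r_weak > r_strong)
  expect_true(!is.na(r_weak))
})
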