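# Semi-analytic solutions of the refractory neural field: radially symmetric
# bumps (existence, radii, shift stability) and 1D traveling waves.

#' Neural-field model parameters
#'
#' @param p refractory recovery rate (per rescaled time unit): the rate at
#'   which neurons leave the refractory pool for the resting pool. The
#'   nonlinear negative feedback it provides is what allows localized
#'   propagating waves.
#' @param kappa firing threshold on synaptic input.
#' @param tau membrane time constant in ms; only used to convert between
#'   rescaled time and wall-clock time.
#' @return an object of class \code{model_params}.
#' @examples
#' model_params(p = 0.42)
#' @export
model_params <- function(p = 0.42, kappa = 1, tau = 10) {
  if (!is.finite(p) || p <= 0) stop("p must be strictly positive")
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be strictly positive")
  if (!is.finite(tau) || tau <= 0) stop("tau must be strictly positive")
  structure(list(p = p, kappa = kappa, tau = tau), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params> p=%.4g kappa=%.4g tau=%.4g ms\n",
              x$p, x$kappa, x$tau))
  invisible(x)
}

#' Interior bump fixed point
#'
#' A stationary radially symmetric bump has constant interior values
#' \eqn{f = p/(1+2p)}, \eqn{h = 1/(1+2p)} and is zero outside its radius.
#' These interior values are an exact fixed point of the field equations with
#' the firing nonlinearity active.
#'
#' @param rho bump radius (field units).
#' @param model a \code{\link{model_params}} object.
#' @param branch optional branch label (\code{"smaller"} or \code{"larger"}).
#' @return an object of class \code{bump_solution} with fields \code{rho},
#'   \code{f_in}, \code{h_in}, \code{branch}.
#' @export
bump_profile <- function(rho, model, branch = NA_character_) {
  stopifnot(rho > 0)
  p <- model$p
  structure(list(rho = rho, f_in = p / (1 + 2 * p), h_in = 1 / (1 + 2 * p),
                 branch = branch, growth_rate = NA_real_),
            class = "bump_solution")
}

#' @export
print.bump_solution <- function(x, ...) {
  cat(sprintf("<bump_solution> rho=%.5g f_in=%.5g h_in=%.5g branch=%s\n",
              x$rho, x$f_in, x$h_in, x$branch))
  invisible(x)
}

# Integral of w over a disc of radius rho, evaluated at a point on the disc
# boundary: I(rho) = int_0^rho r' int_0^{2pi} w(d) dtheta dr' with
# d = sqrt(rho^2 + r'^2 - 2 rho r' cos theta). The integrand is bounded (the
# Bessel difference has a finite limit at zero separation), so fixed-order
# Gauss-Legendre on both axes converges fast; order 160 is well past the
# 1e-8 level for kernels at the spatial scales used here.
disc_boundary_integral <- function(rho, params, n = 120) {
  gl_t <- pracma::gaussLegendre(n, 0, pi)
  gl_r <- pracma::gaussLegendre(n, 0, rho)
  ct <- cos(gl_t$x)
  d2 <- outer(gl_r$x^2, rep(1, n)) + rho^2 -
    2 * rho * outer(gl_r$x, ct)
  d <- sqrt(pmax(d2, 0))
  wv <- matrix(eval_kernel(as.vector(d), params), n, n)
  # factor 2: theta integral over (0, pi) doubled by symmetry
  2 * sum((gl_r$w * gl_r$x) %*% t(gl_t$w) * wv)
}

#' Bump existence residual
#'
#' Left-hand side of the bump existence condition
#' \deqn{\frac{p}{1+2p}\left[\oint_{disc} w - 2\kappa\right] - \kappa,}
#' where the integral is the synaptic weight collected over the bump disc at
#' a boundary point. The raw boundary synaptic input
#' \eqn{u(\rho) = f_{in} \oint_{disc} w} is attached as attribute \code{u},
#' and the crossing level it is compared against,
#' \eqn{u^* = \kappa(1+4p)/(1+2p)}, as attribute \code{u_star}. The residual
#' is zero exactly where \eqn{u(\rho)} crosses \eqn{u^*}.
#'
#' @param rho bump radius (field units), may be a vector.
#' @param params a \code{\link{kernel_params}} object.
#' @param model a \code{\link{model_params}} object.
#' @return residual value(s); attributes \code{u}, \code{u_star}.
#' @export
bump_existence_residual <- function(rho, params, model) {
  stopifnot(all(rho > 0))
  p <- model$p; kappa <- model$kappa
  f_in <- p / (1 + 2 * p)
  I <- vapply(rho, disc_boundary_integral, numeric(1), params = params)
  res <- f_in * (I - 2 * kappa) - kappa
  attr(res, "u") <- f_in * I
  attr(res, "u_star") <- kappa * (1 + 4 * p) / (1 + 2 * p)
  res
}

#' Solve for bump radii
#'
#' Finds all roots of the bump existence residual on \eqn{(0, 20\sigma_I]} by
#' sign-change bracketing on a log-spaced radial grid followed by bisection.
#' At most two roots occur for a Mexican-hat kernel (the boundary-input curve
#' is concave): the smaller-radius root is the unstable branch, the larger
#' the stable one.
#'
#' @inheritParams bump_existence_residual
#' @param n_grid number of scan radii.
#' @return a list of \code{bump_solution} objects (possibly empty), sorted by
#'   radius, with \code{branch} set to \code{"smaller"} / \code{"larger"}.
#' @export
solve_bump_radii <- function(params, model, n_grid = 200) {
  r_max <- 20 * max(params$sigma_E, params$sigma_I)
  r_grid <- exp(seq(log(0.05), log(r_max), length.out = n_grid))
  res <- bump_existence_residual(r_grid, params, model)
  s <- sign(res)
  flips <- which(diff(s) != 0 & s[-length(s)] != 0)
  roots <- vapply(flips, function(i) {
    stats::uniroot(function(r) as.numeric(bump_existence_residual(r, params, model)),
                   lower = r_grid[i], upper = r_grid[i + 1],
                   tol = 1e-10 * r_grid[i + 1])$root
  }, numeric(1))
  roots <- sort(roots)
  if (length(roots) == 0L) return(list())
  branches <- if (length(roots) == 1L) {
    # classify by slope sign: rising residual => unstable small-bump branch
    eps <- 1e-4 * roots
    dr <- as.numeric(bump_existence_residual(roots + eps, params, model)) -
      as.numeric(bump_existence_residual(roots - eps, params, model))
    if (dr > 0) "smaller" else "larger"
  } else c("smaller", rep("larger", length(roots) - 1L))
  mapply(function(r, b) bump_profile(r, model, branch = b),
         roots, branches, SIMPLIFY = FALSE)
}

# ---- 1D traveling waves ------------------------------------------------

#' Profile coefficients of the 1D traveling wave
#'
#' For refractory rate \eqn{p < 4} the comoving-frame profile oscillates with
#' decay rate \eqn{\alpha = (2+p)/2} and frequency
#' \eqn{\beta = \sqrt{p(4-p)}/2}; the mixing coefficients are
#' \eqn{A = (2-\alpha+1/p)/\beta} and
#' \eqn{B = \{\alpha - 2 - p[(\alpha-2)^2+\beta^2]\}/\beta}.
#'
#' @param p refractory recovery rate, must satisfy \eqn{0 < p < 4}.
#' @return list with \code{alpha}, \code{beta}, \code{A}, \code{B}.
#' @export
wave1d_coeffs <- function(p) {
  if (p >= 4) stop("profile coefficients require p < 4 (oscillatory regime)")
  if (p <= 0) stop("p must be strictly positive")
  alpha <- (2 + p) / 2
  beta <- sqrt(p * (4 - p)) / 2
  A <- (2 - alpha + 1 / p) / beta
  B <- (alpha - 2 - p * ((alpha - 2)^2 + beta^2)) / beta
  list(alpha = alpha, beta = beta, A = A, B = B)
}

#' 1D traveling-wave object
#'
#' @param c wave speed (field units per rescaled time), positive.
#' @param L wave length (field units), positive.
#' @param model a \code{\link{model_params}} object (supplies \code{p}).
#' @param objective boundary-residual objective achieved (if solved).
#' @param converged logical convergence flag.
#' @return object of class \code{wave1d}.
#' @export
wave1d <- function(c, L, model, objective = NA_real_, converged = NA) {
  stopifnot(c > 0, L > 0)
  co <- wave1d_coeffs(model$p)
  structure(c(list(c = c, L = L, p = model$p), co,
              list(objective = objective, converged = converged)),
            class = "wave1d")
}

#' @export
print.wave1d <- function(x, ...) {
  cat(sprintf("<wave1d> c=%.5g L=%.5g p=%.3g objective=%.3g\n",
              x$c, x$L, x$p, x$objective))
  invisible(x)
}

#' Evaluate the 1D traveling-wave profile
#'
#' Piecewise comoving-frame profile of the firing fraction \eqn{F} and
#' refractory deficit \eqn{H}, with the wave front at the origin and motion
#' toward positive \eqn{x}: zero ahead of the front, a damped oscillation
#' about the interior fixed point on the active stretch \eqn{[-L, 0]}, and an
#' exponential recovery tail behind it. On the active stretch
#' \deqn{F(x) = f_{in}\{1 - e^{\alpha x/c}[\cos(\beta x/c) +
#'   A\sin(\beta x/c)]\}}
#' (and likewise \eqn{H} with \eqn{B}): with the coefficient conventions of
#' \code{\link{wave1d_coeffs}} the sine terms enter with a plus sign, which
#' is the unique choice satisfying the comoving-frame equations
#' \eqn{-cF' = -2F - H + 1}, \eqn{-cH' = F - pH} together with
#' \eqn{F(0) = H(0) = 0} (equivalently \eqn{F'(0) = -1/c}); the package's
#' test suite verifies the residual numerically.
#'
#' @param x position(s) in the wave frame (field units).
#' @param wave a \code{\link{wave1d}} object.
#' @param model a \code{\link{model_params}} object.
#' @return list with vectors \code{F} and \code{H} matching \code{x}.
#' @export
wave1d_profile <- function(x, wave, model) {
  p <- model$p
  if (abs(p - 1) < 1e-12) stop("tail branch is singular at p = 1")
  co <- wave1d_coeffs(p)
  cc <- wave$c; L <- wave$L
  f_in <- p / (1 + 2 * p); h_in <- 1 / (1 + 2 * p)
  Fv <- numeric(length(x)); Hv <- numeric(length(x))
  mid <- x <= 0 & x >= -L
  xm <- x[mid]
  e <- exp(co$alpha * xm / cc)
  Fv[mid] <- f_in * (1 - e * (cos(co$beta * xm / cc) + co$A * sin(co$beta * xm / cc)))
  Hv[mid] <- h_in * (1 - e * (cos(co$beta * xm / cc) + co$B * sin(co$beta * xm / cc)))
  # matching values at the tail boundary
  eL <- exp(-co$alpha * L / cc)
  F_L <- f_in * (1 - eL * (cos(co$beta * L / cc) - co$A * sin(co$beta * L / cc)))
  H_L <- h_in * (1 - eL * (cos(co$beta * L / cc) - co$B * sin(co$beta * L / cc)))
  # tail: -cF' = -F and -cH' = -pH + F with H -> 0 far behind the wave
  tail <- x < -L
  xt <- x[tail]
  Fv[tail] <- F_L * exp((xt + L) / cc)
  Hv[tail] <- (H_L + F_L / (1 - p)) * exp(p * (xt + L) / cc) -
    F_L / (1 - p) * exp((xt + L) / cc)
  list(F = Fv, H = Hv)
}

# Boundary synaptic inputs of the 1D wave: u(0) and u(-L), line convolution
# of the kernel with the profile, truncated deep in the exponential tail.
wave1d_boundary_inputs <- function(c, L, params, model) {
  wv <- wave1d(c, L, model)
  lower <- -L - max(40 * c, 20 * max(params$sigma_E, params$sigma_I))
  Ff <- function(x) wave1d_profile(x, wv, model)$F
  u_at <- function(x0) {
    f <- function(x) eval_kernel(abs(x - x0), params) * Ff(x)
    i1 <- stats::integrate(f, -L, 0, rel.tol = 1e-9, abs.tol = 1e-12,
                           subdivisions = 400L)$value
    i2 <- stats::integrate(f, lower, -L, rel.tol = 1e-9, abs.tol = 1e-12,
                           subdivisions = 400L)$value
    i1 + i2
  }
  c(u0 = u_at(0), uL = u_at(-L))
}

#' Solve for 1D traveling-wave speed and length
#'
#' Finds \eqn{(c, L)} such that the synaptic input at both wave boundaries
#' equals the firing threshold, by minimizing the summed squared boundary
#' residuals \eqn{(u(0)-\kappa)^2 + (u(-L)-\kappa)^2} with Nelder-Mead over
#' \eqn{(\log c, \log L)} from a deterministic Latin-hypercube multi-start
#' over \eqn{c \in (0.1, 50)}, \eqn{L \in (0.1, 30)}.
#'
#' @param params a \code{\link{kernel_params}} object.
#' @param model a \code{\link{model_params}} object.
#' @param init optional numeric \code{c(c, L)} initial guess, tried first.
#' @param n_starts multi-start budget.
#' @param seed integer seed making the multi-start deterministic.
#' @param tol convergence tolerance on the objective relative to
#'   \eqn{\kappa^2}.
#' @return a list of converged \code{\link{wave1d}} solutions sorted by
#'   \code{(c, L)} (largest last; distinct minima deduplicated). Errors with
#'   the best candidate attached if nothing converges.
#' @export
solve_wave1d <- function(params, model, init = NULL, n_starts = 15L,
                         seed = 1L, tol = 1e-10) {
  kappa <- model$kappa
  obj <- function(th) {
    cL <- exp(th)
    if (cL[1] > 200 || cL[2] > 100) return(1e6)
    u <- tryCatch(wave1d_boundary_inputs(cL[1], cL[2], params, model),
                  error = function(e) NULL)
    if (is.null(u)) return(1e6)
    (u[["u0"]] - kappa)^2 + (u[["uL"]] - kappa)^2
  }
  set.seed(as.integer(seed) %% .Machine$integer.max)
  starts <- lhs::randomLHS(n_starts, 2)
  starts <- cbind(0.1 * (50 / 0.1)^starts[, 1], 0.1 * (30 / 0.1)^starts[, 2])
  if (!is.null(init)) starts <- rbind(matrix(init, 1), starts)
  sols <- list()
  best <- NULL; best_obj <- Inf
  for (k in seq_len(nrow(starts))) {
    fit <- stats::optim(log(starts[k, ]), obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-14))
    if (fit$value < best_obj) {
      best_obj <- fit$value
      best <- exp(fit$par)
    }
    if (fit$value < tol * kappa^2) {
      cL <- exp(fit$par)
      dup <- any(vapply(sols, function(s)
        abs(s$c - cL[1]) < 1e-3 * cL[1] && abs(s$L - cL[2]) < 1e-3 * cL[2],
        logical(1)))
      if (!dup)
        sols[[length(sols) + 1L]] <- wave1d(cL[1], cL[2], model,
                                            objective = fit$value,
                                            converged = TRUE)
    }
  }
  if (length(sols) == 0L) {
    e <- simpleError(sprintf(
      "unconverged: best objective %.3g at c=%.4g L=%.4g", best_obj,
      best[1], best[2]))
    e$best <- best
    stop(e)
  }
  ord <- order(vapply(sols, `[[`, numeric(1), "c"),
               vapply(sols, `[[`, numeric(1), "L"))
  sols[ord]
}

#' Shift-perturbation growth rate of a bump
#'
#' Estimates the instability of a stable-branch bump to translation (shift)
#' perturbations by direct simulation: the rasterized bump is displaced by a
#' small sub-grid shift (spectral translation, so the perturbation is
#' smooth), integrated without noise, and the exponential growth rate of the
#' center-of-mass displacement is fitted on the window where the displacement
#' grows from \code{d_lo} to \code{d_hi} grid cells.
#'
#' @param bump a \code{bump_solution}, normally from the larger branch.
#' @param params a \code{\link{kernel_params}} object.
#' @param model a \code{\link{model_params}} object.
#' @param n grid cells per side of the simulation domain.
#' @param spacing grid step (field units).
#' @param dt integration step (rescaled time).
#' @param t_max simulation horizon (rescaled time).
#' @param shift initial displacement in grid cells.
#' @param d_lo,d_hi displacement window (grid cells) used for the log-linear
#'   fit.
#' @return growth rate per rescaled time (attribute \code{displacement}
#'   carries the tracked series). Returns \code{NA} with attribute
#'   \code{flag = "indistinguishable from zero"} when the displacement never
#'   leaves the measurement floor.
#' @export
shift_growth_rate <- function(bump, params, model, n = 128, spacing = 1,
                              dt = 0.01, t_max = 8, shift = 0.2,
                              d_lo = 0.01, d_hi = 1) {
  cfg <- sim_config(n = n, spacing = spacing, dt = dt, duration = t_max,
                    stride = max(1L, round(0.05 / dt)), kernel = params,
                    model = model, noise = noise_spec(0))
  st <- make_initial("bump", cfg, bump = bump)
  ctr <- c(n / 2, n / 2) * cfg$spacing
  cl <- clamp_state(fourier_shift(st$f, shift, 0),
                    fourier_shift(st$h, shift, 0))
  st <- field_state(cl$f, cl$h, cfg$spacing)
  mv <- simulate_field(st, cfg)
  disp <- vapply(seq_along(mv$times), function(i) {
    fr <- list(f = mv$f[, , i], spacing = cfg$spacing)
    comps <- label_patterns(fr, 0.5, f_in = bump$f_in)
    if (length(comps) == 0L) return(NA_real_)
    com <- center_of_mass(comps[[1]], fr)
    sqrt(sum(periodic_delta(com, ctr, n * cfg$spacing)^2))
  }, numeric(1)) / cfg$spacing
  rate <- fit_growth_rate(mv$times, disp, d_lo, d_hi)
  attr(rate, "displacement") <- disp
  attr(rate, "times") <- mv$times
  rate
}

#' Fit an exponential growth rate to a displacement series
#'
#' Least-squares slope of log displacement against time over the window
#' where the displacement lies in \code{[d_lo, d_hi]} (same units as
#' \code{disp}); the window excludes both the sub-measurement floor and the
#' nonlinear saturation regime.
#'
#' @param times sample times.
#' @param disp non-negative displacement series (may contain NA).
#' @param d_lo,d_hi fitting window bounds.
#' @return growth rate per time unit; \code{NA} with attribute
#'   \code{flag = "indistinguishable from zero"} if fewer than 3 samples
#'   fall inside the window.
#' @export
fit_growth_rate <- function(times, disp, d_lo = 0.01, d_hi = 1) {
  ok <- which(is.finite(disp) & disp >= d_lo & disp <= d_hi)
  if (length(ok) < 3) {
    out <- NA_real_
    attr(out, "flag") <- "indistinguishable from zero"
    return(out)
  }
  fit <- stats::lm(log(disp[ok]) ~ times[ok])
  unname(stats::coef(fit)[2])
}
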