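# Direct numerical integration of the two-variable refractory neural field
#   df/dt = -f + (1 - f - h) H(u - kappa) [+ mu]
#   dh/dt = -p h + f                      [- mu]
# on a periodic square lattice, with u = w * f computed by FFT circular
# convolution and mu = f * xi an optional multiplicative Gaussian noise term.

#' Field state on a periodic grid
#'
#' @param f firing-probability matrix.
#' @param h refractory-deficit matrix (same shape as \code{f}).
#' @param spacing grid step in field units.
#' @param time current time (rescaled units).
#' @return object of class \code{field_state}. Invariants \code{f >= 0},
#'   \code{h >= 0}, \code{f + h <= 1} are validated.
#' @export
field_state <- function(f, h, spacing = 1, time = 0) {
  if (!all(dim(f) == dim(h))) stop("f and h grids must share shape")
  if (min(f) < 0 || min(h) < 0 || max(f + h) > 1 + 1e-12)
    stop("field invariants violated: need f >= 0, h >= 0, f + h <= 1")
  structure(list(f = f, h = h, spacing = spacing, time = time,
                 domain = nrow(f) * spacing),
            class = "field_state")
}

#' Noise specification
#'
#' @param sigma_xi standard deviation of the zero-mean Gaussian white noise
#'   \eqn{\xi}; the injected term is multiplicative, \eqn{\mu = f\,\xi}, so
#'   quiescent regions stay quiescent.
#' @param seed integer RNG seed.
#' @param mode \code{"off"}, \code{"single_kick"} (one additive i.i.d.
#'   Gaussian perturbation of \code{f} at the start) or \code{"continuous"}
#'   (a fresh \eqn{\mu} grid each step, held fixed across the four
#'   Runge-Kutta stages).
#' @export
noise_spec <- function(sigma_xi = 0, seed = 1L,
                       mode = c("off", "single_kick", "continuous")) {
  mode <- match.arg(mode)
  if (sigma_xi < 0) stop("sigma_xi must be non-negative")
  structure(list(sigma_xi = sigma_xi, seed = as.integer(seed), mode = mode),
            class = "noise_spec")
}

#' Simulation configuration
#'
#' Defaults mirror the reference setup: 601x601 cells at 0.1 mm spacing (one
#' field unit per cell), 0.1 ms steps i.e. \code{dt = 0.01} in rescaled time
#' with \eqn{\tau} = 10 ms, \eqn{\kappa = 1}, \eqn{p = 0.42}.
#'
#' @param n cells per side.
#' @param spacing grid step (field units).
#' @param dt time step (rescaled time).
#' @param duration total simulated time (rescaled).
#' @param stride snapshot stride in steps.
#' @param kernel a \code{\link{kernel_params}} object.
#' @param model a \code{\link{model_params}} object.
#' @param noise a \code{\link{noise_spec}} object.
#' @param store_h keep \code{h} snapshots in the movie (memory heavy).
#' @export
sim_config <- function(n = 601L, spacing = 1, dt = 0.01, duration = 1,
                       stride = 10L, kernel, model = model_params(),
                       noise = noise_spec(0), store_h = TRUE) {
  stopifnot(dt > 0, duration >= 0, n >= 8, spacing > 0, stride >= 1)
  structure(list(n = as.integer(n), spacing = spacing, dt = dt,
                 duration = duration, stride = as.integer(stride),
                 kernel = kernel, model = model, noise = noise,
                 store_h = isTRUE(store_h)),
            class = "sim_config")
}

#' Sample the coupling kernel on the periodic lattice
#'
#' Kernel image with the origin at index (1, 1) and wrap-around
#' minimal-image distances, scaled by the cell area so that circular
#' convolution approximates the continuous convolution. By default each
#' lattice weight is the cell-averaged kernel (4-point Gauss-Legendre per
#' axis): at the reference resolution the kernel's central peak is only a
#' couple of cells wide, and midpoint sampling misrepresents the delicate
#' excitation/inhibition balance that the wave solutions live on.
#'
#' @param config a \code{\link{sim_config}}.
#' @param cell_average integrate the kernel over each cell (default) rather
#'   than sampling at cell centers.
#' @return list with the kernel matrix \code{k} and its FFT \code{k_hat}.
#' @export
kernel_grid <- function(config, cell_average = TRUE) {
  n <- config$n; sp <- config$spacing
  # signed minimal-image coordinates of cell centers
  s1 <- (((0:(n - 1)) + n %/% 2) %% n - n %/% 2) * sp
  if (!cell_average) {
    dist <- sqrt(outer(s1^2, s1^2, "+"))
    k <- matrix(eval_kernel(as.vector(dist), config$kernel), n, n) * sp^2
  } else {
    gl <- pracma::gaussLegendre(4, -sp / 2, sp / 2)
    k <- matrix(0, n, n)
    for (a in 1:4) for (b in 1:4) {
      dist <- sqrt(outer((s1 + gl$x[a])^2, (s1 + gl$x[b])^2, "+"))
      k <- k + gl$w[a] * gl$w[b] *
        matrix(eval_kernel(as.vector(dist), config$kernel), n, n)
    }
  }
  list(k = k, k_hat = stats::fft(k))
}

#' Synaptic input by circular convolution
#'
#' @param f firing grid.
#' @param kg kernel grid from \code{\link{kernel_grid}} (or any list with
#'   \code{k_hat} of matching shape).
#' @return the synaptic input grid \eqn{u = w * f}.
#' @export
synaptic_input <- function(f, kg) {
  if (!all(dim(f) == dim(kg$k_hat))) stop("grid shape mismatch")
  Re(stats::fft(stats::fft(f) * kg$k_hat, inverse = TRUE)) / length(f)
}

# Right-hand side of the field equations. mu is the (fixed) noise grid.
field_rhs <- function(f, h, kg, model, mu = NULL) {
  u <- synaptic_input(f, kg)
  H <- (u >= model$kappa) * 1
  df <- -f + (1 - f - h) * H
  dh <- -model$p * h + f
  if (!is.null(mu)) {
    df <- df + mu
    dh <- dh - mu
  }
  list(df = df, dh = dh)
}

clamp_state <- function(f, h) {
  n_bad <- sum(f < 0 | f > 1 | h < 0 | h > 1 | f + h > 1)
  f <- pmin(pmax(f, 0), 1)
  h <- pmin(pmax(h, 0), 1)
  over <- f + h > 1
  h[over] <- 1 - f[over]
  list(f = f, h = h, clamped = n_bad)
}

#' One classical fourth-order Runge-Kutta step
#'
#' In continuous-noise mode a fresh multiplicative noise grid
#' \eqn{\mu = f\,\xi} (from the state at the start of the step) is added to
#' \eqn{df/dt} and subtracted from \eqn{dh/dt}, held fixed within the four
#' stages. Probabilistic bounds are restored by clamping afterwards; the
#' clamp count is attached as attribute \code{clamped}.
#'
#' @param state a \code{\link{field_state}}.
#' @param config a \code{\link{sim_config}}.
#' @param kg precomputed \code{\link{kernel_grid}} (recomputed if missing).
#' @return the advanced \code{field_state}.
#' @export
rk4_step <- function(state, config, kg = kernel_grid(config)) {
  dt <- config$dt
  model <- config$model
  mu <- NULL
  if (config$noise$mode == "continuous" && config$noise$sigma_xi > 0) {
    xi <- matrix(stats::rnorm(length(state$f), 0, config$noise$sigma_xi),
                 nrow(state$f))
    mu <- state$f * xi
  }
  f <- state$f; h <- state$h
  k1 <- field_rhs(f, h, kg, model, mu)
  k2 <- field_rhs(f + dt / 2 * k1$df, h + dt / 2 * k1$dh, kg, model, mu)
  k3 <- field_rhs(f + dt / 2 * k2$df, h + dt / 2 * k2$dh, kg, model, mu)
  k4 <- field_rhs(f + dt * k3$df, h + dt * k3$dh, kg, model, mu)
  fn <- f + dt / 6 * (k1$df + 2 * k2$df + 2 * k3$df + k4$df)
  hn <- h + dt / 6 * (k1$dh + 2 * k2$dh + 2 * k3$dh + k4$dh)
  if (any(!is.finite(fn)) || any(!is.finite(hn)))
    stop(sprintf("non-finite field values at t = %.4g; aborting", state$time))
  cl <- clamp_state(fn, hn)
  out <- field_state(cl$f, cl$h, state$spacing, state$time + dt)
  attr(out, "clamped") <- cl$clamped
  out
}

#' Simulate the neural field
#'
#' Integrates from an initial state for \code{config$duration} rescaled time
#' units, recording snapshots every \code{config$stride} steps (the initial
#' state is always frame 1). Runs are reproducible: the noise seed is applied
#' at entry.
#'
#' @param initial a \code{\link{field_state}}.
#' @param config a \code{\link{sim_config}}.
#' @return a \code{field_movie}: list with 3D array \code{f} (and \code{h}
#'   if \code{store_h}), vector \code{times}, the \code{config}, total
#'   \code{clamp_count} and the applied \code{seed}.
#' @export
simulate_field <- function(initial, config) {
  n <- nrow(initial$f)
  if (n != config$n) stop("initial state does not match configured grid size")
  kg <- kernel_grid(config)
  n_steps <- round(config$duration / config$dt)
  snap_at <- unique(c(0L, seq_len(n_steps)[seq_len(n_steps) %% config$stride == 0L],
                      n_steps))
  n_snap <- length(snap_at)
  fa <- array(NA_real_, c(n, n, n_snap))
  ha <- if (config$store_h) array(NA_real_, c(n, n, n_snap)) else NULL
  times <- numeric(n_snap)
  set.seed(config$noise$seed)
  st <- initial
  if (config$noise$mode == "single_kick" && config$noise$sigma_xi > 0) {
    f2 <- st$f + matrix(stats::rnorm(length(st$f), 0, config$noise$sigma_xi),
                        n)
    cl <- clamp_state(f2, st$h)
    st <- field_state(cl$f, cl$h, st$spacing, st$time)
  }
  clamp_count <- 0L
  si <- 1L
  record <- function(i, s) {
    fa[, , i] <<- s$f
    if (config$store_h) ha[, , i] <<- s$h
    times[i] <<- s$time
  }
  record(si, st)
  if (n_steps > 0) {
    for (step in seq_len(n_steps)) {
      st <- rk4_step(st, config, kg)
      clamp_count <- clamp_count + attr(st, "clamped")
      if (step %in% snap_at) {
        si <- si + 1L
        record(si, st)
      }
    }
  }
  structure(list(f = fa, h = ha, times = times, config = config,
                 clamp_count = clamp_count, seed = config$noise$seed,
                 n_steps = n_steps),
            class = "field_movie")
}

#' @export
print.field_movie <- function(x, ...) {
  cat(sprintf("<field_movie> %dx%d grid, %d frames, t in [%.3g, %.3g], %d clamped cells\n",
              dim(x$f)[1], dim(x$f)[2], dim(x$f)[3], x$times[1],
              x$times[length(x$times)], x$clamp_count))
  invisible(x)
}

# Spectral (Fourier phase) translation of a periodic grid by fractional
# cells; used for smooth sub-grid shift perturbations.
fourier_shift <- function(m, dx, dy) {
  n1 <- nrow(m); n2 <- ncol(m)
  k1 <- c(0:floor(n1 / 2), -(ceiling(n1 / 2) - 1):-1)[1:n1]
  k2 <- c(0:floor(n2 / 2), -(ceiling(n2 / 2) - 1):-1)[1:n2]
  ph <- exp(-2i * pi * (outer(k1 * dx / n1, k2 * dy / n2, "+")))
  Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / (n1 * n2)
}

# Signed minimal-image displacement a - b on a periodic interval of length L.
periodic_delta <- function(a, b, L) {
  d <- a - b
  d - L * round(d / L)
}

#' Build initial field states
#'
#' @param kind one of \code{"bump"}, \code{"wave1d_strip"}, \code{"wave2d"},
#'   \code{"random_waves"}.
#' @param config a \code{\link{sim_config}}.
#' @param bump a \code{bump_solution} (for \code{kind = "bump"}).
#' @param wave a \code{\link{wave1d}} (for \code{"wave1d_strip"}).
#' @param shape a \code{\link{wave2d_shape}} (for \code{"wave2d"} and
#'   \code{"random_waves"}).
#' @param n_waves number of waves for \code{"random_waves"}.
#' @param seed placement seed for \code{"random_waves"}.
#' @param center,direction optional center coordinates and unit direction
#'   for single-pattern kinds; defaults are the domain center and +x.
#' @return a \code{\link{field_state}}.
#' @export
make_initial <- function(kind = c("bump", "wave1d_strip", "wave2d",
                                  "random_waves"),
                         config, bump = NULL, wave = NULL, shape = NULL,
                         n_waves = 7L, seed = 1L, center = NULL,
                         direction = c(1, 0)) {
  kind <- match.arg(kind)
  n <- config$n; sp <- config$spacing
  L_dom <- n * sp
  if (is.null(center)) center <- c(L_dom / 2, L_dom / 2)
  xs <- (seq_len(n) - 1) * sp
  if (kind == "bump") {
    if (is.null(bump)) stop("bump solution required")
    dx <- periodic_delta(xs, center[1], L_dom)
    dy <- periodic_delta(xs, center[2], L_dom)
    r <- sqrt(outer(dx^2, dy^2, "+"))
    inside <- r < bump$rho
    f <- matrix(0, n, n); h <- matrix(0, n, n)
    f[inside] <- bump$f_in
    h[inside] <- bump$h_in
    return(field_state(f, h, sp))
  }
  if (kind == "wave1d_strip") {
    if (is.null(wave)) stop("wave1d solution required")
    xrel <- periodic_delta(xs, center[1], L_dom)
    pr <- wave1d_profile(xrel, wave, config$model)
    # cut the tail where it would wrap into the front
    cut <- xrel > 0 | xrel < -0.45 * L_dom
    pr$F[cut] <- 0; pr$H[cut] <- 0
    f <- matrix(pr$F, n, n)
    h <- matrix(pr$H, n, n)
    return(field_state(pmax(f, 0), pmax(h, 0), sp))
  }
  if (kind == "wave2d") {
    if (is.null(shape)) stop("wave2d_shape required")
    return(build_wave2d_state(shape, config$model, config, direction,
                              center))
  }
  # random_waves: n fitted waves, uniform random positions/orientations,
  # rejection sampling to keep pairwise clearance >= 2 sigma_I
  if (is.null(shape)) stop("wave2d_shape required")
  set.seed(as.integer(seed))
  extent <- max(shape$L_f, wave2d_tail_reach(shape), shape$L_w)
  clearance <- 2 * extent + 2 * config$kernel$sigma_I
  centers <- matrix(NA_real_, n_waves, 2)
  angles <- numeric(n_waves)
  placed <- 0L
  tries <- 0L
  while (placed < n_waves) {
    tries <- tries + 1L
    if (tries > 1000L) stop("packing error: cannot place waves without overlap")
    cand <- stats::runif(2, 0, L_dom)
    ok <- TRUE
    if (placed > 0) {
      for (j in seq_len(placed)) {
        d <- periodic_delta(cand, centers[j, ], L_dom)
        if (sqrt(sum(d^2)) < clearance) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    placed <- placed + 1L
    centers[placed, ] <- cand
    angles[placed] <- stats::runif(1, 0, 2 * pi)
  }
  f <- matrix(0, n, n); h <- matrix(0, n, n)
  for (j in seq_len(n_waves)) {
    stj <- build_wave2d_state(shape, config$model, config,
                              c(cos(angles[j]), sin(angles[j])),
                              centers[j, ])
    f <- f + stj$f
    h <- h + stj$h
  }
  cl <- clamp_state(f, h)
  field_state(cl$f, cl$h, sp)
}

# ---- 1D periodic line simulator (oracle for the 1D wave solver) --------

#' Simulate the field on a 1D periodic line
#'
#' Same two-variable dynamics restricted to one spatial dimension, with the
#' kernel evaluated on the line (\eqn{w(|x|)}) and circular FFT convolution.
#' Used to verify that solved 1D traveling waves propagate at their solved
#' speed.
#'
#' @param f,h initial profiles (numeric vectors of equal length).
#' @param params a \code{\link{kernel_params}}.
#' @param model a \code{\link{model_params}}.
#' @param spacing,dt,duration,stride discretization controls (rescaled time).
#' @return list with matrix \code{f} (frames in columns), \code{times},
#'   \code{spacing}.
#' @export
simulate_line <- function(f, h, params, model, spacing = 1, dt = 0.01,
                          duration = 10, stride = 10L) {
  n <- length(f)
  s1 <- (((0:(n - 1)) + n %/% 2) %% n - n %/% 2) * spacing
  # exact cell integrals of the line kernel: the resolution is comparable
  # to sigma_E, and the near-cancelling E/I balance needs them
  rng <- 20 * max(params$sigma_E, params$sigma_I)
  kv <- vapply(s1, function(x) {
    if (abs(x) - spacing / 2 > rng) return(0)
    stats::integrate(function(z) eval_kernel(abs(z), params),
                     x - spacing / 2, x + spacing / 2,
                     rel.tol = 1e-10, abs.tol = 1e-13)$value
  }, numeric(1))
  k_hat <- stats::fft(kv)
  conv1 <- function(v) Re(stats::fft(stats::fft(v) * k_hat, inverse = TRUE)) / n
  rhs <- function(f, h) {
    H <- (conv1(f) >= model$kappa) * 1
    list(df = -f + (1 - f - h) * H, dh = -model$p * h + f)
  }
  n_steps <- round(duration / dt)
  keep <- unique(c(0L, seq_len(n_steps)[seq_len(n_steps) %% stride == 0L]))
  fa <- matrix(NA_real_, n, length(keep))
  times <- numeric(length(keep))
  si <- 1L; fa[, 1] <- f; times[1] <- 0
  for (step in seq_len(n_steps)) {
    k1 <- rhs(f, h)
    k2 <- rhs(f + dt / 2 * k1$df, h + dt / 2 * k1$dh)
    k3 <- rhs(f + dt / 2 * k2$df, h + dt / 2 * k2$dh)
    k4 <- rhs(f + dt * k3$df, h + dt * k3$dh)
    f <- f + dt / 6 * (k1$df + 2 * k2$df + 2 * k3$df + k4$df)
    h <- h + dt / 6 * (k1$dh + 2 * k2$dh + 2 * k3$dh + k4$dh)
    f <- pmin(pmax(f, 0), 1); h <- pmin(pmax(h, 0), 1 - f)
    if (step %in% keep) {
      si <- si + 1L
      fa[, si] <- f
      times[si] <- step * dt
    }
  }
  list(f = fa, times = times, spacing = spacing)
}

#' Measure propagation speed on a 1D line movie
#'
#' Tracks the front (rightmost threshold upcrossing of \eqn{f}) with
#' periodic unwrapping and fits displacement against time.
#'
#' @param line result of \code{\link{simulate_line}}.
#' @param level threshold on \code{f} defining the front.
#' @param skip_frac fraction of initial frames discarded as transient.
#' @return fitted speed (field units per rescaled time).
#' @export
line_speed <- function(line, level = 0.05, skip_frac = 0.2) {
  n <- nrow(line$f); L <- n * line$spacing
  pos <- vapply(seq_along(line$times), function(i) {
    v <- line$f[, i]
    # front = location of maximal forward gradient crossing of the level
    idx <- which(v > level)
    if (length(idx) == 0) return(NA_real_)
    # circular mean of active region as robust position proxy
    ang <- 2 * pi * ((idx - 1) * line$spacing) / L
    wgt <- v[idx]
    atan2(sum(wgt * sin(ang)), sum(wgt * cos(ang))) %% (2 * pi) * L / (2 * pi)
  }, numeric(1))
  keep <- seq(ceiling(length(pos) * skip_frac), length(pos))
  pos <- pos[keep]; tt <- line$times[keep]
  ok <- is.finite(pos)
  pos <- pos[ok]; tt <- tt[ok]
  if (length(pos) < 5) stop("front lost: cannot measure speed")
  # unwrap
  d <- diff(pos)
  d <- d - L * round(d / L)
  disp <- cumsum(c(0, d))
  unname(stats::coef(stats::lm(disp ~ tt))[2])
}
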