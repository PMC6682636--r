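# Mexican-hat coupling kernel built from modified Bessel functions, and its
# integrated excitation/inhibition coordinates (g+, g-).

#' Kernel parameter set
#'
#' Construct and validate the four parameters of the Bessel-based Mexican-hat
#' coupling function
#' \deqn{w(r) = W_E\,w_K(r/\sigma_E) - W_I\,w_K(r/\sigma_I),\quad
#'       w_K(r) = \frac{2}{3\pi}\left[K_0(r) - K_0(2r)\right],}
#' where \eqn{K_0} is the modified Bessel function of the second kind.
#' Lengths are in field units (one unit corresponds to the 0.1 mm grid
#' resolution of the reference simulations).
#'
#' @param W_E,W_I excitatory / inhibitory coupling strengths (dimensionless,
#'   strictly positive).
#' @param sigma_E,sigma_I excitatory / inhibitory spatial scales (field
#'   length units, strictly positive).
#' @param check if \code{TRUE} (default), require the profile to pass the
#'   Mexican-hat predicate: \eqn{w > 0} on an interval \eqn{(0, r_0)} and
#'   \eqn{w < 0} beyond, with exactly one sign change.
#' @return an object of class \code{kernel_params}.
#' @examples
#' kp <- kernel_params(144.4, 73.7, 1.87, 3.24)
#' eval_kernel(0, kp)
#' @export
kernel_params <- function(W_E, W_I, sigma_E, sigma_I, check = TRUE) {
  vals <- c(W_E = W_E, W_I = W_I, sigma_E = sigma_E, sigma_I = sigma_I)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all kernel parameters must be finite and strictly positive")
  kp <- structure(as.list(vals), class = "kernel_params")
  if (check && !is_mexican_hat(kp))
    stop("parameters do not produce a Mexican-hat profile ",
         "(short-range excitation, longer-range inhibition, one sign change)")
  kp
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("<kernel_params> W_E=%.6g W_I=%.6g sigma_E=%.6g sigma_I=%.6g\n",
              x$W_E, x$W_I, x$sigma_E, x$sigma_I))
  invisible(x)
}

# Single-scale radial profile; analytic limit 2/(3*pi)*log(2) at r = 0
# (K0(x) - K0(2x) -> log 2 as x -> 0), avoiding K0's singularity.
w_bessel <- function(r) {
  out <- numeric(length(r))
  z <- r == 0
  out[z] <- 2 / (3 * pi) * log(2)
  rz <- r[!z]
  out[!z] <- 2 / (3 * pi) * (besselK(rz, 0) - besselK(2 * rz, 0))
  out
}

#' Evaluate the coupling function
#'
#' @param r radial distance(s), non-negative (field units).
#' @param params a \code{\link{kernel_params}} object.
#' @return coupling weight \eqn{w(r)}, vectorized over \code{r}.
#' @export
eval_kernel <- function(r, params) {
  if (any(r < 0)) stop("radial distance must be non-negative")
  params$W_E * w_bessel(r / params$sigma_E) -
    params$W_I * w_bessel(r / params$sigma_I)
}

# Log-spaced radial scan used by the Mexican-hat predicate and bracketing.
kernel_scan <- function(params, n = 600) {
  eps <- 1e-6 * params$sigma_E
  rmax <- 20 * max(params$sigma_E, params$sigma_I)
  r <- exp(seq(log(eps), log(rmax), length.out = n))
  list(r = r, w = eval_kernel(r, params))
}

#' Mexican-hat predicate
#'
#' Checks that \eqn{w} is positive near the origin and changes sign exactly
#' once on a log-spaced radial scan out to \eqn{20\,\max(\sigma_E,\sigma_I)}.
#'
#' @inheritParams eval_kernel
#' @return logical scalar.
#' @export
is_mexican_hat <- function(params) {
  sc <- kernel_scan(params)
  if (sc$w[1] <= 0) return(FALSE)
  s <- sign(sc$w)
  s <- s[s != 0]
  sum(diff(s) != 0) == 1L && s[length(s)] < 0
}

#' Radius of the excitation/inhibition transition
#'
#' Locates the unique positive zero crossing \eqn{r_0} of the kernel, i.e.
#' the boundary between the excitatory disc (\eqn{w > 0}) and the inhibitory
#' annulus (\eqn{w < 0}).
#'
#' @inheritParams eval_kernel
#' @return the sign-change radius \eqn{r_0} (field units), located to
#'   relative tolerance \code{1e-10}.
#' @export
zero_crossing_radius <- function(params) {
  sc <- kernel_scan(params)
  s <- sign(sc$w)
  flips <- which(diff(s) != 0 & s[-length(s)] != 0)
  if (length(flips) == 0L)
    stop("no inhibitory region: kernel has no sign change")
  if (length(flips) > 1L || sc$w[1] <= 0)
    stop("non-Mexican-hat kernel: multiple sign changes")
  i <- flips[1]
  root <- stats::uniroot(function(r) eval_kernel(r, params),
                         lower = sc$r[i], upper = sc$r[i + 1],
                         tol = 1e-10 * sc$r[i + 1])
  root$root
}

#' Integrated excitation and inhibition
#'
#' Integrates the kernel over the excitatory disc and the inhibitory annulus,
#' \deqn{g_{(+)} = \int_0^{r_0} 2\pi r\, w(r)\,dr,\qquad
#'       g_{(-)} = \int_{r_0}^{\infty} 2\pi r\, w(r)\,dr,}
#' giving the model's scalar coordinates for excitatory and inhibitory
#' feedback strength. The improper integral is truncated where the kernel has
#' decayed below \code{1e-12} of its central value (at least
#' \eqn{20\,\max(\sigma_E,\sigma_I)}; the Bessel profile decays
#' exponentially).
#'
#' @inheritParams eval_kernel
#' @return an object of class \code{ei_point}: list with \code{g_plus}
#'   (> 0), \code{g_minus} (< 0, stored signed) and \code{r0}.
#' @export
ei_integrals <- function(params) {
  r0 <- zero_crossing_radius(params)
  w0 <- abs(eval_kernel(0, params))
  rmax <- 20 * max(params$sigma_E, params$sigma_I)
  while (abs(eval_kernel(rmax, params)) > 1e-12 * w0) rmax <- rmax * 1.5
  f <- function(r) 2 * pi * r * eval_kernel(r, params)
  gp <- stats::integrate(f, 0, r0, rel.tol = 1e-10, abs.tol = 0,
                         subdivisions = 500L)
  gm <- stats::integrate(f, r0, rmax, rel.tol = 1e-10, abs.tol = 0,
                         subdivisions = 500L)
  structure(list(g_plus = gp$value, g_minus = gm$value, r0 = r0),
            class = "ei_point")
}

#' @export
print.ei_point <- function(x, ...) {
  cat(sprintf("<ei_point> g_plus=%.6g g_minus=%.6g r0=%.6g\n",
              x$g_plus, x$g_minus, x$r0))
  invisible(x)
}

# For fixed spatial scales and strength ratio q = W_I/W_E, r0 depends only on
# (q, sigma_E, sigma_I) and g+- are proportional to W_E. gamma_pm returns the
# per-unit-W_E integrals, the building block of the inversion.
gamma_pm <- function(q, sigma_E, sigma_I) {
  kp <- tryCatch(kernel_params(1, q, sigma_E, sigma_I), error = function(e) NULL)
  if (is.null(kp)) return(NULL)
  tryCatch(ei_integrals(kp), error = function(e) NULL)
}

#' Invert excitation/inhibition coordinates to kernel parameters
#'
#' Finds kernel parameters whose integrated excitation and inhibition match a
#' target \eqn{(g_{(+)}, g_{(-)})} pair. The map from four kernel parameters
#' to two coordinates is many-to-one, so the returned parameter set is one
#' feasible solution, not a unique one. The solver exploits the linearity of
#' \eqn{g_{\pm}} in the coupling strengths: for candidate spatial scales it
#' root-finds the strength ratio \eqn{q = W_I/W_E} matching the target
#' \eqn{g_{(+)}/|g_{(-)}|} ratio, then scales \eqn{W_E} to match magnitudes;
#' candidate scales are multi-started deterministically from \code{seed}.
#'
#' @param g_plus target excitatory integral (> 0).
#' @param g_minus target inhibitory integral (< 0).
#' @param init optional \code{\link{kernel_params}} whose spatial scales seed
#'   the first start.
#' @param seed integer seed for the multi-start sequence.
#' @param n_starts multi-start budget.
#' @param tol absolute tolerance required of each achieved coordinate.
#' @return a \code{kernel_params} object with attributes \code{residual}
#'   (achieved max abs deviation) and \code{achieved} (the \code{ei_point}).
#' @export
invert_ei <- function(g_plus, g_minus, init = NULL, seed = 1L,
                      n_starts = 40L, tol = 1e-6) {
  if (!is.finite(g_plus) || g_plus <= 0)
    stop("target g_plus must be strictly positive")
  if (!is.finite(g_minus) || g_minus >= 0)
    stop("target g_minus must be strictly negative")
  target_ratio <- g_plus / abs(g_minus)

  scales <- matrix(NA_real_, n_starts, 2)
  if (!is.null(init)) scales[1, ] <- c(init$sigma_E, init$sigma_I)
  i0 <- if (is.null(init)) 1L else 2L
  scales[i0, ] <- c(1.87, 3.24)
  if (i0 < n_starts) {
    set.seed(as.integer(seed) %% .Machine$integer.max)
    n_rand <- n_starts - i0
    u <- lhs::randomLHS(n_rand, 2)
    sE <- exp(log(0.4) + u[, 1] * (log(12) - log(0.4)))
    ratio <- 1.25 + u[, 2] * 3.5
    scales[(i0 + 1):n_starts, ] <- cbind(sE, sE * ratio)
  }

  best <- NULL
  best_res <- Inf
  for (k in seq_len(n_starts)) {
    sE <- scales[k, 1]; sI <- scales[k, 2]
    if (!is.finite(sE)) next
    ratio_gap <- function(q) {
      g <- gamma_pm(q, sE, sI)
      if (is.null(g)) return(NA_real_)
      g$g_plus / abs(g$g_minus) - target_ratio
    }
    qs <- seq(0.02, 0.98, length.out = 25)
    vals <- vapply(qs, ratio_gap, numeric(1))
    ok <- which(is.finite(vals))
    if (length(ok) < 2) next
    sgn <- sign(vals[ok])
    flip <- which(diff(sgn) != 0)
    if (length(flip) == 0) next
    j <- ok[flip[1]]; jj <- ok[flip[1] + 1]
    q <- tryCatch(stats::uniroot(ratio_gap, lower = qs[j], upper = qs[jj],
                                 tol = 1e-12)$root,
                  error = function(e) NA_real_)
    if (!is.finite(q)) next
    g1 <- gamma_pm(q, sE, sI)
    if (is.null(g1)) next
    W_E <- g_plus / g1$g_plus
    kp <- tryCatch(kernel_params(W_E, W_E * q, sE, sI),
                   error = function(e) NULL)
    if (is.null(kp)) next
    ach <- ei_integrals(kp)
    res <- max(abs(ach$g_plus - g_plus), abs(ach$g_minus - g_minus))
    if (res < best_res) {
      best_res <- res
      best <- kp
      attr(best, "residual") <- res
      attr(best, "achieved") <- ach
    }
    if (best_res < tol) break
  }
  if (is.null(best) || best_res >= tol)
    stop(sprintf("infeasible or unconverged: best residual %.3g after %d starts",
                 best_res, n_starts))
  best
}

#' Monte-Carlo sampling of admissible kernels
#'
#' Draws kernel parameter sets uniformly in \eqn{(0, 150)} per coordinate and
#' keeps those passing the Mexican-hat predicate, attaching the integrated
#' excitation/inhibition coordinates of each accepted draw.
#'
#' @param n number of accepted samples required.
#' @param seed integer seed; identical seeds give identical sample lists.
#' @param max_tries cap on raw draws (guards against pathological rejection).
#' @return a data.frame with columns \code{W_E, W_I, sigma_E, sigma_I,
#'   g_plus, g_minus, r0}, one row per accepted kernel.
#' @export
sample_kernels_mc <- function(n, seed = 1L, max_tries = NULL) {
  stopifnot(n > 0)
  if (is.null(max_tries)) max_tries <- max(10000L, 200L * n)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- vector("list", n)
  got <- 0L
  tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      if (got / tries < 1e-4)
        stop(sprintf("Mexican-hat acceptance rate %.2g below 1e-4; aborting",
                     got / tries))
      stop("exceeded draw budget before reaching requested sample count")
    }
    d <- stats::runif(4, 0, 150)
    kp <- tryCatch(kernel_params(d[1], d[2], d[3], d[4]),
                   error = function(e) NULL)
    if (is.null(kp)) next
    ei <- tryCatch(ei_integrals(kp), error = function(e) NULL)
    if (is.null(ei)) next
    got <- got + 1L
    out[[got]] <- data.frame(W_E = d[1], W_I = d[2], sigma_E = d[3],
                             sigma_I = d[4], g_plus = ei$g_plus,
                             g_minus = ei$g_minus, r0 = ei$r0)
  }
  df <- do.call(rbind, out)
  attr(df, "seed") <- as.integer(seed)
  attr(df, "n_draws") <- tries
  df
}
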