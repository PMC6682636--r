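# Spatiotemporal spectral analysis of field movies: radially averaged 3D
# power spectra and the distribution of propagation speeds read off along
# lines of constant velocity omega = v * f.

#' Radially averaged spatiotemporal power spectrum
#'
#' Takes the 3D DFT of the movie \eqn{f(x, y, t)} with a Hann window along
#' the temporal dimension only (the spatial dimensions are periodic and need
#' no window), forms the power (squared modulus), and averages the two
#' spatial-frequency axes over annuli one spatial-frequency cell wide
#' (bin means, so annulus area does not bias the profile). Positive and
#' negative temporal frequencies are folded by averaging, leaving one
#' spatial and one temporal axis.
#'
#' @param movie a \code{field_movie} from \code{\link{simulate_field}}, or a
#'   list with 3D array \code{f}, frame interval \code{dt_s} (seconds) and
#'   \code{spacing}.
#' @param demean subtract the global mean before transforming (default
#'   TRUE; the DC bin otherwise dominates).
#' @return object of class \code{st_spectrum}: list with
#'   \code{f_spatial} (cycles per field unit, bin centers), \code{omega}
#'   (Hz, >= 0), power matrix \code{S} (\code{length(f_spatial)} x
#'   \code{length(omega)}), and the sampling info.
#' @export
spatiotemporal_spectrum <- function(movie, demean = TRUE) {
  if (inherits(movie, "field_movie")) {
    arr <- movie$f
    dt_s <- stats::median(diff(movie$times)) * movie$config$model$tau / 1000
    spacing <- movie$config$spacing
  } else {
    arr <- movie$f
    dt_s <- movie$dt_s
    spacing <- movie$spacing
  }
  d <- dim(arr)
  if (length(d) != 3L || d[3] < 64L) stop("need a movie with at least 64 frames")
  n1 <- d[1]; n2 <- d[2]; nt <- d[3]
  if (demean) arr <- arr - mean(arr)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, nt - 1) / (nt - 1)))
  arr <- sweep(arr, 3, win, "*")
  P <- Mod(stats::fft(arr))^2
  # signed spatial frequencies (cycles per field unit)
  kx <- c(0:floor(n1 / 2), -(ceiling(n1 / 2) - 1):-1)[1:n1] / (n1 * spacing)
  ky <- c(0:floor(n2 / 2), -(ceiling(n2 / 2) - 1):-1)[1:n2] / (n2 * spacing)
  kr <- sqrt(outer(kx^2, ky^2, "+"))
  df <- 1 / (n1 * spacing)
  bin <- pmin(floor(kr / df + 0.5), floor(n1 / 2))
  n_bins <- max(bin) + 1L
  bin_counts <- tabulate(bin + 1L, nbins = n_bins)
  # fold temporal axis
  n_om <- floor(nt / 2) + 1L
  S <- matrix(0, n_bins, n_om)
  for (j in seq_len(n_om)) {
    plane <- P[, , j]
    mirror <- nt - j + 2L
    if (j > 1L && mirror <= nt && mirror != j)
      plane <- (plane + P[, , mirror]) / 2
    S[, j] <- as.numeric(tapply(as.vector(plane), as.vector(bin), mean))
  }
  omega <- (seq_len(n_om) - 1L) / (nt * dt_s)
  structure(list(f_spatial = (seq_len(n_bins) - 1L) * df, omega = omega,
                 S = S, dt_s = dt_s, spacing = spacing,
                 bin_counts = bin_counts),
            class = "st_spectrum")
}

#' @export
print.st_spectrum <- function(x, ...) {
  cat(sprintf("<st_spectrum> %d spatial bins (df=%.4g cy/unit) x %d temporal bins (up to %.4g Hz)\n",
              length(x$f_spatial), x$f_spatial[2] - x$f_spatial[1],
              length(x$omega), max(x$omega)))
  invisible(x)
}

#' Velocity-line power profile
#'
#' For each candidate speed \eqn{v}, sums over temporal frequencies
#' \eqn{\omega > 0} the linear interpolation of the spectrum along the
#' constant-velocity line \eqn{f = \omega/v} in the spatial-frequency axis.
#' A rigidly translating pattern at speed \eqn{v_0} concentrates power on
#' that line, so the profile peaks near the propagation speed; for many
#' patterns it reflects their velocity distribution. The
#' \eqn{\omega = 0} row (static structure) is excluded.
#'
#' @param spec an \code{\link{st_spectrum}}.
#' @param velocities candidate speeds in field units per second; default 100
#'   log-spaced values spanning the resolvable range (one spatial cell per
#'   movie up to one domain extent per frame).
#' @return object of class \code{velocity_power_profile}: list with
#'   \code{v}, \code{S_tot}, \code{peak_velocity}, \code{peak_power}. For an
#'   all-zero spectrum the peak fields are \code{NA} with attribute
#'   \code{flag}.
#' @export
velocity_power_profile <- function(spec, velocities = NULL) {
  f_max <- max(spec$f_spatial)
  om <- spec$omega
  pos <- which(om > 0)
  if (is.null(velocities)) {
    # one grid cell over the whole movie, floored at the slowest line that
    # still intersects the resolvable spatial band
    v_lo <- max(spec$spacing * min(om[pos]), min(om[pos]) / f_max)
    v_hi <- (2 * length(spec$f_spatial) * spec$spacing) / spec$dt_s  # domain/frame
    velocities <- exp(seq(log(v_lo), log(v_hi), length.out = 100))
  }
  if (any(velocities <= 0)) stop("velocity grid must be positive")
  if (is.unsorted(velocities)) stop("velocity grid must be increasing")
  # speeds so slow that even the lowest omega needs f beyond Nyquist are
  # unresolvable
  resolvable <- velocities >= min(om[pos]) / f_max * (1 - 1e-9)
  if (!all(resolvable)) {
    warning("trimming velocities below the resolvable range")
    velocities <- velocities[resolvable]
  }
  S_tot <- numeric(length(velocities))
  for (j in pos) {
    f_req <- om[j] / velocities
    vals <- stats::approx(spec$f_spatial, spec$S[, j], xout = f_req,
                          rule = 1)$y
    vals[!is.finite(vals)] <- 0
    S_tot <- S_tot + vals
  }
  out <- structure(list(v = velocities, S_tot = S_tot,
                        peak_velocity = NA_real_, peak_power = NA_real_),
                   class = "velocity_power_profile")
  if (all(S_tot == 0) || all(!is.finite(S_tot))) {
    attr(out, "flag") <- "zero spectrum: peak undefined"
    return(out)
  }
  i <- which.max(S_tot)
  out$peak_velocity <- velocities[i]
  out$peak_power <- S_tot[i]
  out
}

#' @export
print.velocity_power_profile <- function(x, ...) {
  cat(sprintf("<velocity_power_profile> %d speeds in [%.4g, %.4g]; peak %.4g at v=%.4g\n",
              length(x$v), min(x$v), max(x$v), x$peak_power, x$peak_velocity))
  invisible(x)
}
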