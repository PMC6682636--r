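# Desk-scale reference parameter points for the dynamical regimes, and the
# deformed-pattern seed used to nucleate a propagating wave.

#' Desk-scale regime ladder
#'
#' Three kernels from one family (\eqn{\sigma_E = 4}, \eqn{\sigma_I = 6.93}
#' field units, \eqn{W_E = 40}) that differ only in the inhibition ratio
#' \eqn{q = W_I/W_E} and realize the characteristic single-wave regimes at
#' \eqn{p = 0.42}, \eqn{\kappa = 1} on a 128-cell grid at 0.5-unit spacing:
#' strong inhibition (\eqn{q = 0.58}) sustains an isolated rotating wave,
#' intermediate (\eqn{q = 0.52}) a stable traveling wave, and weak
#' (\eqn{q = 0.45}) unstable waves that repeatedly split. The bistable
#' point between rotating and traveling regimes sits at \eqn{q = 0.54}.
#' Decreasing the inhibition ratio moves the integrated inhibition
#' \eqn{|g_{(-)}|} down the ladder, the same direction the full model
#' traverses its regime map.
#'
#' @param which one of \code{"rotating"}, \code{"traveling"},
#'   \code{"splitting"}, \code{"bistable"}.
#' @return a list with \code{kernel} (\code{\link{kernel_params}}),
#'   \code{model} (\code{\link{model_params}}), the recommended grid
#'   (\code{n}, \code{spacing}) and the expected regime label.
#' @export
regime_point <- function(which = c("rotating", "traveling", "splitting",
                                   "bistable")) {
  which <- match.arg(which)
  q <- switch(which, rotating = 0.58, traveling = 0.52, splitting = 0.45,
              bistable = 0.54)
  list(kernel = kernel_params(40, 40 * q, 4, 6.93),
       model = model_params(p = 0.42, kappa = 1, tau = 10),
       n = 128L, spacing = 0.5,
       regime = switch(which, rotating = "I", traveling = "II",
                       splitting = "III", bistable = "I/II"))
}

#' Seed a propagating wave from a deformed bump
#'
#' Builds a teardrop-shaped state sized from the stable bump solution of the
#' configured kernel (front and half-width equal to the bump radius) and
#' displaces the refractory field by a sub-grid transverse shift. The
#' asymmetry between the activity and its refractory wake nucleates
#' propagation; in the rotating regime the transverse bias also breaks the
#' left/right symmetry so the wave settles into an orbit instead of
#' stalling on the grid.
#'
#' @param config a \code{\link{sim_config}}.
#' @param c_guess speed used for the teardrop fill profile.
#' @param transverse_kick refractory-field shift in field units.
#' @param shape optional \code{\link{wave2d_shape}} overriding the
#'   bump-derived one (e.g. a fitted shape).
#' @return a \code{\link{field_state}}.
#' @export
seed_wave_state <- function(config, c_guess = 1.5, transverse_kick = 1,
                            shape = NULL) {
  if (is.null(shape)) {
    bumps <- solve_bump_radii(config$kernel, config$model)
    big <- Filter(function(b) b$branch == "larger", bumps)
    if (length(big) == 0L)
      stop("no stable bump solution to size the seed wave from")
    rho <- big[[1]]$rho
    shape <- wave2d_shape(c_guess, rho, rho, rho / 2, 0.5)
  }
  st <- make_initial("wave2d", config, shape = shape)
  if (transverse_kick != 0) {
    st$h <- fourier_shift(st$h, 0, transverse_kick / config$spacing)
    cl <- clamp_state(st$f, st$h)
    st <- field_state(cl$f, cl$h, config$spacing)
  }
  st
}
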