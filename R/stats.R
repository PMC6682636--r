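# Time-series statistics for wave kinematics: Hann-windowed periodogram,
# spectral degrees of freedom, approximate entropy, detrended fluctuation
# analysis, and reference noise generators for calibrating them.

#' Hann-windowed normalized periodogram
#'
#' Applies a Hann window, takes the discrete Fourier transform, and returns
#' the one-sided power coefficients normalized to unit sum (the DC bin is
#' excluded; the mean carries no information about fluctuations).
#'
#' @param series numeric vector, at least 64 uniformly sampled values.
#' @param dt sampling interval in seconds (frequencies come out in Hz).
#' @return object of class \code{power_spectrum}: list with
#'   \code{frequencies}, \code{S} (normalized coefficients) and \code{N}.
#'   A constant series yields an all-zero spectrum with attribute
#'   \code{flag = "constant series"}.
#' @export
periodogram <- function(series, dt = 1) {
  n <- length(series)
  if (n < 64L) stop("need at least 64 samples")
  win <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  z <- stats::fft((series - mean(series)) * win)
  half <- 2:(floor(n / 2) + 1L)
  S <- Mod(z[half])^2
  freqs <- (half - 1L) / (n * dt)
  tot <- sum(S)
  out <- structure(list(frequencies = freqs,
                        S = if (tot > 0) S / tot else S,
                        N = length(S)),
                   class = "power_spectrum")
  if (tot == 0) attr(out, "flag") <- "constant series"
  out
}

#' Spectral degrees of freedom
#'
#' Uniformity measure of a power spectrum,
#' \deqn{\mathrm{DoF} = \frac{(\sum_i S_i)^2}{N \sum_i S_i^2},}
#' equal to 1 for a flat (white) spectrum of any length and \eqn{1/N} for a
#' single-bin (delta) spectrum, approaching 0 as \eqn{N} grows. The
#' statistic is scale-free: rescaling all coefficients leaves it unchanged.
#'
#' @param spec a \code{\link{periodogram}} result, or a bare non-negative
#'   numeric vector of spectral coefficients.
#' @return DoF value in \eqn{[1/N, 1]}.
#' @export
spectral_dof <- function(spec) {
  S <- if (inherits(spec, "power_spectrum")) spec$S else spec
  if (any(S < 0)) stop("spectral coefficients must be non-negative")
  tot <- sum(S)
  if (tot == 0) stop("all-zero spectrum has no defined DoF")
  tot^2 / (length(S) * sum(S^2))
}

#' Approximate entropy
#'
#' Regularity statistic of Pincus: \eqn{\mathrm{ApEn}(m, r) = \Phi_m -
#' \Phi_{m+1}} with self-matches included and natural logarithms, where
#' \eqn{\Phi_m} is the mean log fraction of length-\eqn{m} templates within
#' Chebyshev distance \eqn{r}. Low values indicate regular, predictable
#' series; i.i.d. noise scores high.
#'
#' @param series numeric vector, length >= 50.
#' @param m embedding (template) length; default 2.
#' @param r matching tolerance; default \code{0.2 * sd(series)}.
#' @return ApEn value (non-negative for the use cases here).
#' @export
approx_entropy <- function(series, m = 2L, r = 0.2 * stats::sd(series)) {
  n <- length(series)
  if (n < 50L) stop("need at least 50 samples")
  if (!is.finite(r) || r <= 0)
    stop("tolerance r must be strictly positive (degenerate for constant series)")
  phi <- function(mm) {
    n_t <- n - mm + 1L
    within <- matrix(TRUE, n_t, n_t)
    for (k in seq_len(mm)) {
      xk <- series[k:(k + n_t - 1L)]
      within <- within & (abs(outer(xk, xk, "-")) <= r)
    }
    mean(log(rowSums(within) / n_t))
  }
  phi(m) - phi(m + 1L)
}

#' Detrended fluctuation analysis
#'
#' Integrates the demeaned series, splits the profile into non-overlapping
#' boxes of size \eqn{n}, removes a per-box least-squares linear trend, and
#' measures the RMS residual fluctuation \eqn{F(n)}; the DFA exponent
#' \eqn{\alpha} is the least-squares slope of \eqn{\log F} against
#' \eqn{\log n} over the fit range. \eqn{\alpha \approx 0.5} for white
#' noise, 1 for 1/f (pink) noise, 1.5 for Brownian motion.
#'
#' @param series numeric vector, length >= 500.
#' @param box_sizes integer vector of box sizes; default ~20 log-spaced
#'   values from 10 to \code{length(series)/4}.
#' @param fit_drop number of smallest box sizes excluded from the exponent
#'   fit (small-\eqn{n} bias); default 2.
#' @return object of class \code{dfa_result}: list with \code{n},
#'   \code{F}, \code{alpha}, \code{fit_range}.
#' @export
dfa <- function(series, box_sizes = NULL, fit_drop = 2L) {
  N <- length(series)
  if (N < 500L) stop("need at least 500 samples")
  if (is.null(box_sizes))
    box_sizes <- unique(round(exp(seq(log(10), log(N / 4), length.out = 20))))
  box_sizes <- sort(unique(as.integer(box_sizes)))
  if (N %/% max(box_sizes) < 4L) {
    warning("fewer than 4 boxes at the largest size; shrinking range")
    box_sizes <- box_sizes[N %/% box_sizes >= 4L]
  }
  y <- cumsum(series - mean(series))
  Fv <- vapply(box_sizes, function(n) {
    n_box <- N %/% n
    idx <- seq_len(n_box * n)
    ym <- matrix(y[idx], nrow = n)
    t_ <- seq_len(n)
    tc <- t_ - mean(t_)
    # per-box linear detrend via closed-form least squares
    slope <- colSums(tc * ym) / sum(tc^2)
    inter <- colMeans(ym)
    resid <- ym - outer(tc, slope) - matrix(inter, n, n_box, byrow = TRUE)
    sqrt(mean(resid^2))
  }, numeric(1))
  keep <- seq.int(fit_drop + 1L, length(box_sizes))
  fit <- stats::lm(log(Fv[keep]) ~ log(box_sizes[keep]))
  structure(list(n = box_sizes, F = Fv,
                 alpha = unname(stats::coef(fit)[2]),
                 fit_range = range(box_sizes[keep])),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> alpha=%.4f over n in [%d, %d] (%d box sizes)\n",
              x$alpha, x$fit_range[1], x$fit_range[2], length(x$n)))
  invisible(x)
}

#' Reference noise series
#'
#' Deterministic (seeded) generators for the three calibration processes of
#' the fluctuation statistics: \code{"white"} (i.i.d. standard Gaussian),
#' \code{"brownian"} (cumulative sum of white) and \code{"one_over_f"}
#' (white spectrum shaped by \eqn{1/\sqrt{f}} and inverse-transformed, i.e.
#' pink noise).
#'
#' @param kind one of \code{"white"}, \code{"brownian"}, \code{"one_over_f"}.
#' @param length series length (>= 500).
#' @param seed integer seed.
#' @return numeric vector.
#' @export
make_reference_noise <- function(kind = c("white", "brownian", "one_over_f"),
                                 length = 2^14, seed = 1L) {
  kind <- match.arg(kind)
  if (length < 500L) stop("length must be at least 500")
  set.seed(as.integer(seed))
  w <- stats::rnorm(length)
  switch(kind,
         white = w,
         brownian = cumsum(w),
         one_over_f = {
           z <- stats::fft(w)
           k <- c(0:floor(length / 2),
                  -(ceiling(length / 2) - 1):-1)[1:length]
           scale <- ifelse(k == 0, 0, 1 / sqrt(abs(k)))
           x <- Re(stats::fft(z * scale, inverse = TRUE)) / length
           x / stats::sd(x)
         })
}
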