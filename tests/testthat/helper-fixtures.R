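# Shared fixtures: reference kernels, models, and small synthetic movies.

reference_kernel <- function() kernel_params(144.4, 73.7, 1.87, 3.24)

# proportionally strengthened kernel (same shape, same r0) that supports
# genuine 1D traveling-wave solutions at p = 0.3
wave_kernel_1d <- function() kernel_params(288.8, 176.88, 1.87, 3.24)

# scaled-down 2D regime family: sigma_E = 4, sigma_I = 6.93 (reference-kernel
# ratio), W_E = 40, inhibition ratio q = W_I/W_E selects the regime
regime_kernel <- function(q, W = 40) kernel_params(W, W * q, 4, 6.93)

# synthetic movie of Gaussian blobs translating on a periodic domain
blob_movie <- function(n = 64, n_frames = 96, speeds, dt_s = 0.01,
                       spacing = 1, sigma = 3, amps = NULL) {
  if (is.null(amps)) amps <- rep(1, length(speeds))
  L <- n * spacing
  xs <- (seq_len(n) - 1) * spacing
  arr <- array(0, c(n, n, n_frames))
  y0 <- L * (seq_along(speeds)) / (length(speeds) + 1)
  for (t in seq_len(n_frames)) {
    for (b in seq_along(speeds)) {
      x0 <- (10 + speeds[b] * (t - 1) * dt_s) %% L
      dx <- xs - x0; dx <- dx - L * round(dx / L)
      dy <- xs - y0[b]; dy <- dy - L * round(dy / L)
      arr[, , t] <- arr[, , t] +
        amps[b] * exp(-outer(dx^2, dy^2, "+") / (2 * sigma^2))
    }
  }
  list(f = arr, dt_s = dt_s, spacing = spacing)
}

# fake field_movie wrapper for tracking tests
fake_movie <- function(frames, times, spacing = 1, p = 0.42) {
  n <- nrow(frames[[1]])
  arr <- array(0, c(n, n, length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
  structure(list(f = arr, h = NULL, times = times,
                 config = list(n = n, spacing = spacing,
                               model = model_params(p = p)),
                 clamp_count = 0L, seed = 1L),
            class = "field_movie")
}

# rasterized bump field at an arbitrary (possibly wrapping) center
bump_field <- function(n, center, rho, f_in = 0.2283, spacing = 1) {
  L <- n * spacing
  xs <- (seq_len(n) - 1) * spacing
  dx <- xs - center[1]; dx <- dx - L * round(dx / L)
  dy <- xs - center[2]; dy <- dy - L * round(dy / L)
  f <- matrix(0, n, n)
  f[sqrt(outer(dx^2, dy^2, "+")) < rho] <- f_in
  f
}
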