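test_that("pattern labelling finds wrapped components and drops specks", {
  st <- list(f = bump_field(64, c(32, 32), 6), spacing = 1)
  comps <- label_patterns(st, 0.5, f_in = 0.2283)
  expect_length(comps, 1)
  # bump straddling the domain corner stays a single component
  st2 <- list(f = bump_field(64, c(1, 1), 6), spacing = 1)
  comps2 <- label_patterns(st2, 0.5, f_in = 0.2283)
  expect_length(comps2, 1)
  expect_equal(length(comps2[[1]]), length(comps[[1]]))
  # empty field, and sub-4-cell specks, give nothing
  expect_length(label_patterns(list(f = matrix(0, 16, 16), spacing = 1),
                               0.5, f_in = 1), 0)
  speck <- matrix(0, 16, 16); speck[4, 4] <- 1; speck[4, 5] <- 1
  expect_length(label_patterns(list(f = speck, spacing = 1), 0.5, f_in = 1), 0)
})

test_that("center of mass respects periodicity", {
  st <- list(f = bump_field(64, c(32.5, 40.5), 6), spacing = 1)
  fs <- field_state(st$f, st$f * 0, 1)
  comp <- label_patterns(fs, 0.5, f_in = 0.2283)[[1]]
  expect_equal(center_of_mass(comp, fs), c(32.5, 40.5), tolerance = 0.5)
  # wrapped bump: compare against a shift-unwrap oracle
  f_w <- bump_field(64, c(2, 62), 6)
  fs_w <- field_state(f_w, f_w * 0, 1)
  comp_w <- label_patterns(fs_w, 0.5, f_in = 0.2283)[[1]]
  com_w <- center_of_mass(comp_w, fs_w)
  # oracle: shift by 16 cells, average plainly, shift back
  f_s <- f_w[c(49:64, 1:48), c(49:64, 1:48)]
  idx <- which(f_s > 0.5 * 0.2283)
  ox <- mean(((idx - 1) %% 64)) ; oy <- mean(((idx - 1) %/% 64))
  oracle <- c((ox - 16) %% 64, (oy - 16) %% 64)
  expect_equal(com_w, oracle, tolerance = 0.6)
  # two equally weighted cells across the seam average on the short arc
  f2 <- matrix(0, 16, 16); f2[1, 8] <- 1; f2[16, 8] <- 1
  fs2 <- field_state(f2, f2 * 0, 1)
  com2 <- center_of_mass(c(which(f2 > 0)), fs2)
  expect_equal(com2[1] %% 16, 15.5, tolerance = 1e-6)
  expect_error(center_of_mass(integer(0), fs2), "empty")
})

test_that("kinematics are exact on analytic trajectories", {
  dt <- 0.1; t <- seq(0, 20, by = dt)
  # straight line at speed 1.3
  lin <- data.frame(time = t, x = (5 + 1.3 * t) %% 100, y = rep(7, length(t)))
  kl <- kinematics(lin, 100)
  expect_equal(mean(kl$v_tot), 1.3, tolerance = 1e-6)
  expect_lt(max(kl$a_tot), 1e-6)
  # circle of radius 5 at angular rate 0.4
  circ <- data.frame(time = t, x = 50 + 5 * cos(0.4 * t),
                     y = 50 + 5 * sin(0.4 * t))
  kc <- kinematics(circ, 100)
  expect_equal(mean(kc$v_tot), 5 * 0.4, tolerance = 0.01)
  expect_equal(mean(kc$a_tot), 5 * 0.4^2, tolerance = 0.05)
  expect_lt(stats::sd(kc$v_tot) / mean(kc$v_tot), 0.01)
  # stationary
  ks <- kinematics(data.frame(time = t, x = rep(3, length(t)),
                              y = rep(4, length(t))), 100)
  expect_true(all(ks$v_tot == 0) && all(ks$a_tot == 0))
  expect_error(kinematics(lin[1:10, ], 100), "21")
})

test_that("state classification separates bump, traveling, rotating", {
  dt <- 0.1; t <- seq(0, 40, by = dt)
  lab_of <- function(x, y) {
    kin <- kinematics(data.frame(time = t, x = x, y = y), 1000)
    classify_state(kin, spacing = 1)$label
  }
  expect_true(all(lab_of((5 + 2 * t) %% 1000, rep(7, length(t))) == "traveling"))
  expect_true(all(lab_of(50 + 5 * cos(0.8 * t), 50 + 5 * sin(0.8 * t))
                  == "rotating"))
  expect_true(all(lab_of(rep(3, length(t)), rep(4, length(t))) == "bump"))
})

test_that("frame-to-frame identity tracking survives two moving patterns", {
  n <- 96
  times <- seq(0, 10, by = 0.25)
  frames <- lapply(times, function(tt) {
    bump_field(n, c(20 + 2 * tt, 25), 6) + bump_field(n, c(70 - 2 * tt, 70), 6)
  })
  mv <- fake_movie(frames, times)
  tr <- track_patterns(mv)
  expect_length(unique(tr$id), 2)
  # each track stays on its own pattern (no identity swap)
  for (id in unique(tr$id)) {
    tri <- tr[tr$id == id, ]
    expect_equal(nrow(tri), length(times))
    expect_lt(max(abs(diff(tri$y))), 1.5)
  }
})

test_that("dwell segmentation partitions the analyzed duration", {
  labs <- structure(
    data.frame(t_mid = seq(0, 19.5, by = 0.5),
               label = rep(c("traveling", "rotating", "traveling",
                             "rotating"), each = 10)),
    class = c("state_label_series", "data.frame"))
  sl <- switching_lifetimes(labs)
  expect_equal(sl$n_transitions, 3)
  expect_equal(sum(sl$lifetimes$total_time), 0.5 * 40)
  expect_equal(sl$lifetimes$n_dwells[sl$lifetimes$state == "rotating"], 2)
  # unclassified windows merge into the preceding dwell
  labs$label[12] <- "unclassified"
  sl2 <- switching_lifetimes(labs)
  expect_equal(sl2$n_transitions, 3)
})

test_that("regime classification flags global and splitting movies", {
  n <- 64
  times <- seq(0, 12, by = 0.25)
  # near-domain-filling band: region IV
  band <- matrix(0, n, n); band[, 10:40] <- 0.23
  mv4 <- fake_movie(rep(list(band), length(times)), times)
  expect_identical(as.character(classify_regime(mv4, transient = 2)), "IV")
  # one pattern splitting into two: region III
  frames3 <- lapply(times, function(tt) {
    if (tt < 6) bump_field(n, c(32, 32), 6)
    else bump_field(n, c(22, 32), 5) + bump_field(n, c(42, 32), 5)
  })
  mv3 <- fake_movie(frames3, times)
  expect_identical(as.character(classify_regime(mv3, transient = 2)), "III")
})
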