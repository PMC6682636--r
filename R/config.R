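# Run configuration, persistence and the pipeline stages binding the
# modules into reproducible runs.

#' Default run configuration
#'
#' Nested configuration covering every stage, filled with the reference
#' parameter values: \eqn{\tau} = 10 ms, \eqn{\kappa} = 1, \eqn{p} = 0.42,
#' a 601x601 grid at 0.1 mm spacing (one field unit per cell) and 0.1 ms
#' steps (\code{dt} = 0.01 rescaled).
#'
#' @return a \code{run_config} list.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = "nfw-out",
    kernel = list(W_E = 144.4, W_I = 73.7, sigma_E = 1.87, sigma_I = 3.24),
    model = list(p = 0.42, kappa = 1, tau = 10),
    sim = list(n_cells = 601L, spacing = 1, dt = 0.01, duration = 1, stride = 10L,
               initial = "wave2d",
               noise = list(sigma_xi = 0, mode = "off")),
    fit = list(grid_n = 128L, n_boundary = 64L, n_starts = 3L,
               wave1d_starts = 15L),
    sweep = list(w_i_factors = c(1.1, 1.0, 0.9)),
    tracking = list(threshold = 0.5, transient = 5, window_t = 2,
                    v_eps = 0.5, a_eps = 0.25, rel_sd_tol = 0.25),
    stats = list(apen_m = 2L, apen_r_frac = 0.2, dfa_fit_drop = 2L),
    spectrum = list(n_velocities = 100L)
  ), class = "run_config")
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    if (!key %in% names(base))
      stop(sprintf("unknown configuration key: %s%s", path, key))
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop(sprintf("configuration key %s%s must be a mapping", path, key))
      base[[key]] <- merge_config(base[[key]], user[[key]],
                                  paste0(path, key, "."))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  with(cfg, {
    if (sim$dt <= 0) stop("sim.dt must be positive")
    if (sim$duration < 0) stop("sim.duration must be non-negative")
    if (model$p <= 0 || model$kappa <= 0 || model$tau <= 0)
      stop("model parameters must be positive")
    if (any(unlist(kernel) <= 0)) stop("kernel parameters must be positive")
    if (!sim$noise$mode %in% c("off", "single_kick", "continuous"))
      stop("sim.noise.mode must be off, single_kick or continuous")
    if (sim$noise$sigma_xi < 0) stop("sim.noise.sigma_xi must be >= 0")
  })
  invisible(cfg)
}

#' Parse a run configuration
#'
#' Reads a YAML (or JSON; JSON is a YAML subset) document, overlays it on
#' \code{\link{default_run_config}}, rejects unknown keys, and validates the
#' numeric constraints. An empty document yields the full default
#' configuration. \code{parse_config(serialize_config(cfg))} is the
#' identity.
#'
#' @param text a YAML string, or a file path when \code{is_file = TRUE}.
#' @param is_file read \code{text} as a path.
#' @return a validated \code{run_config}.
#' @export
parse_config <- function(text = "", is_file = FALSE) {
  user <- if (is_file) yaml::read_yaml(text) else yaml::yaml.load(text)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_run_config(), user)
  validate_config(cfg)
  cfg
}

#' Serialize a run configuration to YAML
#'
#' @param cfg a \code{run_config}.
#' @return a YAML string.
#' @export
serialize_config <- function(cfg) {
  yaml::as.yaml(unclass(cfg))
}

# Deterministic per-stage seed fan-out from the global seed, so stages can
# be rerun independently with identical streams.
stage_seed <- function(global_seed, stage) {
  offsets <- c(simulate = 11L, `fit-wave` = 23L, `sweep-ei` = 37L,
               analyze = 53L, `st-spectrum` = 71L, placement = 89L)
  (as.integer(global_seed) * 101L + offsets[[stage]]) %% 2147483647L
}

config_objects <- function(cfg) {
  kernel <- kernel_params(cfg$kernel$W_E, cfg$kernel$W_I,
                          cfg$kernel$sigma_E, cfg$kernel$sigma_I)
  model <- model_params(cfg$model$p, cfg$model$kappa, cfg$model$tau)
  list(kernel = kernel, model = model)
}

write_manifest <- function(out_dir, stage, cfg, extras = list()) {
  manifest <- c(list(
    stage = stage,
    seed = cfg$seed,
    stage_seed = stage_seed(cfg$seed, stage),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("nfwaves")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = unclass(cfg)
  ), extras)
  path <- file.path(out_dir, paste0(stage, "-manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

fit_wave_stage <- function(cfg, objs) {
  # the 1D solver needs a kernel whose line reduction reaches threshold;
  # where no 1D wave exists, fall back to a bump-sized teardrop guess
  w1 <- tryCatch(solve_wave1d(objs$kernel, objs$model,
                              n_starts = cfg$fit$wave1d_starts,
                              seed = stage_seed(cfg$seed, "fit-wave")),
                 error = function(e) NULL)
  init <- if (!is.null(w1)) {
    wave2d_init_from_1d(w1[[length(w1)]])
  } else {
    bumps <- solve_bump_radii(objs$kernel, objs$model)
    big <- Filter(function(b) b$branch == "larger", bumps)
    if (length(big) == 0L)
      stop("neither a 1D wave nor a bump solution exists to seed the fit")
    rho <- big[[1]]$rho
    wave2d_shape(1.5, rho, rho, rho / 2, 0.5)
  }
  fit_cfg <- sim_config(n = cfg$fit$grid_n, spacing = cfg$sim$spacing,
                        dt = cfg$sim$dt, duration = 0,
                        kernel = objs$kernel, model = objs$model)
  fits <- fit_wave2d(objs$kernel, objs$model, init,
                     fit_cfg, n_boundary = cfg$fit$n_boundary,
                     seed = stage_seed(cfg$seed, "fit-wave"),
                     n_starts = cfg$fit$n_starts)
  list(wave1d = w1, fits = fits)
}

#' Run a pipeline stage
#'
#' Executes one named stage against a configuration, writing artifact files
#' and a JSON run manifest (seed, versions, configuration echo) into the
#' output directory (created if missing).
#'
#' Stages: \code{"simulate"} integrates the field from the configured
#' initial condition and stores the movie (RDS) plus metadata;
#' \code{"fit-wave"} solves the 1D wave and fits the 2D teardrop, writing a
#' CSV of shapes; \code{"sweep-ei"} rescales the inhibitory strength over
#' \code{cfg$sweep$w_i_factors}, simulating a fitted wave at each point and
#' emitting one regime label per point; \code{"analyze"} tracks a movie and
#' writes trajectories, labels and summary statistics (DoF, ApEn, DFA);
#' \code{"st-spectrum"} computes the spatiotemporal spectrum and
#' velocity-power profile.
#'
#' @param cfg a \code{run_config} from \code{\link{parse_config}}.
#' @param command stage name.
#' @param movie optionally, an in-memory \code{field_movie} for the analyze
#'   and st-spectrum stages (otherwise \code{movie.rds} from
#'   \code{cfg$out_dir} is loaded).
#' @return invisible list of artifact paths and in-memory results.
#' @export
run_pipeline <- function(cfg, command = c("simulate", "fit-wave", "sweep-ei",
                                          "analyze", "st-spectrum"),
                         movie = NULL) {
  command <- match.arg(command)
  if (!dir.exists(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE)
    message("created output directory ", cfg$out_dir)
  }
  objs <- config_objects(cfg)
  out <- list()

  if (command == "fit-wave") {
    fw <- fit_wave_stage(cfg, objs)
    ei <- ei_integrals(objs$kernel)
    tab <- do.call(rbind, lapply(fw$fits, function(r) data.frame(
      g_plus = ei$g_plus, g_minus = ei$g_minus, c = r$shape$c,
      L_f = r$shape$L_f, L_w = r$shape$L_w, L_a = r$shape$L_a,
      L_b = r$shape$L_b, objective = r$objective, converged = r$converged)))
    path <- file.path(cfg$out_dir, "wave2d-fits.csv")
    utils::write.csv(tab, path, row.names = FALSE)
    out$fits_csv <- path
    out$result <- fw
  } else if (command == "simulate") {
    scfg <- sim_config(n = cfg$sim$n_cells, spacing = cfg$sim$spacing,
                       dt = cfg$sim$dt, duration = cfg$sim$duration,
                       stride = cfg$sim$stride, kernel = objs$kernel,
                       model = objs$model,
                       noise = noise_spec(cfg$sim$noise$sigma_xi,
                                          stage_seed(cfg$seed, "simulate"),
                                          cfg$sim$noise$mode))
    init <- switch(cfg$sim$initial,
      bump = {
        bumps <- solve_bump_radii(objs$kernel, objs$model)
        if (length(bumps) == 0L) stop("no bump solution at these parameters")
        make_initial("bump", scfg, bump = bumps[[length(bumps)]])
      },
      wave1d_strip = {
        w1 <- solve_wave1d(objs$kernel, objs$model,
                           n_starts = cfg$fit$wave1d_starts,
                           seed = stage_seed(cfg$seed, "simulate"))
        make_initial("wave1d_strip", scfg, wave = w1[[length(w1)]])
      },
      wave2d = {
        fw <- fit_wave_stage(cfg, objs)
        make_initial("wave2d", scfg, shape = fw$fits[[1]]$shape)
      },
      random_waves = {
        fw <- fit_wave_stage(cfg, objs)
        make_initial("random_waves", scfg, shape = fw$fits[[1]]$shape,
                     seed = stage_seed(cfg$seed, "placement"))
      },
      stop("unknown sim.initial kind"))
    mv <- simulate_field(init, scfg)
    path <- file.path(cfg$out_dir, "movie.rds")
    saveRDS(mv, path)
    out$movie_rds <- path
    out$result <- mv
  } else if (command == "sweep-ei") {
    labels <- lapply(cfg$sweep$w_i_factors, function(fac) {
      k2 <- kernel_params(cfg$kernel$W_E, cfg$kernel$W_I * fac,
                          cfg$kernel$sigma_E, cfg$kernel$sigma_I)
      cfg2 <- cfg
      cfg2$kernel$W_I <- cfg$kernel$W_I * fac
      objs2 <- config_objects(cfg2)
      fw <- fit_wave_stage(cfg2, objs2)
      scfg <- sim_config(n = cfg$fit$grid_n, spacing = cfg$sim$spacing,
                         dt = cfg$sim$dt, duration = cfg$sim$duration,
                         stride = cfg$sim$stride, kernel = k2,
                         model = objs2$model, store_h = FALSE)
      mv <- simulate_field(make_initial("wave2d", scfg,
                                        shape = fw$fits[[1]]$shape), scfg)
      ei <- ei_integrals(k2)
      data.frame(w_i_factor = fac, g_plus = ei$g_plus, g_minus = ei$g_minus,
                 regime = as.character(classify_regime(
                   mv, transient = cfg$tracking$transient)))
    })
    tab <- do.call(rbind, labels)
    path <- file.path(cfg$out_dir, "sweep-ei.csv")
    utils::write.csv(tab, path, row.names = FALSE)
    out$sweep_csv <- path
    out$result <- tab
  } else {
    if (is.null(movie)) {
      mpath <- file.path(cfg$out_dir, "movie.rds")
      if (!file.exists(mpath)) stop("no movie available: run simulate first")
      movie <- readRDS(mpath)
    }
    if (command == "analyze") {
      traj <- track_patterns(movie, cfg$tracking$threshold)
      L_dom <- movie$config$n * movie$config$spacing
      traj <- traj[traj$time >= movie$times[1] + cfg$tracking$transient, ]
      summaries <- list()
      rows <- list()
      for (id in unique(traj$id)) {
        tr <- traj[traj$id == id, ]
        if (nrow(tr) < 64) next
        kin <- kinematics(tr, L_dom)
        if (nrow(kin) < 64) next
        dt_s <- stats::median(diff(kin$time)) * movie$config$model$tau / 1000
        spec <- periodogram(kin$v_x, dt_s)
        lab <- classify_state(kin, spacing = movie$config$spacing,
                              window_t = cfg$tracking$window_t,
                              v_eps = cfg$tracking$v_eps,
                              a_eps = cfg$tracking$a_eps,
                              rel_sd_tol = cfg$tracking$rel_sd_tol)
        dfa_a <- if (nrow(kin) >= 500)
          dfa(kin$v_x, fit_drop = cfg$stats$dfa_fit_drop)$alpha else NA_real_
        summaries[[length(summaries) + 1L]] <- data.frame(
          id = id, n_samples = nrow(kin), dof = spectral_dof(spec),
          apen = approx_entropy(kin$v_x, m = cfg$stats$apen_m,
                                r = cfg$stats$apen_r_frac * stats::sd(kin$v_x)),
          alpha_dfa = dfa_a)
        lab$id <- id
        rows[[length(rows) + 1L]] <- merge(kin, tr[, c("time", "x", "y")],
                                           by = "time")
      }
      traj_path <- file.path(cfg$out_dir, "trajectories.csv")
      utils::write.csv(do.call(rbind, rows), traj_path, row.names = FALSE)
      sum_path <- file.path(cfg$out_dir, "summary-stats.csv")
      utils::write.csv(do.call(rbind, summaries), sum_path, row.names = FALSE)
      out$trajectories_csv <- traj_path
      out$summary_csv <- sum_path
      out$result <- do.call(rbind, summaries)
    } else {  # st-spectrum
      spec <- spatiotemporal_spectrum(movie)
      vpp <- velocity_power_profile(spec)
      path <- file.path(cfg$out_dir, "velocity-power.csv")
      utils::write.csv(data.frame(v = vpp$v, S_tot = vpp$S_tot), path,
                       row.names = FALSE)
      out$profile_csv <- path
      out$result <- vpp
    }
  }
  out$manifest <- write_manifest(cfg$out_dir, command, cfg)
  invisible(out)
}
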