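# Configuration files (YAML) and run outputs (CSV + JSON with a sidecar
# schema), binding the modules into a reproducible pipeline.

.configDefaults <- function(preset = "desk_coarse") {
  sim <- simulationConfig(preset)
  list(
    particles = list(sigma_m = 1e-7, v0_m_s = 1e-3, mu_J_T = 1.394e-17,
                     eta_Pa_s = 1e-3, T_b_K = 310, N_p = 1000L),
    field = list(frequency_Hz = 1e6, sound_speed_m_s = 1500,
                 attenuation_m1_MHz1 = 5 * log(10), roc_m = 0.2,
                 aperture_m = 0.2, b_xy_m = 1.790e-3, b_z_m = 11.408e-3),
    plan = list(R_f_m = 0.7927e-3, R_0_m = 0.01, t_s_s = 600,
                plane = "xy", chi = 6.38),
    magnet = list(B_T = 1e-3),
    channels = list(enabled = FALSE, l_qd_m = 0.024, w_m = 5e-4, d_m = 1e-3),
    simulation = list(preset = preset, dt_s = sim$dt, seed = 1L,
                      record_interval_s = sim$record_interval,
                      domain_half_width_m = sim$domain_half_width),
    analysis = list(target_radius_m = 1.5e-3, bin_width_m = 50e-6)
  )
}

.configRanges <- list(
  "particles.sigma_m" = c(0, Inf), "particles.v0_m_s" = c(-1e-12, Inf),
  "particles.mu_J_T" = c(-1e-12, Inf), "particles.eta_Pa_s" = c(0, Inf),
  "particles.T_b_K" = c(0, Inf), "particles.N_p" = c(-1e-12, Inf),
  "field.frequency_Hz" = c(0, Inf), "field.sound_speed_m_s" = c(0, Inf),
  "field.attenuation_m1_MHz1" = c(-1e-12, Inf), "field.roc_m" = c(0, Inf),
  "field.aperture_m" = c(0, Inf), "field.b_xy_m" = c(0, Inf),
  "field.b_z_m" = c(0, Inf),
  "plan.R_f_m" = c(0, Inf), "plan.R_0_m" = c(0, Inf),
  "plan.t_s_s" = c(0, Inf), "plan.chi" = c(1, Inf),
  "magnet.B_T" = c(0, Inf),
  "channels.l_qd_m" = c(0, Inf), "channels.w_m" = c(0, Inf),
  "channels.d_m" = c(0, Inf),
  "simulation.dt_s" = c(0, Inf), "simulation.record_interval_s" = c(0, Inf),
  "simulation.domain_half_width_m" = c(0, Inf),
  "analysis.target_radius_m" = c(0, Inf), "analysis.bin_width_m" = c(0, Inf))

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills unset keys from the preset defaults,
#' rejects unknown keys, and checks every physical quantity against its
#' admissible range.  All quantities are SI with unit-suffixed key names.
#'
#' @param path Path to a YAML file; an empty or missing-section file yields
#'   the full preset defaults.
#' @param preset Simulation preset used for defaults.
#' @return Object of class `runConfig`: nested list with sections
#'   `particles`, `field`, `plan`, `magnet`, `channels`, `simulation`,
#'   `analysis`.
#' @export
loadConfig <- function(path, preset = "desk_coarse") {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.null(user$simulation$preset)) preset <- user$simulation$preset
  cfg <- .configDefaults(preset)
  for (sec in names(user)) {
    if (!sec %in% names(cfg))
      stop("unknown config section: ", sec)
    if (length(user[[sec]]) == 0) next
    for (key in names(user[[sec]])) {
      if (!key %in% names(cfg[[sec]]))
        stop("unknown config key: ", sec, ".", key)
      cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
  }
  for (kk in names(.configRanges)) {
    parts <- strsplit(kk, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    rng <- .configRanges[[kk]]
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) ||
        val <= rng[1] || val > rng[2])
      stop("config range violation at ", kk, ": value ", format(val))
  }
  if (!cfg$plan$plane %in% c("xy", "xz"))
    stop("config range violation at plan.plane: must be 'xy' or 'xz'")
  if (cfg$simulation$record_interval_s < cfg$simulation$dt_s)
    stop("config range violation at simulation.record_interval_s: ",
         "must be at least dt_s")
  structure(cfg, class = "runConfig")
}

#' Write a configuration to YAML
#'
#' @param config A `runConfig` (or compatible nested list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Assemble simulation objects from a configuration
#'
#' @param config A `runConfig` from [loadConfig()].
#' @return List with `config` ([simulationConfig()]), `plan`, `params`,
#'   `focus`, `B` and (when enabled) a generated channel `network`.
#' @export
configToObjects <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  sim <- simulationConfig(config$simulation$preset,
                          dt = config$simulation$dt_s,
                          t_s = config$plan$t_s_s,
                          seed = config$simulation$seed,
                          N_p = config$particles$N_p,
                          domain_half_width =
                            config$simulation$domain_half_width_m,
                          record_interval =
                            config$simulation$record_interval_s)
  plan <- spiralPlan(R_f = config$plan$R_f_m, R_0 = config$plan$R_0_m,
                     t_s = config$plan$t_s_s, plane = config$plan$plane,
                     chi = config$plan$chi)
  params <- particleParams(sigma = config$particles$sigma_m,
                           v0 = config$particles$v0_m_s,
                           mu = config$particles$mu_J_T,
                           eta = config$particles$eta_Pa_s,
                           T_b = config$particles$T_b_K)
  focus <- gaussianFocus(b_xy = config$field$b_xy_m, b_z = config$field$b_z_m)
  network <- NULL
  if (isTRUE(config$channels$enabled)) {
    set.seed(config$simulation$seed)
    paths <- generatePaths(config$channels$l_qd_m, config$channels$d_m,
                           config$channels$w_m)
    network <- buildChannelGeometry(paths, config$channels$w_m,
                                    config$channels$l_qd_m)
  }
  list(config = sim, plan = plan, params = params, focus = focus,
       B = config$magnet$B_T, network = network)
}

#' Write run outputs to a directory
#'
#' Writes the recorded trajectory as CSV (`trajectory.csv`), the guiding
#' summary as CSV (`summary.csv`), a JSON run summary (`summary.json`)
#' embedding the plan calibration and seed, the fully resolved configuration
#' (`config.yaml`), and a sidecar schema (`schema.json`) documenting the CSV
#' columns.
#'
#' @param record A `trajectoryRecord` from [runSimulation()].
#' @param summary A `guidingSummary` from [guidingSummary()].
#' @param out_dir Output directory (created if needed).
#' @param config Optional `runConfig` to embed; reconstructed from the
#'   record's metadata when omitted.
#' @return Character vector of the written file paths, invisibly.
#' @export
writeOutputs <- function(record, summary, out_dir, config = NULL) {
  stopifnot(inherits(record, "trajectoryRecord"),
            inherits(summary, "guidingSummary"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  nt <- length(record$times)
  np <- dim(record$positions)[2]
  traj <- data.frame(
    t = rep(record$times, np),
    particle_id = rep(seq_len(np), each = nt),
    c1 = as.vector(record$positions[, , 1]),
    c2 = as.vector(record$positions[, , 2]),
    phi = as.vector(record$orientations))
  paths <- file.path(out_dir, c("trajectory.csv", "summary.csv",
                                "summary.json", "config.yaml", "schema.json"))
  write.csv(traj, paths[1], row.names = FALSE)
  write.csv(as.data.frame(summary), paths[2], row.names = FALSE)
  jsonlite::write_json(
    list(seed = record$config$seed, preset = record$config$preset,
         plane = record$plan$plane,
         v_phi = record$plan$v_phi, t1 = record$plan$t1, t2 = record$plan$t2,
         t_s = record$plan$t_s, N_p = np, B_T = record$B,
         channelled = record$channelled, exited = record$exited,
         phi_final = summary$phi[nt], q70_final = summary$q70[nt]),
    paths[3], auto_unbox = TRUE, digits = NA)
  if (is.null(config)) {
    config <- .configDefaults(record$config$preset)
    config$particles$N_p <- np
    config$particles$sigma_m <- record$params$sigma
    config$particles$v0_m_s <- record$params$v0
    config$plan$plane <- record$plan$plane
    config$simulation$seed <- record$config$seed
    config$simulation$dt_s <- record$config$dt
    config$channels$enabled <- record$channelled
  }
  writeConfig(config, paths[4])
  jsonlite::write_json(list(
    trajectory.csv = list(
      t = "snapshot time [s]",
      particle_id = "particle index (1-based)",
      c1 = "first in-plane coordinate (x) [m]",
      c2 = "second in-plane coordinate (y for xy runs, z for xz runs) [m]",
      phi = "orientation angle [rad]"),
    summary.csv = list(
      time = "snapshot time [s]",
      phi = "fraction of particles inside the target [-]",
      q70 = "70% quantile of particle distance from the target [m]")),
    paths[5], auto_unbox = TRUE)
  invisible(paths)
}

#' Read back a trajectory written by [writeOutputs()]
#'
#' @param out_dir Directory previously written by [writeOutputs()].
#' @return List with `trajectory` and `summary` data frames and the parsed
#'   `summary.json` list.
#' @export
readOutputs <- function(out_dir) {
  list(trajectory = read.csv(file.path(out_dir, "trajectory.csv")),
       summary = read.csv(file.path(out_dir, "summary.csv")),
       meta = jsonlite::read_json(file.path(out_dir, "summary.json"),
                                  simplifyVector = TRUE))
}
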