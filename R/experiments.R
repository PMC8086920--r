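#' Default run configuration
#'
#' One nested list with sections geometry / physics / controller / training /
#' inflammation / experiment, serializable to JSON by
#' \code{\link{write_config}}.  All values are SI; the command-line layer
#' converts to cm s^-1 and percent at the boundary only.
#'
#' @param preset geometry preset name (\code{"full"}, \code{"mini"},
#'   \code{"micro"}).
#' @return a nested configuration list.
#' @export
default_config <- function(preset = "full") {
  geom <- geometry_preset(preset)
  list(
    geometry = c(list(preset = preset), unclass(geom)),
    physics = unclass(physics_params()),
    controller = list(dv = 1e-3, cadence = 0.1, clamp = c(0, 0.15),
                      mode = "greedy"),
    training = unclass(training_config()),
    inflammation = list(regions = data.frame(x_start = numeric(0),
                                             x_end = numeric(0),
                                             phi = numeric(0)),
                        t0 = NULL),
    experiment = list(seed = 1,
                      sweep_v_wave = seq(0.01, 0.10, by = 0.01),
                      sweep_mu = c(7.8e-3, 7.8e-2, 7.8e-1),
                      sweep_duration = 10,
                      adaptive_duration = 40,
                      adaptive_mu = 7.8e-3,
                      healthy_duration = 10))
}

config_geometry <- function(config) {
  g <- config$geometry
  tube_geometry(L = g$L, R = g$R, dL = g$dL, n_rings = g$n_rings,
                n_per_ring = g$n_per_ring, fluid_slices = g$fluid_slices,
                disc_counts = g$disc_counts, clearance = g$clearance,
                spring_cutoff = g$spring_cutoff)
}

config_physics <- function(config) {
  p <- config$physics
  physics_params(k = p$k, rho0 = p$rho0, mu = p$mu, c0 = p$c0,
                 alpha = p$alpha, b = p$b, h = p$h, A = p$A,
                 r0_couple = p$r0_couple, f = p$f, dt = p$dt, m = p$m,
                 kernel = p$kernel, density = p$density,
                 rho_guard = p$rho_guard)
}

#' Write / read a configuration file
#'
#' @param config a configuration list (see \code{\link{default_config}}).
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config(if (!is.null(cfg$geometry$preset)) cfg$geometry$preset
                         else "full")
  modifyList(base, cfg)
}

#' Constant-wave-speed sweep
#'
#' Runs one constant-speed simulation per (v_wave, mu) grid point, extracts
#' the plateau centre-of-mass velocity and receiving-segment strain, and
#' reports per viscosity the wave speed that maximizes transport.  Unstable
#' grid points are recorded as failed cells and excluded from the argmax.
#'
#' @param config a configuration list.
#' @param verbose print one line per grid point.
#' @return a \code{sweep_result}: list(table, optimum) where table has one
#'   row per grid point (v_wave, mu, v_com, epsilon, failed) and optimum one
#'   row per viscosity (mu, v_star, v_com).
#' @export
run_static_sweep <- function(config, verbose = FALSE) {
  geom <- config_geometry(config)
  tube <- build_tube(geom)
  bonds <- build_springs(tube, geom$spring_cutoff, geom$L)
  grid <- expand.grid(v_wave = config$experiment$sweep_v_wave,
                      mu = config$experiment$sweep_mu)
  # v_com: plateau estimator (mean of the final second);
  # v_com_avg: net COM displacement / duration, a steadier statistic for
  # short periodic tubes that the wave laps several times per run
  tab <- data.frame(grid, v_com = NA_real_, v_com_avg = NA_real_,
                    epsilon = NA_real_, failed = FALSE)
  for (r in seq_len(nrow(tab))) {
    pp <- config_physics(config)
    pp$mu <- tab$mu[r]
    pp$c0 <- viscosity_to_c0(tab$mu[r])
    wave <- wave_state(0, tab$v_wave[r], mode = "static")
    res <- tryCatch(
      simulate_static(tube, bonds, pp, geom, wave,
                      duration = config$experiment$sweep_duration),
      error = function(e) NULL)
    if (is.null(res)) {
      tab$failed[r] <- TRUE
    } else {
      tab$v_com[r] <- plateau(res$v_com[-1])
      tab$v_com_avg[r] <- mean(res$v_com[-1])
      tab$epsilon[r] <- plateau(res$epsilon[-1])
    }
    if (verbose)
      message(sprintf("sweep v_wave=%.3f mu=%.3g -> v_com=%.5f%s",
                      tab$v_wave[r], tab$mu[r], tab$v_com[r],
                      if (tab$failed[r]) " (failed)" else ""))
  }
  opt <- do.call(rbind, lapply(split(tab[!tab$failed, ], tab$mu[!tab$failed]),
    function(d) data.frame(mu = d$mu[1],
                           v_star = d$v_wave[which.max(d$v_com)],
                           v_com = max(d$v_com))))
  rownames(opt) <- NULL
  structure(list(table = tab, optimum = opt), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("constant-wave sweep:\n")
  print(x$table)
  cat("optimal wave speed per viscosity:\n")
  print(x$optimum)
  invisible(x)
}

#' Adaptive (controller-driven) run
#'
#' Runs the coupled model with the policy choosing the wave speed every
#' \code{cadence} seconds (greedy by default).  Optionally applies an
#' inflammation profile to the controller's perception.
#'
#' @param config a configuration list.
#' @param policy a \code{policy_net} or the path of a policy file.
#' @param profile optional \code{\link{inflammation_profile}}.
#' @param duration run length (s); default from the config.
#' @param verbose print a progress line every simulated second.
#' @return data.frame with columns t, v_wave, eps_true, eps_perceived,
#'   v_com; attribute \code{mean_v_wave}.
#' @export
run_adaptive <- function(config, policy, profile = NULL, duration = NULL,
                         verbose = FALSE) {
  geom <- config_geometry(config)
  if (is.character(policy))
    policy <- read_policy(policy)
  pp <- config_physics(config)
  pp$mu <- config$experiment$adaptive_mu
  pp$c0 <- viscosity_to_c0(pp$mu)
  if (is.null(duration)) duration <- config$experiment$adaptive_duration
  cad <- config$controller$cadence
  tube <- build_tube(geom)
  bonds <- build_springs(tube, geom$spring_cutoff, geom$L)
  wave <- wave_state(0, 0, mode = "adaptive")
  set.seed(config$experiment$seed)
  n <- round(duration / cad)
  out <- data.frame(t = seq_len(n) * cad, v_wave = NA_real_,
                    eps_true = NA_real_, eps_perceived = NA_real_,
                    v_com = NA_real_)
  com_prev <- fluid_com(tube)
  for (d in seq_len(n)) {
    cs <- control_step(tube, wave, policy, geom, t = (d - 1) * cad,
                       profile = profile, mode = config$controller$mode,
                       dv = config$controller$dv,
                       clamp = config$controller$clamp)
    wave <- cs$wave
    res <- dmp_run(tube, bonds, pp, geom, wave, nsteps = round(cad / pp$dt))
    tube <- res$state
    wave <- res$wave
    com <- fluid_com(tube)
    out$v_wave[d] <- wave$v_wave
    out$eps_true[d] <- cs$eps_true
    out$eps_perceived[d] <- cs$eps_perceived
    out$v_com[d] <- (com - com_prev) / cad
    com_prev <- com
    if (verbose && d %% round(1 / cad) == 0)
      message(sprintf("t=%.1f s v_wave=%.3f eps=%.4f", d * cad,
                      wave$v_wave, cs$eps_true))
  }
  attr(out, "mean_v_wave") <- mean(out$v_wave)
  out
}

#' Paired healthy / inflamed runs
#'
#' Runs the adaptive model twice with identical seeds: once healthy, once
#' with the given inflammation profile (time-gated so that the first
#' \code{healthy_duration} seconds are healthy in both).  The physics is
#' identical up to the controller's perception, so any divergence is caused
#' by the perceptual distortion alone.
#'
#' @param config a configuration list.
#' @param policy a \code{policy_net} or policy file path.
#' @param profile an \code{\link{inflammation_profile}}; if it carries no
#'   onset time, the config's \code{healthy_duration} is applied as t0.
#' @param duration total run length (s).
#' @return list(healthy, inflamed, summary): two series as in
#'   \code{\link{run_adaptive}} plus phase-wise mean wave speeds.
#' @export
run_inflamed <- function(config, policy, profile, duration = NULL) {
  if (is.null(profile$t0))
    profile$t0 <- config$experiment$healthy_duration
  healthy <- run_adaptive(config, policy, profile = NULL, duration = duration)
  inflamed <- run_adaptive(config, policy, profile = profile,
                           duration = duration)
  t0 <- profile$t0
  phase_means <- function(d) c(
    healthy_phase = mean(d$v_wave[d$t <= t0]),
    inflamed_phase = mean(d$v_wave[d$t > t0]))
  list(healthy = healthy, inflamed = inflamed,
       summary = data.frame(run = c("healthy", "inflamed"),
                            rbind(phase_means(healthy),
                                  phase_means(inflamed))))
}

#' Write particle frames in extended-XYZ format
#'
#' One frame per call: a count line, a comment line with the lattice and
#' column spec, then one line per particle (id, phase, x, y, z, density).
#'
#' @param state a \code{particle_state}.
#' @param path output file.
#' @param time frame time stamp (s), stored in the comment line.
#' @param append append as the next frame of a trajectory?
#' @export
write_xyz <- function(state, path, time = 0, append = FALSE) {
  n <- nrow(state$pos)
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  writeLines(sprintf(
    'Properties=id:I:1:species:S:1:pos:R:3:density:R:1 Time=%g', time), con)
  writeLines(sprintf("%d %s %.8g %.8g %.8g %.6g",
                     seq_len(n),
                     ifelse(state$phase == 0L, "membrane", "fluid"),
                     state$pos[, 1], state$pos[, 2], state$pos[, 3],
                     state$rho), con)
  invisible(path)
}

#' Command-line interface
#'
#' Verbs: \code{build} (construct the tube, report counts, optionally dump
#' an XYZ frame), \code{sweep}, \code{train}, \code{run-adaptive},
#' \code{run-inflamed}, \code{report} (echo the resolved config).  Each verb
#' takes \code{--config <file>} plus \code{key=value} overrides of the
#' experiment section; all randomness flows from the config seed.
#'
#' @param args character vector of command-line arguments (default:
#'   \code{commandArgs(trailingOnly = TRUE)}).
#' @return invisibly, the verb's result object.
#' @export
peristalsim_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: peristalsim <build|sweep|train|run-adaptive|run-inflamed|report>",
        "[--config file.json] [--preset name] [--out prefix]",
        "[--policy file.json] [key=value ...]\n")
    return(invisible(NULL))
  }
  verb <- args[[1]]
  rest <- args[-1]
  opt <- list(config = NULL, preset = "full", out = "peristalsim", policy = NULL)
  kv <- character(0)
  i <- 1
  while (i <= length(rest)) {
    a <- rest[[i]]
    if (a %in% c("--config", "--preset", "--out", "--policy")) {
      opt[[sub("^--", "", a)]] <- rest[[i + 1]]
      i <- i + 2
    } else {
      kv <- c(kv, a)
      i <- i + 1
    }
  }
  cfg <- if (!is.null(opt$config)) read_config(opt$config)
         else default_config(opt$preset)
  for (pair in kv) {
    parts <- strsplit(pair, "=", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(parts[2]))
    cfg$experiment[[parts[1]]] <- if (is.na(val)) parts[2] else val
  }
  switch(verb,
    "build" = {
      geom <- config_geometry(cfg)
      tube <- build_tube(geom)
      print(geom)
      write_xyz(tube, paste0(opt$out, "_initial.xyz"))
      cat("wrote", paste0(opt$out, "_initial.xyz"), "\n")
      invisible(tube)
    },
    "sweep" = {
      sw <- run_static_sweep(cfg, verbose = TRUE)
      tabfile <- paste0(opt$out, "_sweep.csv")
      write.csv(sw$table, tabfile, row.names = FALSE)
      cat("wrote", tabfile, "\n")
      print(sw$optimum)
      invisible(sw)
    },
    "train" = {
      tc <- do.call(training_config, cfg$training[
        setdiff(names(cfg$training), character(0))])
      env <- physics_env(config_geometry(cfg), config_physics(cfg))
      fit <- cem_train(tc, env, verbose = TRUE)
      pf <- paste0(opt$out, "_policy.json")
      hf <- paste0(opt$out, "_history.csv")
      write_policy(fit$policy, pf)
      write.csv(fit$history, hf, row.names = FALSE)
      cat("wrote", pf, "and", hf, "\n")
      invisible(fit)
    },
    "run-adaptive" = {
      if (is.null(opt$policy)) stop("run-adaptive needs --policy", call. = FALSE)
      series <- run_adaptive(cfg, opt$policy, verbose = TRUE)
      sf <- paste0(opt$out, "_adaptive.csv")
      write.csv(series, sf, row.names = FALSE)
      cat("wrote", sf, sprintf("(mean v_wave %.2f cm/s)\n",
                               100 * attr(series, "mean_v_wave")))
      invisible(series)
    },
    "run-inflamed" = {
      if (is.null(opt$policy)) stop("run-inflamed needs --policy", call. = FALSE)
      profile <- inflammation_profile(cfg$inflammation$regions,
                                      cfg$inflammation$t0)
      res <- run_inflamed(cfg, opt$policy, profile)
      write.csv(res$healthy, paste0(opt$out, "_healthy.csv"), row.names = FALSE)
      write.csv(res$inflamed, paste0(opt$out, "_inflamed.csv"), row.names = FALSE)
      print(res$summary)
      invisible(res)
    },
    "report" = {
      cat(jsonlite::toJSON(cfg, auto_unbox = TRUE, pretty = TRUE,
                           null = "null", digits = NA), "\n")
      invisible(cfg)
    },
    stop("unknown verb: ", verb, call. = FALSE))
}
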