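#' Physics parameters of the coupled particle model
#'
#' All constants of the discrete-multiphysics tube in SI units.  Defaults are
#' the reference configuration: Hookean membrane springs, a weakly
#' compressible Tait fluid with Monaghan-style artificial viscosity, a
#' repulsive cosine coupling potential between membrane and fluid, and a
#' constant-magnitude radial contraction force.
#'
#' The nominal dynamic viscosity \code{mu} is realized through the artificial
#' sound speed: \code{c0 = viscosity_to_c0(mu)} spans 0.005--0.5 m s^-1 over
#' the modelled viscosity decade range 7.8e-3--7.8e-1 Pa s.
#'
#' @param k spring stiffness (N m^-1).
#' @param rho0 reference fluid density (kg m^-3).
#' @param mu nominal dynamic viscosity (Pa s); sets \code{c0} unless \code{c0}
#'   is given explicitly.
#' @param c0 artificial speed of sound (m s^-1).
#' @param alpha artificial-viscosity linear coefficient (dimensionless).
#' @param b artificial-viscosity denominator regularizer (dimensionless).
#' @param h SPH smoothing length = kernel support radius (m).
#' @param A coupling potential amplitude (J).
#' @param r0_couple coupling potential range (m).
#' @param f contraction force magnitude (N) per actuated membrane particle.
#' @param dt integration time step (s).
#' @param m particle mass (kg), uniform.
#' @param kernel SPH kernel: \code{"lucy"} (quartic, default) or
#'   \code{"wendland"} (C2).
#' @param density fluid density handling.  \code{"summation"} (default):
#'   normalized kernel-sum density, \code{rho_i = rho0 * W_i / W_i(0)} with
#'   each particle's freshly built kernel sum as its own reference, so the
#'   initial state has \code{rho = rho0} exactly, densities always track the
#'   actual particle configuration and stay positive.
#'   \code{"continuity"}: continuity-equation integration; at the low end of
#'   the modelled sound speeds (supersonic flow, near-zero pressure) the
#'   integrated density decouples from the configuration and can drift
#'   negative, so this mode is kept for comparison runs only.
#' @param rho_guard length-2 numeric: a run aborts when any fluid density
#'   leaves \code{rho_guard * rho0}.  At the low end of the modelled sound
#'   speeds the flow is locally supersonic, so order-one density excursions
#'   are part of normal operation; the default guard only catches genuine
#'   blow-ups.
#' @return an object of class \code{physics_params}.
#' @export
physics_params <- function(k = 0.5, rho0 = 1000, mu = 7.8e-3,
                           c0 = viscosity_to_c0(mu),
                           alpha = 1, b = 0.01, h = 1.2e-2,
                           A = 2e-6, r0_couple = 6e-3,
                           f = 1e-3, dt = 2e-3, m = 2.5e-4,
                           kernel = c("lucy", "wendland"),
                           density = c("summation", "continuity"),
                           rho_guard = c(0.05, 20)) {
  kernel <- match.arg(kernel)
  density <- match.arg(density)
  if (length(rho_guard) != 2L || rho_guard[1] <= 0 || diff(rho_guard) <= 0)
    stop("rho_guard must be an increasing positive pair", call. = FALSE)
  vals <- c(k = k, rho0 = rho0, mu = mu, c0 = c0, alpha = alpha, b = b,
            h = h, A = A, r0_couple = r0_couple, f = f, dt = dt, m = m)
  if (any(!is.finite(vals)) || any(vals[setdiff(names(vals), "f")] <= 0))
    stop("physics parameters must be positive and finite", call. = FALSE)
  if (f < 0) stop("contraction force must be >= 0", call. = FALSE)
  structure(c(as.list(vals), list(kernel = kernel, density = density,
                                  rho_guard = rho_guard)),
            class = "physics_params")
}

#' Map a nominal viscosity to the artificial sound speed
#'
#' The artificial-viscosity term scales like \code{alpha * h * c0 * rho0}, so
#' the effective dynamic viscosity is proportional to \code{c0}.  The linear
#' map \code{c0 = mu / 1.56} reproduces the modelled decade spacing:
#' mu = 7.8e-3 / 7.8e-2 / 7.8e-1 Pa s map to c0 = 0.005 / 0.05 / 0.5 m s^-1.
#'
#' @param mu dynamic viscosity (Pa s).
#' @return sound speed c0 (m s^-1).
#' @export
viscosity_to_c0 <- function(mu) mu / 1.56

#' Tait equation of state
#'
#' \code{P = (c0^2 rho0 / 7) * ((rho/rho0)^7 - 1)}: zero at the reference
#' density, strictly increasing in density, negative (tension) below it.
#'
#' @param rho particle density (kg m^-3), positive.
#' @param rho0 reference density (kg m^-3).
#' @param c0 speed of sound (m s^-1).
#' @return pressure (Pa).
#' @export
tait_pressure <- function(rho, rho0 = 1000, c0 = 0.005) {
  if (any(rho <= 0)) stop("non-positive density in Tait equation", call. = FALSE)
  (c0^2 * rho0 / 7) * ((rho / rho0)^7 - 1)
}

#' Hookean spring force
#'
#' Force on particle i from a bond to j: magnitude \code{k (|r_ij| - rest)},
#' attractive when stretched, repulsive when compressed, along the pair axis.
#'
#' @param r_ij separation vector r_i - r_j (m).
#' @param rest bond rest length (m).
#' @param k stiffness (N m^-1).
#' @return force vector on i (N).
#' @export
spring_force <- function(r_ij, rest, k = 0.5) {
  r <- sqrt(sum(r_ij^2))
  if (r == 0) stop("coincident particles in spring_force", call. = FALSE)
  -k * (r - rest) * r_ij / r
}

#' Pairwise artificial viscosity
#'
#' \code{Pi_ij = -alpha h c0 (v_ij . r_ij) / (rho_ij (r_ij^2 + b h^2))} with
#' \code{rho_ij = rho_i + rho_j}.  Positive (extra repulsive pressure) for
#' approaching pairs, negative for receding ones, zero for tangential motion;
#' symmetric under particle exchange.  Enters the SPH momentum equation
#' alongside the pressure term.
#'
#' @param v_ij relative velocity v_i - v_j (m s^-1).
#' @param r_ij separation vector r_i - r_j (m).
#' @param rho_i,rho_j densities (kg m^-3), positive.
#' @param params a \code{\link{physics_params}}.
#' @return the scalar Pi_ij.
#' @export
artificial_viscosity <- function(v_ij, r_ij, rho_i, rho_j, params) {
  if (rho_i <= 0 || rho_j <= 0)
    stop("non-positive density in artificial_viscosity", call. = FALSE)
  r2 <- sum(r_ij^2)
  -params$alpha * params$h * params$c0 * sum(v_ij * r_ij) /
    ((rho_i + rho_j) * (r2 + params$b * params$h^2))
}

#' Membrane-fluid coupling force
#'
#' Repulsive force from the anti-compenetration potential
#' \code{U = A (1 + cos(pi r / r0))} for \code{r < r0}:
#' magnitude \code{(A pi / r0) sin(pi r / r0)}, pushing the pair apart,
#' identically zero at and beyond \code{r0} (continuous at the cutoff).
#'
#' @param r_ij separation vector r_i - r_j (m).
#' @param A potential amplitude (J).
#' @param r0 potential range (m).
#' @return force vector on i (N).
#' @export
coupling_force <- function(r_ij, A = 2e-6, r0 = 6e-3) {
  r <- sqrt(sum(r_ij^2))
  if (r >= r0 || r == 0) return(c(0, 0, 0))
  (A * pi / r0) * sin(pi * r / r0) * r_ij / r
}

#' Coupling potential energy
#' @inheritParams coupling_force
#' @return potential energy (J); \code{2A} in the contact limit, 0 beyond r0.
#' @export
coupling_potential <- function(r_ij, A = 2e-6, r0 = 6e-3) {
  r <- sqrt(sum(r_ij^2))
  if (r >= r0) return(0)
  A * (1 + cos(pi * r / r0))
}

#' SPH smoothing kernel
#'
#' The kernel is pluggable through \code{params$kernel}; both choices have
#' compact support of radius \code{h}.
#'
#' @param r pair distance (m), vectorized.
#' @param h support radius (m).
#' @param kernel \code{"lucy"} or \code{"wendland"}.
#' @return kernel value (m^-3).
#' @export
sph_kernel <- function(r, h, kernel = c("lucy", "wendland")) {
  kernel <- match.arg(kernel)
  type <- if (kernel == "wendland") 1L else 0L
  vapply(r, function(ri) cpp_kernel_w(type, ri, h), numeric(1))
}

#' Travelling-wave state
#'
#' @param x_wave axial origin of the contraction window (m), wrapped to
#'   \code{[0, L)}.
#' @param v_wave wave speed (m s^-1).
#' @param mode \code{"static"} (constant speed) or \code{"adaptive"}
#'   (controller-driven).
#' @return an object of class \code{wave_state}.
#' @export
wave_state <- function(x_wave = 0, v_wave = 0,
                       mode = c("static", "adaptive")) {
  structure(list(x_wave = x_wave, v_wave = v_wave, mode = match.arg(mode)),
            class = "wave_state")
}

#' Advance the contraction window
#'
#' \code{x_wave <- (x_wave + v_wave dt) mod L}.
#'
#' @param wave a \code{\link{wave_state}}.
#' @param dt time increment (s).
#' @param L axial period (m).
#' @return the updated wave state.
#' @export
advance_wave <- function(wave, dt, L) {
  wave$x_wave <- (wave$x_wave + wave$v_wave * dt) %% L
  wave
}

engine_params <- function(params, geometry) {
  c(unclass(params), list(dL = geometry$dL, L = geometry$L))
}

#' Evaluate all forces and density rates once
#'
#' Diagnostic single evaluation of the pair forces (pressure + artificial
#' viscosity on fluid-fluid pairs, coupling on membrane-fluid pairs, springs
#' on the bond list), the continuity-equation density rates, and optionally
#' the contraction force on the current window.
#'
#' @param state a \code{particle_state}.
#' @param bonds a \code{bond_set}.
#' @param params a \code{\link{physics_params}}.
#' @param geometry the \code{\link{tube_geometry}}.
#' @param wave a \code{\link{wave_state}}.
#' @param contract apply the contraction force? (default TRUE).
#' @return list with \code{force} (N x 3, N) and \code{drho} (kg m^-3 s^-1).
#' @export
dmp_forces <- function(state, bonds, params, geometry, wave,
                       contract = TRUE) {
  cpp_dmp_forces(state$pos, state$vel, state$rho, state$phase,
                 as.matrix(bonds[, c("i", "j")]), bonds$rest,
                 engine_params(params, geometry),
                 wave$x_wave, contract)
}

#' Advance the coupled system
#'
#' Runs \code{nsteps} velocity-Verlet steps of size \code{params$dt}.  Within
#' the chunk the contraction window moves with the (fixed) current wave
#' speed; call once per controller decision interval for adaptive runs.
#' Densities evolve by the continuity equation; a run aborts with an error if
#' any fluid density leaves \code{[0.5 rho0, 2 rho0]}.
#'
#' @inheritParams dmp_forces
#' @param nsteps number of time steps.
#' @return list(state, wave) with both advanced.
#' @export
dmp_run <- function(state, bonds, params, geometry, wave, nsteps,
                    contract = TRUE) {
  if (is.null(state$wref))
    state <- attach_density_reference(state, params, geometry)
  out <- cpp_dmp_run(state$pos, state$vel, state$rho, state$xun, state$phase,
                     as.matrix(bonds[, c("i", "j")]), bonds$rest,
                     state$wref, if (params$density == "summation") 0L else 1L,
                     engine_params(params, geometry),
                     params$dt, as.integer(nsteps),
                     wave$x_wave, wave$v_wave, contract,
                     params$rho_guard[1], params$rho_guard[2])
  if (out$status != 0L)
    stop(sprintf(paste0("numerical instability: fluid density left ",
                        "[%g rho0, %g rho0] at step %d (particle %d)"),
                 params$rho_guard[1], params$rho_guard[2],
                 out$bad_step, out$bad_particle),
         call. = FALSE)
  state$pos <- out$pos
  colnames(state$pos) <- c("x", "y", "z")
  state$vel <- out$vel
  state$rho <- out$rho
  state$xun <- out$xun
  wave$x_wave <- out$x_wave
  list(state = state, wave = wave)
}

#' Attach the summation-density reference to a freshly built state
#'
#' Computes each fluid particle's kernel sum in the reference (as-built)
#' configuration; the normalized summation density divides by it, so the
#' reference state has density exactly \code{rho0}.  Called automatically by
#' \code{\link{dmp_run}} on first use; call explicitly if the state has
#' already been deformed by other means.
#'
#' @inheritParams dmp_forces
#' @return the state with a \code{wref} field.
#' @export
attach_density_reference <- function(state, params, geometry) {
  state$wref <- cpp_wsum(state$pos, state$phase, engine_params(params, geometry))
  state
}

#' Receiving-segment window
#'
#' The receiving segment is the window of length \code{dL} immediately
#' downstream of the contraction window: \code{[x_wave + dL, x_wave + 2 dL)}
#' modulo \code{L}.
#'
#' @param wave a \code{\link{wave_state}}.
#' @param geometry the \code{\link{tube_geometry}}.
#' @return the window origin (m), wrapped.
#' @export
receiving_window <- function(wave, geometry) {
  (wave$x_wave + geometry$dL) %% geometry$L
}

#' Per-particle diameter strains of the receiving segment
#'
#' For each membrane particle in the receiving segment, the radial Cauchy
#' strain \code{(r - R)/R} of its distance from the tube axis.  These are the
#' controller's raw (particle-neuron dual) inputs.
#'
#' @inheritParams receiving_window
#' @param state a \code{particle_state}.
#' @return numeric vector of strains (one per member particle).
#' @export
segment_strains <- function(state, wave, geometry) {
  x0 <- receiving_window(wave, geometry)
  mem <- which(state$phase == 0L)
  idx <- mem[window_members(state$pos[mem, 1], x0, geometry$dL, geometry$L)]
  if (length(idx) == 0L)
    stop("receiving segment is empty", call. = FALSE)
  sqrt(state$pos[idx, 2]^2 + state$pos[idx, 3]^2) / geometry$R - 1
}

#' Mean diameter strain of the receiving segment
#'
#' Ring-wise estimator: for each membrane ring whose centre lies in the
#' receiving segment, the ring diameter is twice the mean radial distance of
#' its particles from the axis; the ring strain is \code{(d - 2R)/(2R)} and
#' \code{epsilon} is the mean over rings.  Rings are identified by
#' construction order (\code{build_membrane} is ring-major) and located by
#' the circular mean of their current axial positions.
#'
#' @inheritParams segment_strains
#' @return scalar strain (dimensionless fraction).
#' @export
measure_strain <- function(state, wave, geometry) {
  x0 <- receiving_window(wave, geometry)
  mem <- which(state$phase == 0L)
  np <- geometry$n_per_ring
  nr <- geometry$n_rings
  stopifnot(length(mem) == np * nr)
  px <- state$pos[mem, 1]
  ring <- rep(seq_len(nr), each = np)
  # circular mean of each ring's axial position
  th <- 2 * pi * px / geometry$L
  cx <- vapply(split(cos(th), ring), mean, numeric(1))
  sx <- vapply(split(sin(th), ring), mean, numeric(1))
  ring_x <- (atan2(sx, cx) / (2 * pi) * geometry$L) %% geometry$L
  sel <- window_members(ring_x, x0, geometry$dL, geometry$L)
  if (length(sel) == 0L)
    stop("receiving segment contains no membrane rings", call. = FALSE)
  rad <- sqrt(state$pos[mem, 2]^2 + state$pos[mem, 3]^2)
  ring_rad <- vapply(split(rad, ring), mean, numeric(1))
  mean(ring_rad[sel] / geometry$R - 1)
}

#' Fluid centre-of-mass position (unwrapped)
#'
#' @param state a \code{particle_state} with unwrapped axial coordinates.
#' @return mass-weighted mean unwrapped axial coordinate of the fluid (m).
#' @export
fluid_com <- function(state) {
  flu <- state$phase == 1L
  if (!any(flu)) return(NA_real_)
  mean(state$xun[flu])  # uniform masses
}

#' Centre-of-mass velocity series from sampled COM positions
#'
#' \code{v_COM(t)} is the finite difference of the fluid centre of mass over
#' the reporting interval.
#'
#' @param com vector of COM positions (m) sampled every \code{cadence} s.
#' @param cadence sampling interval (s), default 0.1.
#' @return vector of length \code{length(com) - 1} (m s^-1).
#' @export
vcom_series <- function(com, cadence = 0.1) {
  if (length(com) < 2) return(numeric(0))
  diff(com) / cadence
}

#' Plateau statistic of a time series
#'
#' Mean over the final window of the series; the default 1 s window at the
#' 0.1 s observable cadence averages the last 10 samples.
#'
#' @param series numeric vector sampled at \code{cadence}.
#' @param window plateau window (s).
#' @param cadence sampling interval (s).
#' @return scalar mean of the final window.
#' @export
plateau <- function(series, window = 1, cadence = 0.1) {
  n <- max(1L, round(window / cadence))
  if (length(series) < n)
    stop("series shorter than the plateau window", call. = FALSE)
  mean(series[(length(series) - n + 1L):length(series)])
}

#' Run a constant-wave-speed simulation
#'
#' Builds nothing: takes a prepared system and integrates it for
#' \code{duration} seconds at fixed wave speed, sampling the observables
#' (receiving-segment strain and fluid COM velocity) every \code{cadence}
#' seconds.
#'
#' @param state,bonds,params,geometry,wave as in \code{\link{dmp_run}}.
#' @param duration simulated time (s).
#' @param cadence observable sampling interval (s).
#' @return data.frame with columns t, v_wave, epsilon, v_com (first row is
#'   the initial sample with v_com = 0).
#' @export
simulate_static <- function(state, bonds, params, geometry, wave,
                            duration = 10, cadence = 0.1) {
  steps_per <- round(cadence / params$dt)
  n_chunks <- round(duration / cadence)
  t <- numeric(n_chunks + 1)
  eps <- numeric(n_chunks + 1)
  com <- numeric(n_chunks + 1)
  eps[1] <- measure_strain(state, wave, geometry)
  com[1] <- fluid_com(state)
  for (ch in seq_len(n_chunks)) {
    res <- dmp_run(state, bonds, params, geometry, wave, steps_per)
    state <- res$state
    wave <- res$wave
    t[ch + 1] <- ch * cadence
    eps[ch + 1] <- measure_strain(state, wave, geometry)
    com[ch + 1] <- fluid_com(state)
  }
  data.frame(t = t,
             v_wave = wave$v_wave,
             epsilon = eps,
             v_com = c(0, vcom_series(com, cadence)))
}
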