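#' Training configuration for the cross-entropy method
#'
#' Defaults follow the reference setup: 20 000 five-second episodes in
#' batches of 10, one elite-selection + gradient pass per batch at the 70th
#' reward percentile, a log-uniform random viscosity per episode spanning
#' the three modelled decades, and the Adam optimizer on a categorical
#' cross-entropy loss.
#'
#' @param episodes total number of episodes.
#' @param batch_size episodes per batch (>= 2).
#' @param elite_percentile keep episodes at or above this reward percentile
#'   of the batch (70 keeps the top 30\%).
#' @param mu_range viscosity range (Pa s) sampled log-uniformly.
#' @param mu_sampling \code{"per_episode"} (each episode draws its own
#'   viscosity, default) or \code{"per_batch"} (one draw shared by the whole
#'   batch).
#' @param duration episode length (s).
#' @param cadence controller decision interval (s).
#' @param dv wave-speed increment per action (m s^-1).
#' @param clamp wave-speed clamp (m s^-1).
#' @param lr Adam learning rate.
#' @param seed base RNG seed; episode seeds are derived from it.
#' @return an object of class \code{training_config}.
#' @export
training_config <- function(episodes = 20000, batch_size = 10,
                            elite_percentile = 70,
                            mu_range = c(7.8e-3, 7.8e-1),
                            mu_sampling = c("per_episode", "per_batch"),
                            duration = 5, cadence = 0.1,
                            dv = 1e-3, clamp = c(0, 0.15),
                            lr = 1e-3, seed = 1) {
  mu_sampling <- match.arg(mu_sampling)
  if (batch_size < 2) stop("batch size must be >= 2", call. = FALSE)
  if (elite_percentile <= 0 || elite_percentile >= 100)
    stop("elite percentile must lie in (0, 100)", call. = FALSE)
  structure(list(episodes = episodes, batch_size = batch_size,
                 elite_percentile = elite_percentile, mu_range = mu_range,
                 mu_sampling = mu_sampling, duration = duration,
                 cadence = cadence, dv = dv, clamp = clamp,
                 lr = lr, seed = seed),
            class = "training_config")
}

#' Draw random episode viscosities
#'
#' Log-uniform over \code{range}: equal probability per decade, matching the
#' decade spacing of the three reference viscosities.
#'
#' @param n number of draws.
#' @param range viscosity range (Pa s).
#' @return viscosities (Pa s).
#' @export
sample_viscosity <- function(n = 1, range = c(7.8e-3, 7.8e-1))
  exp(runif(n, log(range[1]), log(range[2])))

#' Physics episode environment
#'
#' Wraps a tube geometry into the episode interface used by
#' \code{\link{run_episode}}: \code{reset(mu)} builds the tube at rest and
#' returns the environment state, \code{strains(es)} reads the
#' receiving-segment strains, \code{advance(es, v_wave, dt)} integrates the
#' coupled physics, and \code{reward(es, duration)} is the net axial
#' centre-of-mass displacement of the fluid divided by the episode duration
#' (a time-averaged v_COM).
#'
#' @param geometry a \code{\link{tube_geometry}} (or preset name).
#' @param base_params a \code{\link{physics_params}} whose non-viscosity
#'   entries are reused for every episode.
#' @return an environment object (list of closures) of class
#'   \code{episode_env}.
#' @export
physics_env <- function(geometry = "micro", base_params = physics_params()) {
  if (is.character(geometry)) geometry <- geometry_preset(geometry)
  tube0 <- build_tube(geometry)
  bonds <- build_springs(tube0, geometry$spring_cutoff, geometry$L)
  tube0 <- attach_density_reference(tube0, base_params, geometry)
  structure(list(
    n_input = with(geometry, n_per_ring * round(dL / (L / n_rings))),
    reset = function(mu) {
      params <- base_params
      params$mu <- mu
      params$c0 <- viscosity_to_c0(mu)
      list(state = tube0, wave = wave_state(0, 0, mode = "adaptive"),
           params = params, com0 = fluid_com(tube0), failed = FALSE)
    },
    strains = function(es) segment_strains(es$state, es$wave, geometry),
    advance = function(es, v_wave, dt) {
      es$wave$v_wave <- v_wave
      res <- tryCatch(
        dmp_run(es$state, bonds, es$params, geometry, es$wave,
                nsteps = round(dt / es$params$dt)),
        error = function(e) e)
      if (inherits(res, "error")) { es$failed <- TRUE; return(es) }
      es$state <- res$state
      es$wave <- res$wave
      es
    },
    reward = function(es, duration) {
      if (es$failed) return(-Inf)
      (fluid_com(es$state) - es$com0) / duration
    }),
    class = "episode_env")
}

#' Analytic surrogate environment
#'
#' A fast stand-in for the physics with the same episode interface, for
#' trainer correctness tests.  The wall strain responds instantaneously and
#' monotonically to the product of wave speed and viscosity,
#' \code{eps = c_eps * v * mu / mu_ref}.  The reward is the episode-time
#' average of the smooth unimodal transport rate
#' \code{g(v) = (v/v_opt) exp(1 - v/v_opt) * v_opt}: for a constant-speed
#' rollout this reduces to \code{g(vbar)}, maximized at the known optimum
#' \code{v_opt}, and like the real tube (where excessive speed causes
#' backflow while the wave runs) it penalizes overshoot as it happens, which
#' is what makes the back-off action learnable.
#'
#' @param v_opt optimal wave speed (m s^-1).
#' @param c_eps strain per unit wave speed at the reference viscosity
#'   (s m^-1); the default puts eps ~ 6\% at v = 5 cm s^-1.
#' @param mu_ref reference viscosity (Pa s).
#' @param n_input nominal input width reported to the controller.
#' @return an \code{episode_env}.
#' @export
surrogate_env <- function(v_opt = 0.01, c_eps = 1.2, mu_ref = 7.8e-2,
                          n_input = 250) {
  g <- function(v) (v / v_opt) * exp(1 - v / v_opt) * v_opt
  structure(list(
    n_input = n_input,
    v_opt = v_opt,
    reward_fn = g,
    reset = function(mu) list(mu = mu, v = 0, disp = 0, racc = 0, t = 0,
                              failed = FALSE),
    strains = function(es) rep(c_eps * es$v * es$mu / mu_ref, n_input),
    advance = function(es, v_wave, dt) {
      es$v <- v_wave
      es$disp <- es$disp + v_wave * dt
      es$racc <- es$racc + g(v_wave) * dt
      es$t <- es$t + dt
      es
    },
    reward = function(es, duration) es$racc / duration),
    class = "episode_env")
}

#' Run one training or evaluation episode
#'
#' Starts the environment at rest, then every \code{cadence} seconds reads
#' the receiving-segment strains, pools them, applies the optional
#' inflammation perception map, evaluates the policy, selects an action
#' (stochastic in training, greedy in evaluation) and advances the
#' environment at the updated wave speed.  Records the (perceived strain,
#' action) pair of every decision and the scalar episode reward.
#'
#' @param policy a \code{\link{policy_new}} network.
#' @param mu episode viscosity (Pa s).
#' @param seed RNG seed for this episode's action sampling.
#' @param env an \code{episode_env}.
#' @param mode \code{"sample"} or \code{"greedy"}.
#' @param duration episode length (s).
#' @param cadence decision interval (s).
#' @param dv,clamp action parameters, see \code{\link{apply_action}}.
#' @param perceive_fn optional function(eps_true, t) -> perceived strain.
#' @return an \code{episode_record}: list(mu, eps, action, v_wave, reward,
#'   seed, failed).
#' @export
run_episode <- function(policy, mu, seed, env, mode = c("sample", "greedy"),
                        duration = 5, cadence = 0.1,
                        dv = 1e-3, clamp = c(0, 0.15),
                        perceive_fn = NULL) {
  mode <- match.arg(mode)
  set.seed(seed)
  es <- env$reset(mu)
  n_dec <- round(duration / cadence)
  deltas <- c(dv, 0, -dv)
  eps <- numeric(n_dec)
  act <- integer(n_dec)
  vws <- numeric(n_dec)
  v_wave <- 0
  for (d in seq_len(n_dec)) {
    e_true <- pool_strains(env$strains(es))
    e_per <- if (is.null(perceive_fn)) e_true else
      perceive_fn(e_true, (d - 1) * cadence)
    probs <- policy_forward(policy, e_per)
    a <- select_action(probs, mode)
    v_wave <- min(max(v_wave + deltas[a], clamp[1]), clamp[2])
    eps[d] <- e_per
    act[d] <- a
    vws[d] <- v_wave
    es <- env$advance(es, v_wave, cadence)
    if (isTRUE(es$failed)) break
  }
  structure(list(mu = mu, eps = eps, action = act, v_wave = vws,
                 reward = env$reward(es, duration), seed = seed,
                 failed = isTRUE(es$failed)),
            class = "episode_record")
}

#' Elite selection
#'
#' Keeps the episodes whose reward is at or above the batch's
#' \code{percentile} reward (type-7 quantile); for a batch of 10 at the 70th
#' percentile that is the top 3, with ties at the threshold all included.
#' Failed episodes carry a \code{-Inf} sentinel reward and can never be
#' elite.
#'
#' @param batch list of \code{episode_record}s (>= 2).
#' @param percentile elite percentile in (0, 100).
#' @return the elite subset (possibly the whole batch when all rewards tie).
#' @export
select_elites <- function(batch, percentile = 70) {
  if (length(batch) < 2) stop("need at least 2 episodes", call. = FALSE)
  rewards <- vapply(batch, function(b) b$reward, numeric(1))
  ok <- is.finite(rewards)
  if (!any(ok)) return(batch[0])
  thr <- quantile(rewards[ok], percentile / 100, type = 7, names = FALSE)
  batch[ok & rewards >= thr]
}

#' Adam optimizer state
#'
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param epsilon numerical regularizer.
#' @return an optimizer object consumed by \code{\link{train_on_elites}}.
#' @export
adam_opt <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7)
  structure(list(lr = lr, beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 t = 0L, m = NULL, v = NULL),
            class = "adam_opt")

# gradient of the mean categorical cross-entropy over (eps, action) pairs
policy_gradient <- function(policy, eps, action) {
  n <- length(eps)
  fw <- policy_forward_full(policy, eps)
  D3 <- fw$probs
  D3[cbind(seq_len(n), action)] <- D3[cbind(seq_len(n), action)] - 1
  D3 <- D3 / n
  gW3 <- t(fw$A2) %*% D3
  gb3 <- colSums(D3)
  D2 <- (D3 %*% t(policy$W3)) * (fw$A2 > 0)
  gW2 <- t(fw$A1) %*% D2
  gb2 <- colSums(D2)
  D1 <- (D2 %*% t(policy$W2)) * (fw$A1 > 0)
  gW1 <- t(matrix(eps, n, 1)) %*% D1
  gb1 <- colSums(D1)
  loss <- -mean(log(pmax(fw$probs[cbind(seq_len(n), action)], 1e-12)))
  list(grad = c(gW1, gb1, gW2, gb2, gW3, gb3), loss = loss)
}

#' Fit the policy to the elite state-action pairs
#'
#' One full-batch Adam step minimizing the categorical cross-entropy between
#' the policy's action distribution at each recorded strain and the one-hot
#' action the elite episode actually took.
#'
#' @param policy a \code{\link{policy_new}} network.
#' @param elites non-empty list of \code{episode_record}s.
#' @param opt an \code{\link{adam_opt}} state.
#' @return list(policy, opt, loss) with the updated network and optimizer.
#' @export
train_on_elites <- function(policy, elites, opt = adam_opt()) {
  if (length(elites) == 0) stop("empty elite set", call. = FALSE)
  eps <- unlist(lapply(elites, function(e) e$eps[seq_along(e$action)]))
  action <- unlist(lapply(elites, function(e) e$action))
  pg <- policy_gradient(policy, eps, action)
  if (!is.finite(pg$loss))
    stop("non-finite training loss", call. = FALSE)
  theta <- policy_flatten(policy)
  if (is.null(opt$m)) { opt$m <- numeric(length(theta)); opt$v <- numeric(length(theta)) }
  opt$t <- opt$t + 1L
  opt$m <- opt$beta1 * opt$m + (1 - opt$beta1) * pg$grad
  opt$v <- opt$beta2 * opt$v + (1 - opt$beta2) * pg$grad^2
  mhat <- opt$m / (1 - opt$beta1^opt$t)
  vhat <- opt$v / (1 - opt$beta2^opt$t)
  theta <- theta - opt$lr * mhat / (sqrt(vhat) + opt$epsilon)
  list(policy = policy_unflatten(policy, theta), opt = opt, loss = pg$loss)
}

#' Cross-entropy-method training loop
#'
#' Iterates: draw episode viscosities, run a batch of stochastic rollouts,
#' keep the elite fraction, fit the policy to the elite state-action pairs.
#' Fully reproducible: (config, env) and the config seed determine every
#' episode seed, so the reward history is identical across runs.
#'
#' @param config a \code{\link{training_config}}.
#' @param env an \code{episode_env} (physics or surrogate).
#' @param policy optional starting network (default: fresh Glorot init from
#'   the config seed).
#' @param train set FALSE to disable the gradient pass (diagnostic baseline
#'   with a frozen random policy).
#' @param verbose print one line per batch.
#' @return list(policy, history, opt); history is a data.frame with one row
#'   per batch: batch, mean_reward, elite_threshold, loss.
#' @export
cem_train <- function(config = training_config(), env,
                      policy = NULL, train = TRUE, verbose = FALSE) {
  n_batches <- floor(config$episodes / config$batch_size)
  if (is.null(policy))
    policy <- policy_new(n_input = env$n_input, seed = config$seed)
  opt <- adam_opt(lr = config$lr)
  hist <- data.frame(batch = seq_len(n_batches), mean_reward = NA_real_,
                     elite_threshold = NA_real_, loss = NA_real_)
  ep_counter <- 0L
  for (b in seq_len(n_batches)) {
    set.seed(config$seed + 7L * b)
    mus <- if (config$mu_sampling == "per_batch")
      rep(sample_viscosity(1, config$mu_range), config$batch_size)
    else
      sample_viscosity(config$batch_size, config$mu_range)
    batch <- vector("list", config$batch_size)
    for (i in seq_len(config$batch_size)) {
      ep_counter <- ep_counter + 1L
      batch[[i]] <- run_episode(policy, mus[i],
                                seed = config$seed + 131L * ep_counter,
                                env = env, mode = "sample",
                                duration = config$duration,
                                cadence = config$cadence,
                                dv = config$dv, clamp = config$clamp)
    }
    rewards <- vapply(batch, function(e) e$reward, numeric(1))
    elites <- select_elites(batch, config$elite_percentile)
    hist$mean_reward[b] <- mean(rewards[is.finite(rewards)])
    hist$elite_threshold[b] <- if (length(elites))
      min(vapply(elites, function(e) e$reward, numeric(1))) else NA_real_
    if (train && length(elites)) {
      fit <- train_on_elites(policy, elites, opt)
      policy <- fit$policy
      opt <- fit$opt
      hist$loss[b] <- fit$loss
    }
    if (verbose)
      message(sprintf("batch %d/%d mean reward %.5f elite thr %.5f",
                      b, n_batches, hist$mean_reward[b], hist$elite_threshold[b]))
  }
  list(policy = policy, history = hist, opt = opt)
}
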