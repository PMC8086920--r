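#' Stretch-sensing policy network
#'
#' The controller that imitates the enteric neuromechanical loop: the
#' membrane particles of the receiving segment are its input layer
#' (particle-neuron duals, one strain per particle), a pooling stage averages
#' them to the scalar strain \code{epsilon}, two rectified-linear hidden
#' layers of 100 units follow, and a 3-unit softmax output gives the
#' probabilities of increasing, maintaining or decreasing the wave speed.
#'
#' The physical input layer has \code{n_input} neurons (250 in the reference
#' geometry) even though pooling reduces it to one scalar; this preserves the
#' particle-neuron dual structure and leaves room for non-pooled variants.
#'
#' @param n_input number of input neurons = receiving-segment particles.
#' @param hidden hidden layer widths.
#' @param n_actions output units (3: increase / maintain / decrease).
#' @param init \code{"glorot"} (uniform Glorot) or \code{"zeros"}.
#' @param seed RNG seed for the initialization draw.
#' @return an object of class \code{policy_net} with weight matrices
#'   \code{W1, b1, W2, b2, W3, b3}.
#' @export
policy_new <- function(n_input = 250, hidden = c(100, 100), n_actions = 3,
                       init = c("glorot", "zeros"), seed = NULL) {
  init <- match.arg(init)
  stopifnot(length(hidden) == 2)
  if (!is.null(seed)) set.seed(seed)
  glorot <- function(nin, nout) {
    if (init == "zeros") return(matrix(0, nin, nout))
    lim <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -lim, lim), nin, nout)
  }
  structure(list(
    n_input = as.integer(n_input),
    hidden = as.integer(hidden),
    n_actions = as.integer(n_actions),
    W1 = glorot(1, hidden[1]),          b1 = rep(0, hidden[1]),
    W2 = glorot(hidden[1], hidden[2]),  b2 = rep(0, hidden[2]),
    W3 = glorot(hidden[2], n_actions),  b3 = rep(0, n_actions)),
    class = "policy_net")
}

#' @export
print.policy_net <- function(x, ...) {
  cat(sprintf("policy_net: %d inputs -> pool -> %s -> %d actions (%d parameters)\n",
              x$n_input, paste(x$hidden, collapse = " -> "), x$n_actions,
              length(policy_flatten(x))))
  invisible(x)
}

policy_flatten <- function(policy)
  c(policy$W1, policy$b1, policy$W2, policy$b2, policy$W3, policy$b3)

policy_unflatten <- function(policy, theta) {
  shapes <- list(W1 = dim(policy$W1), b1 = length(policy$b1),
                 W2 = dim(policy$W2), b2 = length(policy$b2),
                 W3 = dim(policy$W3), b3 = length(policy$b3))
  off <- 0L
  for (nm in names(shapes)) {
    sz <- prod(shapes[[nm]])
    vals <- theta[(off + 1L):(off + sz)]
    policy[[nm]] <- if (length(shapes[[nm]]) == 2L)
      matrix(vals, shapes[[nm]][1], shapes[[nm]][2]) else vals
    off <- off + sz
  }
  policy
}

#' Pooling stage: average the receiving-segment strains
#'
#' @param strains per-particle strains of the receiving segment.
#' @param n_expected expected cardinality (the policy's input width); an
#'   input of any other length is rejected.
#' @return the scalar mean strain.
#' @export
pool_strains <- function(strains, n_expected = length(strains)) {
  if (length(strains) != n_expected)
    stop(sprintf("pooling expected %d strains, got %d",
                 n_expected, length(strains)), call. = FALSE)
  mean(strains)
}

#' Forward pass of the policy network
#'
#' Evaluates the network on the pooled strain.  Accepts a vector of strains
#' (rows of the returned matrix) for batched evaluation.
#'
#' @param policy a \code{\link{policy_new}} network.
#' @param eps pooled strain(s), dimensionless.
#' @return probability vector (or matrix, one row per input) over the
#'   actions increase / maintain / decrease.
#' @export
policy_forward <- function(policy, eps) {
  if (any(!is.finite(eps))) stop("non-finite strain input", call. = FALSE)
  if (length(eps) == 1L) {
    # scalar fast path (hot loop of episode rollouts)
    a1 <- pmax(eps * policy$W1[1L, ] + policy$b1, 0)
    a2 <- pmax(drop(a1 %*% policy$W2) + policy$b2, 0)
    z3 <- drop(a2 %*% policy$W3) + policy$b3
    e <- exp(z3 - max(z3))
    return(e / sum(e))
  }
  policy_forward_full(policy, eps)$probs
}

# forward pass keeping intermediate activations (for backprop)
policy_forward_full <- function(policy, eps) {
  n <- length(eps)
  A1 <- matrix(eps, n, 1) %*% policy$W1 +
        matrix(policy$b1, n, length(policy$b1), byrow = TRUE)
  A1 <- pmax(A1, 0)
  A2 <- A1 %*% policy$W2 +
        matrix(policy$b2, n, length(policy$b2), byrow = TRUE)
  A2 <- pmax(A2, 0)
  Z3 <- A2 %*% policy$W3 +
        matrix(policy$b3, n, length(policy$b3), byrow = TRUE)
  Z3 <- Z3 - apply(Z3, 1, max)   # stabilized softmax
  E <- exp(Z3)
  list(A1 = A1, A2 = A2, probs = E / rowSums(E))
}

#' Action set of the wave-speed controller
#'
#' Three actions: increase the wave speed by \code{dv}, maintain it, or
#' decrease it by \code{dv}.  The default step is 0.1 cm s^-1.
#'
#' @param dv speed increment (m s^-1).
#' @return data.frame of actions and speed deltas.
#' @export
action_set <- function(dv = 1e-3)
  data.frame(action = c("increase", "maintain", "decrease"),
             delta = c(dv, 0, -dv))

#' Select an action from the output probabilities
#'
#' @param probs probability triple from \code{\link{policy_forward}}.
#' @param mode \code{"sample"} draws from the distribution (training
#'   rollouts); \code{"greedy"} takes the argmax (evaluation runs), breaking
#'   ties toward the lowest action index.
#' @return the 1-based action index.
#' @export
select_action <- function(probs, mode = c("sample", "greedy")) {
  mode <- match.arg(mode)
  if (length(probs) < 2 || any(probs < -1e-9) || abs(sum(probs) - 1) > 1e-6)
    stop("invalid action distribution", call. = FALSE)
  if (mode == "greedy") return(which.max(probs))
  sample.int(length(probs), 1L, prob = pmax(probs, 0))
}

#' Apply an action to the wave state
#'
#' \code{v_wave <- clip(v_wave + delta, clamp[1], clamp[2])}.  The floor of
#' the default clamp is physical (no retrograde wave); the ceiling is a
#' numerical safety margin at 1.5x the largest swept speed.
#'
#' @param wave a \code{\link{wave_state}}.
#' @param action 1-based action index (see \code{\link{action_set}}).
#' @param dv speed increment (m s^-1).
#' @param clamp numeric pair \code{c(v_min, v_max)} (m s^-1).
#' @return the updated wave state.
#' @export
apply_action <- function(wave, action, dv = 1e-3, clamp = c(0, 0.15)) {
  delta <- action_set(dv)$delta[action]
  wave$v_wave <- min(max(wave$v_wave + delta, clamp[1]), clamp[2])
  wave
}

#' One controller decision
#'
#' Executed once per 0.1 s of simulated time during adaptive runs: read the
#' receiving-segment strains at the window's current location (the network
#' slides with the wave: input is always the receiving segment, output the
#' contracting segment), apply the inflammation perception map if one is
#' configured, pool, run the forward pass, select an action and update the
#' wave speed.  In \code{"static"} wave mode the controller is bypassed.
#'
#' @param state a \code{particle_state}.
#' @param wave a \code{\link{wave_state}}.
#' @param policy a \code{\link{policy_new}} network.
#' @param geometry the \code{\link{tube_geometry}}.
#' @param t current simulation time (s), used by time-gated inflammation.
#' @param profile optional \code{\link{inflammation_profile}}.
#' @param mode action selection mode, see \code{\link{select_action}}.
#' @param dv,clamp see \code{\link{apply_action}}.
#' @return list(wave, eps_true, eps_perceived, action).
#' @export
control_step <- function(state, wave, policy, geometry, t = 0,
                         profile = NULL, mode = c("sample", "greedy"),
                         dv = 1e-3, clamp = c(0, 0.15)) {
  if (wave$mode == "static")
    return(list(wave = wave, eps_true = NA_real_,
                eps_perceived = NA_real_, action = NA_integer_))
  # pooling is width-agnostic, so slight fluctuations of the member count
  # under deformation (rings drifting across the half-open window edge) are
  # tolerated; policy$n_input is the nominal width.
  strains <- segment_strains(state, wave, geometry)
  eps_true <- pool_strains(strains)
  eps_per <- if (is.null(profile)) eps_true else
    perceive(eps_true,
             x = (receiving_window(wave, geometry) + geometry$dL / 2) %% geometry$L,
             t = t, profile = profile, L = geometry$L)
  probs <- policy_forward(policy, eps_per)
  act <- select_action(probs, mode)
  list(wave = apply_action(wave, act, dv, clamp),
       eps_true = eps_true, eps_perceived = eps_per, action = act)
}

#' Serialize a policy to a portable JSON file
#'
#' Stores the architecture descriptor and flat parameter arrays; the
#' round-trip restores the network bit-for-bit (doubles are written in full
#' precision).
#'
#' @param policy a \code{\link{policy_new}} network.
#' @param path output file path.
#' @export
write_policy <- function(policy, path) {
  obj <- list(format = "peristalsim-policy-1",
              n_input = policy$n_input, hidden = policy$hidden,
              n_actions = policy$n_actions,
              theta = policy_flatten(policy))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Restore a policy written by \code{\link{write_policy}}
#'
#' @param path file path.
#' @param expect_input optional input width; a mismatch (e.g. loading a
#'   full-tube policy for a mini geometry) is an error naming both widths.
#' @return a \code{policy_net}.
#' @export
read_policy <- function(path, expect_input = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "peristalsim-policy-1")
    stop("not a peristalsim policy file: ", path, call. = FALSE)
  pol <- policy_new(n_input = obj$n_input, hidden = obj$hidden,
                    n_actions = obj$n_actions, init = "zeros")
  pol <- policy_unflatten(pol, obj$theta)
  if (!is.null(expect_input) && pol$n_input != expect_input)
    stop(sprintf("policy architecture mismatch: file has %d inputs, geometry needs %d",
                 pol$n_input, expect_input), call. = FALSE)
  pol
}
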