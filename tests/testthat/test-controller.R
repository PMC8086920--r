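test_that("pooling is the plain arithmetic mean and rejects bad cardinality", {
  expect_identical(pool_strains(rep(0.06, 250), 250), 0.06)
  set.seed(5)
  x <- rnorm(250, 0.05, 0.01)
  expect_identical(pool_strains(x, 250), pool_strains(sample(x), 250))
  expect_equal(pool_strains(x, 250), sum(x) / 250)
  expect_error(pool_strains(x[-1], 250), "expected 250")
})

test_that("forward pass is a valid softmax classifier", {
  # zero-initialized network: equal logits -> uniform distribution
  pol0 <- policy_new(init = "zeros")
  expect_equal(policy_forward(pol0, 0.37), rep(1 / 3, 3))
  expect_equal(policy_forward(pol0, -2), rep(1 / 3, 3))
  # probabilities sum to 1 for random parameter draws
  set.seed(9)
  for (i in 1:100) {
    pol <- policy_new(seed = i)
    p <- policy_forward(pol, runif(1, -0.5, 0.5))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  expect_error(policy_forward(pol0, NaN), "finite")
})

test_that("forward pass matches a hand-evaluated toy network", {
  # 2-unit hidden layers with hand-set weights, evaluated by explicit
  # matrix arithmetic here and compared against the implementation
  pol <- policy_new(n_input = 4, hidden = c(2, 2), init = "zeros")
  pol$W1 <- matrix(c(1, -2), 1, 2)
  pol$b1 <- c(0.1, 0.2)
  pol$W2 <- matrix(c(0.5, -1, 2, 0.3), 2, 2)
  pol$b2 <- c(0, -0.1)
  pol$W3 <- matrix(c(1, 0, -1, 0.2, 0.4, 0), 2, 3)
  pol$b3 <- c(0.05, 0, -0.05)
  eps <- 0.07
  a1 <- pmax(c(eps * 1 + 0.1, eps * -2 + 0.2), 0)
  a2 <- pmax(c(a1[1] * 0.5 + a1[2] * -1, a1[1] * 2 + a1[2] * 0.3 - 0.1), 0)
  z3 <- c(a2[1] * 1 + a2[2] * 0 + 0.05,
          a2[1] * -1 + a2[2] * 0.2,
          a2[1] * 0.4 + a2[2] * 0 - 0.05)
  expect_equal(policy_forward(pol, eps), exp(z3) / sum(exp(z3)),
               tolerance = 1e-14)
})

test_that("action selection follows the distribution and the tie rule", {
  expect_identical(select_action(c(1, 0, 0), "sample"), 1L)
  expect_identical(select_action(c(1, 0, 0), "greedy"), 1L)
  # empirical frequencies within 3 sigma of the multinomial expectation
  set.seed(13)
  draws <- replicate(1e5, select_action(c(0.2, 0.3, 0.5), "sample"))
  for (k in 1:3) {
    p <- c(0.2, 0.3, 0.5)[k]
    expect_lt(abs(sum(draws == k) - 1e5 * p), 3 * sqrt(1e5 * p * (1 - p)))
  }
  # greedy tie-break: lowest index
  expect_identical(select_action(c(0.5, 0.5, 0), "greedy"), 1L)
  expect_error(select_action(c(0.5, 0.2), "sample"), "invalid")
})

test_that("actions move and clamp the wave speed", {
  w <- wave_state(0, 0, mode = "adaptive")
  expect_equal(apply_action(w, 3)$v_wave, 0)             # floor
  w$v_wave <- 0.05
  expect_equal(apply_action(w, 1)$v_wave, 0.051)
  expect_equal(apply_action(w, 2)$v_wave, 0.05)
  w$v_wave <- 0
  for (i in 1:10) w <- apply_action(w, 1)
  expect_equal(w$v_wave, 0.01)
  w$v_wave <- 0.15
  expect_equal(apply_action(w, 1)$v_wave, 0.15)          # ceiling
})

test_that("the controller sees the membrane only through the pooled strain", {
  # permuting the receiving-segment strains never changes the distribution
  pol <- policy_new(n_input = 20, seed = 4)
  set.seed(21)
  strains <- rnorm(20, 0.04, 0.02)
  p_ref <- policy_forward(pol, pool_strains(strains, 20))
  for (i in 1:10)
    expect_identical(policy_forward(pol, pool_strains(sample(strains), 20)),
                     p_ref)
})

test_that("control_step honours the mode gate and the inflammation map", {
  gm <- geometry_preset("micro")
  st <- build_tube(gm)
  pol <- policy_new(n_input = 20, init = "zeros", seed = 1)
  # static mode: controller bypassed
  wv <- wave_state(0, 0.03, mode = "static")
  cs <- control_step(st, wv, pol, gm)
  expect_identical(cs$wave$v_wave, 0.03)
  expect_true(is.na(cs$action))
  # adaptive mode on a distended segment with 50% inflammation: the pooled
  # input doubles
  wv <- wave_state(0, 0.03, mode = "adaptive")
  x0 <- receiving_window(wv, gm)
  mem <- which(st$phase == 0L)
  idx <- mem[window_members(st$pos[mem, 1], x0, gm$dL, gm$L)]
  st$pos[idx, 2:3] <- st$pos[idx, 2:3] * 1.04
  prof <- inflammation_profile(data.frame(x_start = 0, x_end = gm$L, phi = 50))
  set.seed(2)
  cs <- control_step(st, wv, pol, gm, t = 0, profile = prof)
  expect_equal(cs$eps_true, 0.04, tolerance = 1e-10)
  expect_equal(cs$eps_perceived, 2 * cs$eps_true, tolerance = 1e-12)
})

test_that("a 5 s episode makes exactly 50 decisions", {
  env <- surrogate_env(n_input = 8)
  pol <- policy_new(n_input = 8, seed = 3)
  rec <- run_episode(pol, mu = 7.8e-2, seed = 99, env = env)
  expect_length(rec$action, 50L)
  expect_length(rec$eps, 50L)
  # reproducibility: same policy + same seed -> identical record
  rec2 <- run_episode(pol, mu = 7.8e-2, seed = 99, env = env)
  expect_identical(rec, rec2)
})

test_that("policies survive a serialization round trip", {
  pol <- policy_new(n_input = 20, seed = 8)
  path <- tempfile(fileext = ".json")
  write_policy(pol, path)
  back <- read_policy(path)
  expect_equal(back, pol)
  expect_error(read_policy(path, expect_input = 250), "mismatch")
})

test_that("a trained policy shows the accelerate-then-back-off crossover", {
  # surrogate training at fixed reference viscosity (shared across files);
  # the learned policy should prefer 'increase' at low strain and
  # 'decrease' beyond some threshold (the motif the reference model
  # develops near 6% strain)
  ts <- trained_surrogate()
  eps_grid <- seq(0, 0.12, by = 0.005)
  pr <- policy_forward(ts$fit$policy, eps_grid)
  d <- pr[, 3] - pr[, 1]           # decrease minus increase
  expect_lt(d[1], 0)               # accelerate at zero strain
  expect_gt(d[length(d)], 0)       # back off at high strain
  # a monotone crossover exists: one sign change on the grid
  expect_identical(sum(diff(sign(d)) != 0), 1L)
})
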