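test_that("episode viscosities are log-uniform over the stated range", {
  set.seed(17)
  mu <- sample_viscosity(1e4)
  expect_true(all(mu >= 7.8e-3 & mu <= 7.8e-1))
  # ~uniform counts per log bin (chi-square on 10 bins)
  counts <- table(cut(log(mu), breaks = seq(log(7.8e-3), log(7.8e-1),
                                            length.out = 11)))
  chi2 <- sum((counts - 1e3)^2 / 1e3)
  expect_lt(chi2, qchisq(0.999, df = 9))
  # determinism under a fixed seed
  set.seed(123); a <- sample_viscosity(5)
  set.seed(123); b <- sample_viscosity(5)
  expect_identical(a, b)
})

test_that("elite selection keeps the top of the batch, ties included", {
  mk <- function(rewards) lapply(rewards, function(r) list(reward = r))
  # rewards 1..10 at the 70th percentile -> {8, 9, 10}
  el <- select_elites(mk(1:10), 70)
  expect_setequal(vapply(el, `[[`, numeric(1), "reward"), c(8, 9, 10))
  # all equal -> everything is at the threshold
  expect_length(select_elites(mk(rep(2, 6)), 70), 6L)
  # failed episodes (-Inf sentinel) can never be elite
  el <- select_elites(mk(c(-Inf, 1, 2, -Inf, 3)), 70)
  expect_true(all(is.finite(vapply(el, `[[`, numeric(1), "reward"))))
  expect_error(select_elites(mk(1), 70), "at least 2")
  # property: matches a brute-force sort-and-threshold oracle
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    r <- rnorm(n)
    p <- sample(c(30, 50, 70, 90), 1)
    got <- sort(vapply(select_elites(mk(r), p), `[[`, numeric(1), "reward"))
    thr <- quantile(r, p / 100, type = 7, names = FALSE)
    expect_identical(got, sort(r[r >= thr]))
  }
})

test_that("the gradient pass moves probabilities toward elite actions", {
  pol <- policy_new(n_input = 8, seed = 2)
  eps_star <- 0.05
  p0 <- policy_forward(pol, eps_star)
  elite <- list(list(eps = rep(eps_star, 10), action = rep(1L, 10)))
  fit <- train_on_elites(pol, elite)
  expect_gt(policy_forward(fit$policy, eps_star)[1], p0[1])
  # loss decreases over repeated passes on a frozen elite set
  losses <- numeric(10)
  pol2 <- pol; opt <- adam_opt()
  for (i in 1:10) {
    fit <- train_on_elites(pol2, elite, opt)
    pol2 <- fit$policy; opt <- fit$opt
    losses[i] <- fit$loss
  }
  expect_true(all(diff(losses) < 0))
  # zero learning rate leaves the parameters untouched
  fit0 <- train_on_elites(pol, elite, adam_opt(lr = 0))
  expect_equal(fit0$policy, pol)
  expect_error(train_on_elites(pol, list()), "empty")
})

test_that("the surrogate environment has the advertised structure", {
  env <- surrogate_env(v_opt = 0.02, n_input = 16)
  # constant-speed rollouts: grid scan peaks at the known optimum
  grid <- seq(0.005, 0.05, by = 0.0025)
  rewards <- vapply(grid, function(v) {
    es <- env$reset(7.8e-2)
    for (i in 1:50) es <- env$advance(es, v, 0.1)
    env$reward(es, 5)
  }, numeric(1))
  expect_equal(grid[which.max(rewards)], 0.02, tolerance = 1e-12)
  # strain increases with viscosity at fixed wave speed
  strain_at <- function(mu) {
    es <- env$reset(mu)
    es <- env$advance(es, 0.03, 0.1)
    pool_strains(env$strains(es))
  }
  mus <- c(7.8e-3, 7.8e-2, 7.8e-1)
  expect_true(all(diff(vapply(mus, strain_at, numeric(1))) > 0))
  # inert (maintain-only) policy: wave never moves, reward ~ 0
  rec <- run_episode(inert_policy(16), 7.8e-2, seed = 1, env = env)
  expect_true(all(rec$v_wave == 0))
  expect_equal(rec$reward, 0, tolerance = 1e-12)
})

test_that("training bookkeeping and reproducibility hold", {
  env <- surrogate_env(n_input = 8)
  cfg <- training_config(episodes = 60, batch_size = 10, seed = 11)
  fit1 <- cem_train(cfg, env)
  fit2 <- cem_train(cfg, env)
  expect_identical(nrow(fit1$history), 6L)   # episodes / batch size
  expect_identical(fit1$history, fit2$history)
  expect_equal(fit1$policy, fit2$policy)
})

test_that("without training the reward history is statistically flat", {
  env <- surrogate_env(n_input = 8)
  cfg <- training_config(episodes = 300, batch_size = 10, seed = 19,
                         mu_range = c(7.8e-2, 7.8e-2))
  fit <- cem_train(cfg, env, train = FALSE)
  sl <- summary(lm(mean_reward ~ batch, data = fit$history))
  expect_gt(sl$coefficients["batch", "Pr(>|t|)"], 0.05)
})

test_that("CEM learns on the surrogate: improvement and optimum recovery", {
  # learning curve: the late batches of the first 20 beat the early ones,
  # for every tested seed
  env <- surrogate_env(v_opt = 0.01, n_input = 8)
  for (seed in 1:3) {
    cfg <- training_config(episodes = 200, batch_size = 10, seed = seed,
                           mu_range = c(7.8e-2, 7.8e-2), lr = 3e-3)
    fit <- cem_train(cfg, env)
    h <- fit$history$mean_reward
    expect_gt(mean(h[16:20]), mean(h[1:5]))
    # policy-improvement property: final greedy reward >= initial
    pol0 <- policy_new(n_input = 8, seed = cfg$seed)
    r0 <- run_episode(pol0, 7.8e-2, 1, env, mode = "greedy")$reward
    r1 <- run_episode(fit$policy, 7.8e-2, 1, env, mode = "greedy")$reward
    expect_gte(r1, r0)
  }
  # the long shared training run recovers the known optimum: the settled
  # greedy wave speed (after the start-from-rest ramp) is within 10%
  ts <- trained_surrogate()
  rec <- run_episode(ts$fit$policy, 7.8e-2, 1, ts$env, mode = "greedy")
  v_settled <- mean(rec$v_wave[26:50])
  expect_lt(abs(v_settled - ts$env$v_opt) / ts$env$v_opt, 0.10)
})
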