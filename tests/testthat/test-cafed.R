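pv_of <- function(...) flatten_params(list(w = c(...)))

test_that("pseudo-gradient is the pulled-minus-trained difference", {
  expect_equal(as.numeric(pseudo_gradient(pv_of(3, 1), pv_of(1, 2))), c(2, -1))
  w <- pv_of(rnorm(4))
  expect_equal(as.numeric(pseudo_gradient(w, w)), rep(0, 4))

  # one local full-gradient step at rate gamma on a quadratic:
  # g = gamma * grad F(w_back) exactly
  pb <- make_quadratic_problem(1, dim = 3, seed = 2)
  model <- make_quadratic_model(3)
  w0 <- pv_of(c(1, -2, 0.5))
  gamma <- 0.07
  w1 <- worker_local_round(model, w0, pb$shards[[1]], gamma)
  g <- pseudo_gradient(w0, w1)
  grad <- drop(pb$shards[[1]]$A %*% as.numeric(w0)) - pb$shards[[1]]$b
  expect_equal(as.numeric(g), gamma * grad, tolerance = 1e-12)
})

test_that("staleness counts intervening updates per entry", {
  w0 <- pv_of(0, 0, 0)
  cfg <- cafed_config(v = Inf, gamma = 0.1, theta = 0)
  srv <- server_init(w0, 2)
  srv <- pull(srv, 1)$server          # device 1 pulls at tau = 0
  srv <- pull(srv, 2)$server
  expect_equal(staleness(srv, 1), c(0, 0, 0))   # just pulled

  # three updates from device 2, all touching entries 1 and 3 only
  for (u in 1:3) {
    srv <- server_apply(srv, 2, pv_of(0.5, 0, -0.2), cfg)
    srv <- pull(srv, 2)$server
  }
  expect_equal(staleness(srv, 1), c(3, 0, 3))
  expect_equal(staleness(srv, 2), c(0, 0, 0))   # refreshed each time
  expect_equal(staleness(srv, 1, cap = 2), c(2, 0, 2))  # clamped at M

  # theta masks small-magnitude updates out of the history
  srv2 <- server_init(w0, 1, theta = 0.3)
  srv2 <- pull(srv2, 1)$server
  cfg2 <- cafed_config(v = Inf, gamma = 0.1, theta = 0.3)
  srv2 <- server_apply(srv2, 1, pv_of(0.5, 0.29, 0.31), cfg2)
  expect_equal(unname(srv2$counts), c(1, 0, 1))
})

test_that("incremental staleness equals brute-force recounts on random runs", {
  set.seed(123)
  for (rep in 1:12) {
    s <- tiny_logistic_setup(n_users = 45, n_devices = 3,
                             seed = 100 + rep, vocab_size = 25,
                             signal_tokens = 6)
    run <- cafed_run(s$model, s$shards, T = 20,
                     config = cafed_config(v = 0.8, gamma = 0.25),
                     seed = 200 + rep, eval_every = 0,
                     store_history = TRUE)
    srv <- run$server
    for (i in 1:3) {
      b <- srv$back[[i]]
      expect_equal(unname(staleness(srv, i)),
                   recount_staleness(srv$g_log, b$tau, srv$t,
                                     k_len = length(srv$w)))
    }
  }
})

test_that("adaptive weights are 1/s with the fresh-entry convention", {
  expect_equal(adaptive_weight(0), 1)
  expect_equal(adaptive_weight(1), 1)
  expect_equal(adaptive_weight(4), 0.25)
  expect_error(adaptive_weight(-1), "non-negative")
  s <- 0:50
  w <- adaptive_weight(s)
  expect_true(all(w > 0 & w <= 1))
  expect_true(all(diff(w) <= 0))   # non-increasing in s
})

test_that("the push gate transmits iff r < sigmoid(v)", {
  expect_true(should_push(0, r = 0.4))
  expect_false(should_push(0, r = 0.6))
  expect_true(should_push(20, r = 0.999999))    # saturated gate
  expect_false(should_push(-20, r = 1e-6))
  # moderate Monte-Carlo check (the full calibration runs in acceptance)
  st <- rng_stream(5)
  hits <- mean(vapply(1:20000, function(i) should_push(1, stream = st),
                      logical(1)))
  p <- stats::plogis(1)
  expect_lt(abs(hits - p), 3 * sqrt(p * (1 - p) / 20000))
})

test_that("server_apply reduces to w - g when noiseless and fresh", {
  w0 <- pv_of(1, 2, 3)
  cfg <- cafed_config(v = Inf, beta = 0, gamma = 0.1)
  srv <- server_init(w0, 1)
  srv <- pull(srv, 1)$server
  g <- pv_of(0.1, -0.2, 0)
  srv <- server_apply(srv, 1, g, cfg)
  expect_equal(as.numeric(srv$w), c(0.9, 2.2, 3))
  expect_equal(srv$t, 1)

  # null update: w unchanged but the epoch still advances
  srv <- pull(srv, 1)$server
  srv <- server_apply(srv, 1, pv_of(0, 0, 0), cfg)
  expect_equal(as.numeric(srv$w), c(0.9, 2.2, 3))
  expect_equal(srv$t, 2)
  expect_error(server_apply(srv, 1, pv_of(1, 1), cfg), "conformable")
})

test_that("injected noise has the prescribed per-entry moments", {
  # moderate version of the calibration (full size in acceptance):
  # frozen server state, repeated applications, deltas ~ wgt*(g + beta*N)
  w0 <- pv_of(0, 0, 0, 0)
  cfg <- cafed_config(v = Inf, beta = 0.05, sigma = 1, gamma = 0.1)
  base <- server_init(w0, 1)
  base <- pull(base, 1)$server
  g <- pv_of(0.3, -0.1, 0, 0.2)
  ns <- rng_stream(11)
  n_trials <- 3000
  deltas <- matrix(0, n_trials, 4)
  for (i in seq_len(n_trials)) {
    srv <- server_apply(base, 1, g, cfg, noise_stream = ns)
    deltas[i, ] <- as.numeric(base$w) - as.numeric(srv$w)
  }
  wgt <- adaptive_weight(staleness(base, 1))     # all fresh -> 1
  se_mean <- wgt * cfg$beta * cfg$sigma / sqrt(n_trials)
  expect_true(all(abs(colMeans(deltas) - wgt * as.numeric(g)) < 4 * se_mean))
  v_emp <- apply(deltas, 2, stats::var)
  v_th <- wgt^2 * cfg$beta^2 * cfg$sigma^2
  se <- v_th * sqrt(2 / (n_trials - 1))
  expect_true(all(abs(v_emp - v_th) < 3.5 * se))
})

test_that("noiseless trajectories are recovered in expectation", {
  # averaging noisy applied deltas converges to the clean damped delta
  w0 <- pv_of(1, -1)
  cfg <- cafed_config(v = Inf, beta = 0.1, sigma = 1, gamma = 0.1)
  base <- server_init(w0, 1)
  base <- pull(base, 1)$server
  g <- pv_of(0.4, 0.4)
  ns <- rng_stream(21)
  acc <- c(0, 0)
  n_trials <- 5000
  for (i in seq_len(n_trials)) {
    srv <- server_apply(base, 1, g, cfg, noise_stream = ns)
    acc <- acc + (as.numeric(base$w) - as.numeric(srv$w))
  }
  expect_true(all(abs(acc / n_trials - c(0.4, 0.4)) <
                    4 * 0.1 / sqrt(n_trials)))
})

test_that("degenerate asynchronous training equals sequential SGD", {
  # n=1 worker, open gate, no noise, one local step per round: every
  # staleness is 0, g = gamma * minibatch gradient, so the global
  # trajectory is plain SGD on the same shard with the same seed
  s <- tiny_logistic_setup(n_users = 80, n_devices = 1, l2 = 1e-4)
  run <- cafed_run(s$model, s$shards, T = 60,
                   config = cafed_config(v = Inf, beta = 0, gamma = 0.3),
                   seed = 12, local_steps = 1, eval_every = 0)
  ref <- central_sgd(s$model, s$shards[[1]], gamma = 0.3, steps = 60,
                     batch_size = 16, seed = 12)
  expect_lt(max(abs(as.numeric(run$w) - as.numeric(ref$w))), 1e-6)
})
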