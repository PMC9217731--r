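# Discrete-event simulation of an asynchronous federated run.
#
# Virtual time: each worker's local round takes a seeded random duration
# (log-normal by default; heterogeneous compute is the point of the
# asynchrony). The server processes push attempts strictly in
# (arrival time, device id) order and applies at most one global update
# per simulation instant. A dropped push (the gate fails) discards the
# round: the worker re-pulls the current global model and starts over,
# which also keeps its staleness bounded.
#
# Every random draw comes from a dedicated stream derived from the master
# seed (per-worker minibatches, per-worker delays, the gate, the noise),
# so the whole run log is a pure function of (configuration, seed).

schedule_rate <- function(gamma, t, schedule = "constant", t0 = 10) {
  switch(schedule,
         constant = gamma,
         diminishing = gamma * t0 / (t + t0),
         abort(sprintf("unknown lr schedule '%s'", schedule)))
}

#' Run asynchronous federated training (CAFed)
#'
#' Simulates `n` workers training a shared model under the asynchronous
#' staleness-aware update rule until exactly `T` global updates have been
#' applied.
#'
#' @param model A model object.
#' @param shards List of per-device datasets.
#' @param test_data Optional held-out dataset for accuracy evaluation.
#' @param T Number of global epochs (applied updates; default 100).
#' @param config A [cafed_config()]; a `NULL` `stale_cap` becomes
#'   `10 * length(shards)`.
#' @param seed Master seed; the run log is a pure function of it and the
#'   configuration.
#' @param batch_size Local minibatch size (default 16).
#' @param local_steps Local SGD steps per round; `NULL` = one pass over
#'   the shard.
#' @param eval_every Evaluate on `test_data` every this many global
#'   epochs (0 = never).
#' @param delay_meanlog,delay_sdlog Log-normal compute-delay parameters.
#' @param delay_fn Optional deterministic delay override: a function
#'   `(device, round_index) -> duration`, replacing the random delays
#'   (used for scripted schedules).
#' @param lr_schedule `"constant"` (algorithm default) or `"diminishing"`
#'   (`gamma * t0 / (t + t0)`, for convex convergence runs).
#' @param lr_t0 Offset of the diminishing schedule.
#' @param store_history Keep all applied pseudo-gradients on the server
#'   (for staleness recounts).
#' @param threshold Classification threshold for evaluation.
#' @param eval_fn Optional custom evaluator `function(w)` returning a list
#'   with `accuracy` and/or `loss`; overrides the classifier evaluation
#'   (used e.g. to track a quadratic objective along the run).
#' @param max_consecutive_drops Stall guard: abort if this many push
#'   attempts in a row are dropped before an update lands.
#' @return A `fed_run` object: final model `w`, the event log (`events`),
#'   per-epoch `metrics`, the final `server` state, and bookkeeping.
#' @export
cafed_run <- function(model, shards, test_data = NULL, T = 100,
                      config = cafed_config(), seed = 1L,
                      batch_size = 16L, local_steps = NULL,
                      eval_every = 1L,
                      delay_meanlog = 0, delay_sdlog = 0.5,
                      delay_fn = NULL,
                      lr_schedule = "constant", lr_t0 = 10,
                      store_history = FALSE, threshold = 0.5,
                      eval_fn = NULL,
                      max_consecutive_drops = 10000L) {
  stopifnot(inherits(config, "cafed_config"), T >= 1, length(shards) >= 1)
  n <- length(shards)
  if (is.null(config$stale_cap)) config$stale_cap <- 10L * n

  data_streams <- lapply(seq_len(n), function(i) rng_stream(derive_seed(seed, 101L, i)))
  delay_streams <- lapply(seq_len(n), function(i) rng_stream(derive_seed(seed, 202L, i)))
  gate_stream <- rng_stream(derive_seed(seed, 303L))
  noise_stream <- rng_stream(derive_seed(seed, 404L))

  w0 <- model_init(model, derive_seed(seed, 505L))
  server <- server_init(w0, n, theta = config$theta, store_history = store_history)

  ev_time <- numeric(0); ev_kind <- character(0)
  ev_dev <- integer(0); ev_epoch <- integer(0)
  log_event <- function(time, kind, device, epoch) {
    ev_time <<- c(ev_time, time); ev_kind <<- c(ev_kind, kind)
    ev_dev <<- c(ev_dev, device); ev_epoch <<- c(ev_epoch, epoch)
  }

  metrics <- list()
  uploads <- 0L; downloads <- 0L; drops <- 0L
  record_metrics <- function(epoch, sim_time) {
    row <- tibble::tibble(epoch = epoch, sim_time = sim_time,
                          accuracy = NA_real_, loss = NA_real_,
                          uploads = uploads, downloads = downloads,
                          drops = drops)
    if (!is.null(eval_fn)) {
      ev <- eval_fn(server$w)
      if (!is.null(ev$accuracy)) row$accuracy <- ev$accuracy
      if (!is.null(ev$loss)) row$loss <- ev$loss
    } else if (!is.null(test_data)) {
      ev <- evaluate_model(model, server$w, test_data, threshold)
      row$accuracy <- ev$accuracy; row$loss <- ev$loss
    }
    metrics[[length(metrics) + 1L]] <<- row
    log_event(sim_time, "eval", NA_integer_, epoch)
  }

  next_delay <- function(i, round) {
    if (!is.null(delay_fn)) delay_fn(i, round)
    else draw_with(delay_streams[[i]], stats::rlnorm(1, delay_meanlog, delay_sdlog))
  }

  workers <- vector("list", n)
  arrival <- numeric(n)
  rounds <- integer(n)
  for (i in seq_len(n)) {
    res <- pull(server, i)
    server <- res$server
    workers[[i]] <- list(snapshot = res$snapshot,
                         gamma = schedule_rate(config$gamma, res$tau,
                                               lr_schedule, lr_t0))
    downloads <- downloads + 1L
    log_event(0, "pull", i, res$tau)
    rounds[i] <- 1L
    arrival[i] <- next_delay(i, rounds[i])
  }
  if (eval_every > 0) record_metrics(0L, 0)

  consecutive_drops <- 0L
  while (server$t < T) {
    i <- which.min(arrival)            # ties: lowest device id wins
    now <- arrival[i]
    w_new <- worker_local_round(model, workers[[i]]$snapshot, shards[[i]],
                                workers[[i]]$gamma, batch_size,
                                steps = local_steps,
                                stream = data_streams[[i]])
    log_event(now, "push_attempt", i, server$t)
    if (should_push(config$v, stream = gate_stream)) {
      g <- pseudo_gradient(server$back[[i]]$w, w_new)
      server <- server_apply(server, i, g, config, noise_stream)
      uploads <- uploads + 1L
      consecutive_drops <- 0L
      log_event(now, "global_update", i, server$t - 1L)
      if (eval_every > 0 &&
          (server$t %% eval_every == 0 || server$t == T)) {
        record_metrics(server$t, now)
      }
    } else {
      drops <- drops + 1L
      consecutive_drops <- consecutive_drops + 1L
      log_event(now, "drop", i, server$t)
      if (consecutive_drops >= max_consecutive_drops) {
        abort("stalled: no surviving push within the drop guard")
      }
    }
    # start the next local round from the current global model
    res <- pull(server, i)
    server <- res$server
    workers[[i]]$snapshot <- res$snapshot
    workers[[i]]$gamma <- schedule_rate(config$gamma, res$tau, lr_schedule, lr_t0)
    downloads <- downloads + 1L
    log_event(now, "pull", i, res$tau)
    rounds[i] <- rounds[i] + 1L
    arrival[i] <- now + next_delay(i, rounds[i])
  }

  structure(list(
    algo = "cafed",
    w = server$w,
    model = model,
    config = config,
    seed = seed,
    n_devices = n,
    T = T,
    events = tibble::tibble(sim_time = ev_time, kind = ev_kind,
                            device = ev_dev, epoch = ev_epoch),
    metrics = if (length(metrics)) dplyr::bind_rows(metrics) else
      tibble::tibble(epoch = integer(), sim_time = numeric(),
                     accuracy = numeric(), loss = numeric(),
                     uploads = integer(), downloads = integer(),
                     drops = integer()),
    uploads = uploads, downloads = downloads, drops = drops,
    server = server
  ), class = "fed_run")
}
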