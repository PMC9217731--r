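# Synchronous Federated Averaging baseline.
#
# Each round, a seeded random subset of workers trains locally from the
# current global model and the server replaces the model by the
# shard-size-weighted average of the returned models. One round costs m
# uploads and m downloads (m = participants), against one upload per
# accepted push for the asynchronous trainer; both runs expose the same
# communication counters so the comparison can be re-created as a plot.

#' Shard-size-weighted model average
#'
#' @param w_list List of conformable `param_vector`s.
#' @param sizes Shard sizes (aggregation weight of model i is
#'   `sizes[i] / sum(sizes)`; weights sum to 1).
#' @return The aggregated `param_vector`.
#' @export
fedavg_aggregate <- function(w_list, sizes) {
  stopifnot(length(w_list) >= 1, length(sizes) == length(w_list),
            all(sizes > 0))
  for (w in w_list[-1]) check_conformable(w_list[[1]], w)
  wts <- sizes / sum(sizes)
  acc <- numeric(length(w_list[[1]]))
  for (i in seq_along(w_list)) acc <- acc + wts[i] * as.numeric(w_list[[i]])
  new_param_vector(acc, attr(w_list[[1]], "keys"))
}

#' One FedAvg round
#'
#' @param model A model object.
#' @param w Current global model.
#' @param shards List of per-device datasets.
#' @param participants Device ids training this round.
#' @param gamma Learning rate.
#' @param local_epochs Local passes over each shard.
#' @param batch_size Minibatch size.
#' @param data_streams Per-device [rng_stream()]s for minibatch sampling.
#' @return List with the new global model `w` and the participant shard
#'   `sizes`.
#' @export
fedavg_round <- function(model, w, shards, participants, gamma,
                         local_epochs = 1L, batch_size = 16L,
                         data_streams = NULL) {
  if (length(participants) == 0) abort("empty participant set")
  w_list <- vector("list", length(participants))
  sizes <- numeric(length(participants))
  for (j in seq_along(participants)) {
    i <- participants[j]
    steps <- local_epochs * max(1L, ceiling(n_obs(shards[[i]]) / batch_size))
    w_list[[j]] <- worker_local_round(
      model, w, shards[[i]], gamma, batch_size, steps = steps,
      stream = if (is.null(data_streams)) NULL else data_streams[[i]])
    sizes[j] <- n_obs(shards[[i]])
  }
  list(w = fedavg_aggregate(w_list, sizes), sizes = sizes)
}

#' Run synchronous federated averaging
#'
#' @inheritParams cafed_run
#' @param T Number of global rounds (default 200).
#' @param fraction Fraction of devices sampled per round (default 1:
#'   all devices participate).
#' @param local_epochs Local passes per round.
#' @param gamma Learning rate.
#' @return A `fed_run` object (same shape as [cafed_run()]'s).
#' @export
fedavg_run <- function(model, shards, test_data = NULL, T = 200,
                       fraction = 1, local_epochs = 1L, batch_size = 16L,
                       gamma = 0.1, eval_every = 1L, seed = 1L,
                       threshold = 0.5) {
  stopifnot(fraction > 0, fraction <= 1, T >= 1)
  n <- length(shards)
  m <- max(1L, ceiling(fraction * n))
  data_streams <- lapply(seq_len(n), function(i) rng_stream(derive_seed(seed, 101L, i)))
  select_stream <- rng_stream(derive_seed(seed, 303L))
  w <- model_init(model, derive_seed(seed, 505L))

  ev_time <- numeric(0); ev_kind <- character(0)
  ev_dev <- integer(0); ev_epoch <- integer(0)
  log_event <- function(time, kind, device, epoch) {
    ev_time <<- c(ev_time, time); ev_kind <<- c(ev_kind, kind)
    ev_dev <<- c(ev_dev, device); ev_epoch <<- c(ev_epoch, epoch)
  }

  uploads <- 0L; downloads <- 0L
  metrics <- list()
  record_metrics <- function(epoch, sim_time) {
    row <- tibble::tibble(epoch = epoch, sim_time = sim_time,
                          accuracy = NA_real_, loss = NA_real_,
                          uploads = uploads, downloads = downloads,
                          drops = 0L)
    if (!is.null(test_data)) {
      ev <- evaluate_model(model, w, test_data, threshold)
      row$accuracy <- ev$accuracy; row$loss <- ev$loss
    }
    metrics[[length(metrics) + 1L]] <<- row
    log_event(sim_time, "eval", NA_integer_, epoch)
  }
  if (eval_every > 0) record_metrics(0L, 0)

  for (r in seq_len(T)) {
    participants <- sort(draw_with(select_stream, sample.int(n, m)))
    for (i in participants) log_event(r, "pull", i, r - 1L)
    downloads <- downloads + m
    res <- fedavg_round(model, w, shards, participants, gamma,
                        local_epochs, batch_size, data_streams)
    w <- res$w
    for (i in participants) log_event(r, "push_attempt", i, r - 1L)
    uploads <- uploads + m
    log_event(r, "global_update", NA_integer_, r - 1L)
    if (eval_every > 0 && (r %% eval_every == 0 || r == T)) {
      record_metrics(r, r)
    }
  }

  structure(list(
    algo = "fedavg",
    w = w,
    model = model,
    config = list(fraction = fraction, local_epochs = local_epochs,
                  batch_size = batch_size, gamma = gamma),
    seed = seed,
    n_devices = n,
    T = T,
    events = tibble::tibble(sim_time = ev_time, kind = ev_kind,
                            device = ev_dev, epoch = ev_epoch),
    metrics = dplyr::bind_rows(metrics),
    uploads = uploads, downloads = downloads, drops = 0L,
    server = NULL
  ), class = "fed_run")
}
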