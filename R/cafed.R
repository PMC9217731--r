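# Asynchronous update rule with per-parameter staleness weighting.
#
# The server never sees gradients. A worker pulls the global model w_t
# (the server keeps the pulled snapshot in its w_back store, with the pull
# timestamp tau), trains locally, and pushes its new model. The server
# reconstructs a pseudo-gradient g = w_back - w_new, damps each entry k by
# an adaptive weight 1/s_k (s_k = how many applied global updates touched
# entry k since this worker's pull; weight 1 when s_k = 0), optionally
# adds Gaussian noise beta * N(0, sigma^2) per entry for privacy, and
# applies w[k] <- w[k] - weight_k * (g[k] + noise_k) as one global epoch.
# Uploads are thinned by a Bernoulli push gate with acceptance probability
# sigmoid(v).

#' CAFed hyper-parameters
#'
#' @param v Push-gate hyper-parameter; a push attempt survives with
#'   probability `plogis(v)` (sigmoid). `Inf` accepts everything.
#' @param beta Noise magnitude coefficient (>= 0); 0 disables the
#'   randomized privacy mechanism.
#' @param sigma Noise scale; the injected noise is `beta * N(0, sigma^2)`
#'   per entry (default 1).
#' @param theta Zero tolerance: a global update counts toward entry k's
#'   staleness only if `|g[k]| > theta` (default 0).
#' @param stale_cap Cap M on effective staleness; `NULL` means 10 * n
#'   devices, set when a run starts.
#' @param gamma Local SGD learning rate.
#' @return A `cafed_config` list.
#' @export
cafed_config <- function(v = 2, beta = 0, sigma = 1, theta = 0,
                         stale_cap = NULL, gamma = 0.1) {
  stopifnot(beta >= 0, sigma >= 0, theta >= 0, gamma > 0,
            is.null(stale_cap) || stale_cap >= 1)
  structure(list(v = v, beta = beta, sigma = sigma, theta = theta,
                 stale_cap = stale_cap, gamma = gamma),
            class = "cafed_config")
}

#' Initialize the server state
#'
#' @param w0 Initial global model (`param_vector`).
#' @param n_devices Number of devices.
#' @param theta Zero tolerance for the staleness history counts.
#' @param store_history Keep the full list of applied pseudo-gradients
#'   (used by brute-force staleness recounts; memory scales with T).
#' @return A `fed_server` list: global model `w`, epoch counter `t`,
#'   per-entry cumulative update counts `counts`, the per-device `back`
#'   store (pulled snapshot, pull timestamp, counts at pull), and
#'   optionally `g_log`.
#' @export
server_init <- function(w0, n_devices, theta = 0, store_history = FALSE) {
  structure(list(
    w = w0,
    t = 0L,
    theta = theta,
    counts = numeric(length(w0)),
    back = vector("list", n_devices),
    g_log = if (store_history) list() else NULL
  ), class = "fed_server")
}

#' Pull the global model for a device
#'
#' The server snapshots (w_t, t, current history counts) into its back
#' store for the device; the device trains from that snapshot.
#'
#' @param server A `fed_server`.
#' @param i Device id.
#' @return List with the updated `server`, the model `snapshot`, and the
#'   pull timestamp `tau`.
#' @export
pull <- function(server, i) {
  server$back[[i]] <- list(w = server$w, tau = server$t, counts = server$counts)
  list(server = server, snapshot = server$w, tau = server$t)
}

#' Pseudo-gradient of a device's local round
#'
#' @param w_back The snapshot the device pulled.
#' @param w_new The device's locally trained model.
#' @return `param_vector` g = w_back - w_new.
#' @export
pseudo_gradient <- function(w_back, w_new) {
  check_conformable(w_back, w_new)
  new_param_vector(as.numeric(w_back) - as.numeric(w_new), attr(w_back, "keys"))
}

#' Per-entry staleness from history counts
#'
#' Entry k's staleness is the number of global updates u in [tau, t-1]
#' with |g_u[k]| > theta, computed incrementally as the difference of
#' cumulative counts, then clamped at the cap M.
#'
#' @param counts_now Cumulative per-entry counts at server time t.
#' @param counts_at_pull Cumulative counts snapshotted at the pull.
#' @param cap Staleness cap M (default `Inf`).
#' @return Integer-valued numeric vector of per-entry staleness.
#' @export
staleness_from_counts <- function(counts_now, counts_at_pull, cap = Inf) {
  s <- counts_now - counts_at_pull
  if (any(s < 0)) abort("staleness counts decreased; tau > t?")
  pmin(s, cap)
}

#' Per-entry staleness of a device's pending push
#'
#' @param server A `fed_server`.
#' @param i Device id (must have pulled).
#' @param cap Staleness cap M.
#' @return Per-entry staleness vector for device `i` at the current t.
#' @export
staleness <- function(server, i, cap = Inf) {
  b <- server$back[[i]]
  if (is.null(b)) abort(sprintf("device %d has not pulled", i))
  staleness_from_counts(server$counts, b$counts, cap)
}

#' Adaptive per-entry weight
#'
#' 1/s for stale entries, 1 for fresh ones (s = 0). Lies in (0, 1] and is
#' non-increasing in s.
#'
#' @param s Non-negative staleness (vectorized).
#' @return Numeric vector of weights.
#' @export
adaptive_weight <- function(s) {
  if (any(s < 0)) abort("staleness must be non-negative")
  ifelse(s == 0, 1, 1 / s)
}

#' Push gate
#'
#' A device about to push draws r ~ U(0, 1) and transmits iff
#' r < sigmoid(v); otherwise the round's result is dropped.
#'
#' @param v Gate hyper-parameter.
#' @param r The uniform draw; if `NULL`, drawn from `stream` (or the
#'   session RNG).
#' @param stream Optional [rng_stream()] supplying the draw.
#' @return Logical: transmit?
#' @export
should_push <- function(v, r = NULL, stream = NULL) {
  if (is.null(r)) {
    r <- if (is.null(stream)) runif(1) else draw_with(stream, runif(1))
  }
  r < stats::plogis(v)
}

#' Apply an accepted push to the global model
#'
#' Computes the pusher's per-entry staleness and adaptive weights, injects
#' `beta * N(0, sigma^2)` noise per entry into the pseudo-gradient, applies
#' the damped update, increments the epoch counter, updates the staleness
#' history using the clean (noise-free) pseudo-gradient, and refreshes the
#' pusher's back-store snapshot to the new model.
#'
#' @param server A `fed_server`.
#' @param i Pushing device id.
#' @param g Pseudo-gradient (`param_vector`) from [pseudo_gradient()].
#' @param cfg A [cafed_config()].
#' @param noise_stream Optional [rng_stream()] for the privacy noise.
#' @return The updated `fed_server`.
#' @export
server_apply <- function(server, i, g, cfg, noise_stream = NULL) {
  check_conformable(server$w, g)
  if (cfg$beta < 0) abort("beta must be >= 0")
  cap <- if (is.null(cfg$stale_cap)) Inf else cfg$stale_cap
  s <- staleness(server, i, cap = cap)
  wgt <- adaptive_weight(s)
  gk <- as.numeric(g)
  noisy <- gk
  if (cfg$beta > 0) {
    eps <- if (is.null(noise_stream)) rnorm(length(gk), 0, cfg$sigma)
           else draw_with(noise_stream, rnorm(length(gk), 0, cfg$sigma))
    noisy <- gk + cfg$beta * eps
  }
  server$w <- axpy(server$w, new_param_vector(noisy, attr(g, "keys")), wgt)
  server$t <- server$t + 1L
  server$counts <- server$counts + (abs(gk) > cfg$theta)
  if (!is.null(server$g_log)) server$g_log[[length(server$g_log) + 1L]] <- gk
  # the pusher's state is now the fresh model, as if it re-pulled
  server$back[[i]] <- list(w = server$w, tau = server$t, counts = server$counts)
  server
}
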