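# Model interface shared by the trainers.
#
# A model object bundles four pure functions over a flat param_vector:
# seeded initialization, loss, (mini-batch) gradient, and prediction.
# Three concrete models exist: the text CNN (textcnn.R), a logistic
# classifier (the analytically tractable convex stand-in used heavily by
# the test suite), and a quadratic objective for convex convergence runs.
#
# A dataset is a plain list. Supervised models use `x`/`ids` plus `y`
# (0/1); the quadratic model's "shard" is its own objective piece
# (A, b): F_i(w) = 0.5 w'Aw - b'w.

model_init <- function(model, seed) model$init(seed)
model_loss <- function(model, pv, data) model$loss(pv, data)
model_grad <- function(model, pv, data, idx = NULL, stream = NULL) {
  model$grad(pv, data, idx, stream)
}
model_predict <- function(model, pv, data) model$predict(pv, data)

n_obs <- function(data) if (!is.null(data$y)) length(data$y) else 1L

# log(1 + exp(z)) without overflow
log1pexp <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

#' Logistic classifier over a fixed feature matrix
#'
#' Binary cross-entropy plus an l2 penalty on the weight vector (not the
#' intercept). Convex, so trajectories and optima are analytically
#' checkable; used as the tractable stand-in model in federated runs.
#'
#' @param n_features Number of input features.
#' @param l2 l2 penalty coefficient.
#' @return A model object.
#' @export
make_logistic_model <- function(n_features, l2 = 0) {
  stopifnot(n_features > 0, l2 >= 0)
  logits <- function(pv, x) {
    p <- unflatten_params(pv)
    drop(x %*% p$w) + p$b
  }
  model <- list(
    kind = "logistic",
    n_features = n_features,
    l2 = l2,
    init = function(seed) {
      flatten_params(list(w = rep(0, n_features), b = 0))
    },
    loss = function(pv, data) {
      z <- logits(pv, data$x)
      w <- unflatten_params(pv)$w
      mean(log1pexp(z) - data$y * z) + l2 * sum(w^2)
    },
    grad = function(pv, data, idx = NULL, stream = NULL) {
      if (is.null(idx)) idx <- seq_along(data$y)
      x <- data$x[idx, , drop = FALSE]
      y <- data$y[idx]
      r <- stats::plogis(logits(pv, x)) - y
      w <- unflatten_params(pv)$w
      flatten_params(list(
        w = drop(crossprod(x, r)) / length(idx) + 2 * l2 * w,
        b = mean(r)
      ))
    },
    predict = function(pv, data) {
      stats::plogis(logits(pv, data$x))
    }
  )
  class(model) <- c("logistic_model", "fed_model")
  model
}

#' Quadratic objective split across workers
#'
#' Worker i's shard is a piece (A_i, b_i) of a strongly convex quadratic;
#' the global objective is the average of the pieces. Gradients are exact,
#' making this the reference problem for convergence properties.
#'
#' @param dim Parameter dimension.
#' @return A model object.
#' @export
make_quadratic_model <- function(dim) {
  model <- list(
    kind = "quadratic",
    dim = dim,
    init = function(seed) flatten_params(list(w = rep(0, dim))),
    loss = function(pv, data) {
      w <- as.numeric(pv)
      0.5 * drop(w %*% data$A %*% w) - drop(data$b %*% w)
    },
    grad = function(pv, data, idx = NULL, stream = NULL) {
      w <- as.numeric(pv)
      new_param_vector(drop(data$A %*% w) - data$b, attr(pv, "keys"))
    },
    predict = function(pv, data) NULL
  )
  class(model) <- c("quadratic_model", "fed_model")
  model
}

#' Build random quadratic shards with a known global optimum
#'
#' Each worker i gets F_i(w) = 0.5 (w - c_i)' A_i (w - c_i) with a seeded
#' SPD matrix A_i and local center c_i; the global objective is the
#' average, minimized at w* = (sum A_i)^-1 sum A_i c_i.
#'
#' @param n_workers Number of shards.
#' @param dim Dimension.
#' @param center_spread Standard deviation of the local centers.
#' @param seed Integer seed.
#' @return List with `shards`, `w_star`, `f_star`, and `objective` (a
#'   function of a param_vector giving the global loss).
#' @export
make_quadratic_problem <- function(n_workers, dim = 2, center_spread = 0.5,
                                   seed = 1L) {
  stream <- rng_stream(derive_seed(seed, 606L))
  shards <- lapply(seq_len(n_workers), function(i) {
    m <- draw_with(stream, matrix(rnorm(dim * dim, sd = 0.3), dim, dim))
    a <- crossprod(m) + diag(dim)            # SPD, eigenvalues >= 1
    ci <- draw_with(stream, rnorm(dim, sd = center_spread))
    list(A = a, b = drop(a %*% ci), center = ci)
  })
  a_sum <- Reduce(`+`, lapply(shards, `[[`, "A"))
  b_sum <- Reduce(`+`, lapply(shards, `[[`, "b"))
  w_star <- drop(solve(a_sum, b_sum))
  objective <- function(pv) {
    w <- as.numeric(pv)
    mean(vapply(shards, function(s)
      0.5 * drop(w %*% s$A %*% w) - drop(s$b %*% w), numeric(1)))
  }
  f_star <- objective(new_param_vector(w_star, list(list(name = "w", dim = length(w_star)))))
  list(shards = shards, w_star = w_star, f_star = f_star, objective = objective)
}

# One local training round: `steps` minibatch SGD steps at rate gamma,
# minibatch indices drawn from the worker's own RNG stream. For datasets
# without observations (quadratic shards) each step uses the exact local
# gradient. Default steps = one pass over the shard.
worker_local_round <- function(model, pv, data, gamma, batch_size = 16L,
                               steps = NULL, stream = NULL) {
  n <- n_obs(data)
  if (is.null(steps)) {
    steps <- if (is.null(data$y)) 1L else max(1L, ceiling(n / batch_size))
  }
  for (s in seq_len(steps)) {
    idx <- NULL
    if (!is.null(data$y)) {
      take <- min(batch_size, n)
      idx <- if (is.null(stream)) sample.int(n, take)
             else draw_with(stream, sample.int(n, take))
    }
    g <- model_grad(model, pv, data, idx, stream)
    pv <- axpy(pv, g, gamma)
  }
  pv
}

#' Centralized minibatch SGD
#'
#' The non-federated reference trainer: plain SGD on one dataset, seeded
#' identically to a single federated worker so that degenerate federated
#' configurations can be compared against it step for step.
#'
#' @param model A model object.
#' @param data Training dataset.
#' @param gamma Learning rate.
#' @param steps Total SGD steps.
#' @param batch_size Minibatch size (default 32 for centralized runs).
#' @param seed Master seed.
#' @param record_every Record the parameter vector every this many steps
#'   (0 = only final).
#' @return List with `w` (final `param_vector`) and `trajectory` (list of
#'   recorded param_vectors, if requested).
#' @export
central_sgd <- function(model, data, gamma, steps, batch_size = 32L,
                        seed = 1L, record_every = 0L) {
  stream <- rng_stream(derive_seed(seed, 101L, 1L))
  pv <- model_init(model, derive_seed(seed, 505L))
  traj <- list()
  for (s in seq_len(steps)) {
    pv <- worker_local_round(model, pv, data, gamma, batch_size,
                             steps = 1L, stream = stream)
    if (record_every > 0 && s %% record_every == 0) {
      traj[[length(traj) + 1L]] <- pv
    }
  }
  list(w = pv, trajectory = traj)
}

#' Evaluate a classifier on a dataset
#'
#' @param model A model object.
#' @param pv Parameters.
#' @param data Dataset with labels.
#' @param threshold Decision threshold; predicted label is 1 iff
#'   probability >= threshold.
#' @return One-row tibble with `accuracy` and `loss`.
#' @export
evaluate_model <- function(model, pv, data, threshold = 0.5) {
  p <- model_predict(model, pv, data)
  tibble::tibble(
    accuracy = mean((p >= threshold) == (data$y == 1)),
    loss = model_loss(model, pv, data)
  )
}
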