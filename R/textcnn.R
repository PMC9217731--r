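# Text CNN for sentence-level binary classification.
#
# Architecture: embedding lookup -> 1-D convolutions with ReLU, one bank
# per filter size -> max-over-time pooling per feature map -> concatenation
# -> (inverted) dropout -> fully connected layer -> single sigmoid output.
# The forward and backward passes are written directly in matrix algebra so
# the whole parameter set lives in a flat param_vector and federates like
# any other model. Gradients are exact (verified against finite differences
# in the test suite).
#
# Embedding modes: "rand" and "nostatic" keep the embedding matrix inside
# the trainable param_vector; "static" freezes it outside the vector, so
# federated updates never touch it. The padding row (id 0) is pinned to
# zero in every mode.

#' Text-CNN configuration
#'
#' @param d Embedding dimension.
#' @param filter_sizes Integer vector of convolution window lengths
#'   (defaults 3, 4, 5).
#' @param n_filters Feature maps per filter size (default 128).
#' @param dropout Dropout rate on the pooled feature vector, in [0, 1)
#'   (default 0.5).
#' @param l2 l2 coefficient applied to all non-embedding trainables.
#' @param L Input sequence length.
#' @param mode Embedding mode: `"rand"`, `"static"`, or `"nostatic"`.
#' @return A `textcnn_config` list.
#' @export
textcnn_config <- function(d, L, filter_sizes = c(3L, 4L, 5L),
                           n_filters = 128L, dropout = 0.5, l2 = 0,
                           mode = c("rand", "static", "nostatic")) {
  mode <- match.arg(mode)
  stopifnot(d > 0, L > 0, length(filter_sizes) > 0, n_filters > 0,
            dropout >= 0, dropout < 1, l2 >= 0)
  if (any(filter_sizes > L)) {
    abort("filter size exceeds sequence length L")
  }
  structure(list(d = d, L = L, filter_sizes = as.integer(filter_sizes),
                 n_filters = as.integer(n_filters), dropout = dropout,
                 l2 = l2, mode = mode),
            class = "textcnn_config")
}

glorot_uniform <- function(nr, nc, stream) {
  lim <- sqrt(6 / (nr + nc))
  draw_with(stream, matrix(runif(nr * nc, -lim, lim), nr, nc))
}

#' Build a text-CNN model
#'
#' @param cfg A [textcnn_config()].
#' @param vocab Vocabulary tibble ([build_vocabulary()]).
#' @param table Optional `embedding_table` (required for static/nostatic
#'   modes).
#' @return A model object; `model$init(seed)` is a pure function of the
#'   seed. Datasets for this model are lists with `ids` (n x L integer
#'   matrix of vocabulary ids, 0 = pad) and `y` (0/1).
#' @export
build_textcnn <- function(cfg, vocab, table = NULL) {
  stopifnot(inherits(cfg, "textcnn_config"))
  sizes <- cfg$filter_sizes
  nf <- cfg$n_filters
  n_pooled <- nf * length(sizes)
  env <- new.env(parent = emptyenv())   # holds frozen embedding in static mode
  env$emb <- NULL

  trainable_names <- c(
    if (cfg$mode != "static") "emb",
    as.vector(rbind(paste0("convW", sizes), paste0("convb", sizes))),
    "denseW", "denseb"
  )

  get_emb <- function(p) if (cfg$mode == "static") env$emb else p$emb

  forward <- function(p, ids, mask = NULL) {
    emb <- get_emb(p)
    b <- nrow(ids)
    pooled <- matrix(0, b, n_pooled)
    cache <- list()
    for (si in seq_along(sizes)) {
      h <- sizes[si]
      n_pos <- cfg$L - h + 1L
      w <- p[[paste0("convW", h)]]
      bias <- p[[paste0("convb", h)]]
      zs <- vector("list", b)
      arg <- matrix(0L, b, nf)
      for (i in seq_len(b)) {
        e <- emb[ids[i, ] + 1L, , drop = FALSE]
        z <- matrix(0, n_pos, h * cfg$d)
        for (j in seq_len(h)) {
          z[, ((j - 1L) * cfg$d + 1L):(j * cfg$d)] <-
            e[j:(n_pos + j - 1L), , drop = FALSE]
        }
        pre <- z %*% w + matrix(bias, n_pos, nf, byrow = TRUE)
        act <- pmax(pre, 0)
        arg[i, ] <- max.col(t(act), ties.method = "first")
        pooled[i, (si - 1L) * nf + seq_len(nf)] <-
          act[cbind(arg[i, ], seq_len(nf))]
        zs[[i]] <- z
      }
      cache[[si]] <- list(zs = zs, arg = arg)
    }
    dropped <- if (is.null(mask)) pooled else pooled * mask
    z_out <- drop(dropped %*% p$denseW) + p$denseb
    list(prob = stats::plogis(z_out), z_out = z_out, pooled = pooled,
         dropped = dropped, cache = cache)
  }

  l2_penalty <- function(p) {
    terms <- setdiff(trainable_names, "emb")
    cfg$l2 * sum(vapply(terms, function(nm) sum(p[[nm]]^2), numeric(1)))
  }

  model <- list(
    kind = "textcnn",
    cfg = cfg,
    n_pooled = n_pooled,
    init = function(seed) {
      ei <- embedding_init(vocab, mode = cfg$mode, table = table,
                           d = cfg$d, seed = seed)
      if (cfg$mode == "static") env$emb <- ei$weights
      stream <- rng_stream(derive_seed(seed, 808L))
      params <- list()
      if (cfg$mode != "static") params$emb <- ei$weights
      for (h in sizes) {
        params[[paste0("convW", h)]] <- glorot_uniform(h * cfg$d, nf, stream)
        params[[paste0("convb", h)]] <- rep(0, nf)
      }
      params$denseW <- drop(glorot_uniform(n_pooled, 1L, stream))
      params$denseb <- 0
      flatten_params(params)
    },
    loss = function(pv, data) {
      p <- unflatten_params(pv)
      z <- forward(p, data$ids)$z_out
      mean(log1pexp(z) - data$y * z) + l2_penalty(p)
    },
    grad = function(pv, data, idx = NULL, stream = NULL) {
      p <- unflatten_params(pv)
      if (is.null(idx)) idx <- seq_along(data$y)
      ids <- data$ids[idx, , drop = FALSE]
      y <- data$y[idx]
      b <- length(idx)
      mask <- NULL
      if (cfg$dropout > 0 && !is.null(stream)) {
        keep <- 1 - cfg$dropout
        mask <- draw_with(stream,
          matrix(rbinom(b * n_pooled, 1L, keep), b, n_pooled)) / keep
      }
      fw <- forward(p, ids, mask)
      dz <- (fw$prob - y) / b
      g <- list()
      if (cfg$mode != "static") g$emb <- matrix(0, nrow(p$emb), ncol(p$emb))
      g$denseW <- drop(crossprod(fw$dropped, dz)) + 2 * cfg$l2 * p$denseW
      g$denseb <- sum(dz) + 2 * cfg$l2 * p$denseb
      d_drop <- outer(dz, p$denseW)
      d_pool <- if (is.null(mask)) d_drop else d_drop * mask
      for (si in seq_along(sizes)) {
        h <- sizes[si]
        w <- p[[paste0("convW", h)]]
        ca <- fw$cache[[si]]
        dw <- matrix(0, h * cfg$d, nf)
        db <- rep(0, nf)
        cols <- (si - 1L) * nf + seq_len(nf)
        for (i in seq_len(b)) {
          dp <- d_pool[i, cols]
          active <- fw$pooled[i, cols] > 0    # ReLU subgradient 0 at <= 0
          dp <- dp * active
          nz <- which(dp != 0)
          if (!length(nz)) next
          z <- ca$zs[[i]]
          dzrow <- NULL
          for (f in nz) {
            pos <- ca$arg[i, f]
            dw[, f] <- dw[, f] + z[pos, ] * dp[f]
            db[f] <- db[f] + dp[f]
          }
          if (cfg$mode != "static") {
            # scatter through the windows back onto embedding rows
            for (f in nz) {
              pos <- ca$arg[i, f]
              dvec <- w[, f] * dp[f]
              for (j in seq_len(h)) {
                row <- ids[i, pos + j - 1L] + 1L
                g$emb[row, ] <- g$emb[row, ] +
                  dvec[((j - 1L) * cfg$d + 1L):(j * cfg$d)]
              }
            }
          }
        }
        g[[paste0("convW", h)]] <- dw + 2 * cfg$l2 * w
        g[[paste0("convb", h)]] <- db + 2 * cfg$l2 * p[[paste0("convb", h)]]
      }
      if (cfg$mode != "static") g$emb[1L, ] <- 0   # padding row stays pinned
      flatten_params(g[trainable_names])
    },
    predict = function(pv, data) {
      p <- unflatten_params(pv)
      forward(p, data$ids)$prob
    },
    frozen_embedding = function() env$emb
  )
  class(model) <- c("textcnn_model", "fed_model")
  model
}
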