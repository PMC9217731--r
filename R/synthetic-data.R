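# Synthetic study inputs.
#
# The corpus generator emulates a labeled user-post corpus with a
# class-discriminative vocabulary: token frequencies follow a Zipf-like
# base distribution, and a chosen subset of "signal" tokens has its
# log-weight shifted by `signal_strength` in the positive
# (depression-labeled) class only, so the ground-truth per-token log-odds
# are known exactly. The vector generator emulates a 10-class image-style
# dataset (Gaussian class blobs) for partitioning experiments. Default
# corpus shape mirrors a 900-user cohort with 327 positive users and an
# 80/20 train/test split.

#' Generate a labeled user-post corpus
#'
#' @param n_users Number of users (default 900).
#' @param prevalence Positive-class probability (default 327/900).
#' @param vocab_size Vocabulary size.
#' @param signal_tokens Number of class-discriminative tokens.
#' @param signal_strength Log-weight shift of signal tokens in the
#'   positive class (0 = null signal: both class-conditional token
#'   distributions identical).
#' @param posts_per_user Integer range (min, max) of posts per user.
#' @param post_length Integer range (min, max) of tokens per post.
#' @param zipf Exponent of the Zipf-like base token weights.
#' @param seed Integer seed; the corpus is a pure function of the
#'   arguments.
#' @return A corpus tibble (`user_id`, `posts`, `label`) with attributes
#'   `token_log_odds` (named vector of true log P(token|pos)/P(token|neg)),
#'   `signal_ids` and `spec`.
#' @export
gen_corpus <- function(n_users = 900, prevalence = 327 / 900,
                       vocab_size = 500, signal_tokens = 40,
                       signal_strength = 1.2,
                       posts_per_user = c(3L, 8L),
                       post_length = c(5L, 15L),
                       zipf = 0.7, seed = 1L) {
  stopifnot(n_users >= 1, prevalence > 0, prevalence < 1,
            prevalence * n_users >= 1, signal_tokens < vocab_size,
            signal_strength >= 0, length(posts_per_user) == 2,
            length(post_length) == 2)
  stream <- rng_stream(derive_seed(seed, 1101L))
  tokens <- sprintf("tok%05d", seq_len(vocab_size))
  base_w <- 1 / seq_len(vocab_size)^zipf
  signal_ids <- draw_with(stream, sample.int(vocab_size, signal_tokens))
  pos_w <- base_w
  pos_w[signal_ids] <- pos_w[signal_ids] * exp(signal_strength)
  p_neg <- base_w / sum(base_w)
  p_pos <- pos_w / sum(pos_w)
  log_odds <- stats::setNames(log(p_pos / p_neg), tokens)

  labels <- draw_with(stream, rbinom(n_users, 1L, prevalence))
  posts <- vector("list", n_users)
  for (i in seq_len(n_users)) {
    probs <- if (labels[i] == 1L) p_pos else p_neg
    np <- draw_with(stream,
      sample(posts_per_user[1]:posts_per_user[2], 1L))
    posts[[i]] <- lapply(seq_len(np), function(j) {
      len <- draw_with(stream, sample(post_length[1]:post_length[2], 1L))
      tokens[draw_with(stream,
        sample.int(vocab_size, len, replace = TRUE, prob = probs))]
    })
  }
  corpus <- tibble::tibble(
    user_id = sprintf("user%05d", seq_len(n_users)),
    posts = posts,
    label = as.integer(labels)
  )
  attr(corpus, "token_log_odds") <- log_odds
  attr(corpus, "signal_ids") <- signal_ids
  attr(corpus, "spec") <- list(n_users = n_users, prevalence = prevalence,
                               vocab_size = vocab_size,
                               signal_tokens = signal_tokens,
                               signal_strength = signal_strength,
                               posts_per_user = posts_per_user,
                               post_length = post_length, zipf = zipf,
                               seed = seed)
  corpus
}

#' Generate a synthetic embedding table
#'
#' Gaussian random vectors in word2vec text-format shape, one row per
#' token.
#'
#' @param tokens Character vector of tokens (e.g. a vocabulary's tokens).
#' @param d Embedding dimension (default 300).
#' @param sd Entry standard deviation.
#' @param seed Integer seed.
#' @return An `embedding_table`.
#' @export
gen_embedding_table <- function(tokens, d = 300L, sd = 0.3, seed = 1L) {
  stream <- rng_stream(derive_seed(seed, 1202L))
  m <- draw_with(stream, matrix(rnorm(length(tokens) * d, sd = sd),
                                length(tokens), d))
  new_embedding_table(tokens, m)
}

#' Generate a labeled Gaussian-blob vector dataset
#'
#' Class-balanced stand-in for an image-classification training set
#' (e.g. 60,000 records across 10 classes): class centers are seeded
#' random directions scaled by `class_sep`, points are unit-variance
#' Gaussians around them.
#'
#' @param n Total number of records.
#' @param n_classes Number of classes (>= 2).
#' @param dim Feature dimension.
#' @param class_sep Distance scale of the class centers (0 = chance-level
#'   separability).
#' @param seed Integer seed.
#' @return Tibble with `label` (0-based integer) and feature columns
#'   `x1..xdim`; classes are exactly balanced up to remainder.
#' @export
gen_vectors <- function(n, n_classes = 10L, dim = 20L, class_sep = 2,
                        seed = 1L) {
  if (n_classes < 2) abort("n_classes must be >= 2")
  stopifnot(n >= n_classes, dim >= 1, class_sep >= 0)
  stream <- rng_stream(derive_seed(seed, 1303L))
  centers <- draw_with(stream, matrix(rnorm(n_classes * dim), n_classes, dim))
  centers <- centers / sqrt(rowSums(centers^2)) * class_sep
  base <- n %/% n_classes
  counts <- rep(base, n_classes) + c(rep(1L, n %% n_classes),
                                     rep(0L, n_classes - n %% n_classes))
  labels <- rep(seq_len(n_classes) - 1L, counts)
  labels <- draw_with(stream, sample(labels))
  x <- centers[labels + 1L, , drop = FALSE] +
    draw_with(stream, matrix(rnorm(n * dim), n, dim))
  out <- tibble::as_tibble(as.data.frame(x), .name_repair = ~ paste0("x", seq_len(dim)))
  dplyr::bind_cols(tibble::tibble(label = labels), out)
}

#' Partition a dataset across devices
#'
#' Three schemes:
#' * `iid` — a seeded shuffle split into near-equal parts;
#' * `shards` — the pathological non-IID scheme: sort by label, cut into
#'   `n_shards` contiguous shards of `shard_size`, then deal
#'   `shards_per_device` shards to each device in a seeded round-robin,
#'   so each device sees very few distinct labels;
#' * `imbalanced` — device sizes drawn from a seeded power law (each at
#'   least `min_size`).
#'
#' @param data A data frame with a `label` column, a label vector, or a
#'   single integer (the dataset size; sufficient for `iid` and
#'   `imbalanced`).
#' @param scheme `"iid"`, `"shards"`, or `"imbalanced"`.
#' @param n_devices Number of devices.
#' @param n_shards,shard_size,shards_per_device Shard-scheme geometry;
#'   must satisfy `n_shards * shard_size == N` and
#'   `n_shards == n_devices * shards_per_device`.
#' @param min_size Minimum device size for `imbalanced` (default 16, a
#'   minibatch).
#' @param alpha Power-law exponent for `imbalanced` sizes.
#' @param seed Integer seed.
#' @return List of `n_devices` disjoint integer index vectors covering
#'   `1..N`, with attribute `scheme`.
#' @export
partition_data <- function(data, scheme = c("iid", "shards", "imbalanced"),
                           n_devices, n_shards = NULL, shard_size = NULL,
                           shards_per_device = NULL, min_size = 16L,
                           alpha = 1.5, seed = 1L) {
  scheme <- match.arg(scheme)
  labels <- NULL
  if (is.data.frame(data)) {
    n <- nrow(data)
    labels <- data$label
  } else if (length(data) == 1 && is.numeric(data)) {
    n <- as.integer(data)
  } else {
    n <- length(data)
    labels <- data
  }
  stopifnot(n_devices >= 1, n >= n_devices)
  stream <- rng_stream(derive_seed(seed, 1404L))

  out <- switch(scheme,
    iid = {
      idx <- draw_with(stream, sample.int(n))
      sizes <- rep(n %/% n_devices, n_devices)
      rem <- n %% n_devices
      if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
      split(idx, rep(seq_len(n_devices), sizes))
    },
    shards = {
      if (is.null(labels)) abort("shards scheme needs labels")
      if (is.null(n_shards) || is.null(shard_size) || is.null(shards_per_device)) {
        abort("shards scheme needs n_shards, shard_size, shards_per_device")
      }
      if (n_shards * shard_size != n) {
        abort("n_shards * shard_size must equal the dataset size")
      }
      if (n_shards != n_devices * shards_per_device) {
        abort("n_shards must equal n_devices * shards_per_device")
      }
      by_label <- order(labels)   # stable: ties keep original order
      shard_of <- rep(seq_len(n_shards), each = shard_size)
      dealt <- draw_with(stream, sample.int(n_shards))
      device_of_shard <- integer(n_shards)
      device_of_shard[dealt] <- rep(seq_len(n_devices),
                                    length.out = n_shards)
      lapply(seq_len(n_devices), function(d) {
        by_label[shard_of %in% which(device_of_shard == d)]
      })
    },
    imbalanced = {
      raw <- draw_with(stream, runif(n_devices))^(-1 / alpha)
      avail <- n - n_devices * min_size
      if (avail < 0) abort("dataset too small for min_size per device")
      extra <- floor(avail * raw / sum(raw))
      sizes <- min_size + extra
      short <- n - sum(sizes)
      if (short > 0) {   # hand rounding remainders to the largest devices
        ord <- order(-raw)
        sizes[ord[seq_len(short)]] <- sizes[ord[seq_len(short)]] + 1L
      }
      idx <- draw_with(stream, sample.int(n))
      split(idx, rep(seq_len(n_devices), sizes))
    })
  out <- lapply(unname(out), as.integer)
  attr(out, "scheme") <- scheme
  out
}

#' Stratified train/test split of a corpus
#'
#' @param corpus A corpus tibble.
#' @param test_frac Fraction held out (default 0.2).
#' @param seed Integer seed.
#' @return List with `train` and `test` corpus tibbles (per-class
#'   proportions preserved).
#' @export
split_corpus <- function(corpus, test_frac = 0.2, seed = 1L) {
  check_corpus(corpus)
  stream <- rng_stream(derive_seed(seed, 1505L))
  test_idx <- integer(0)
  for (lab in c(0L, 1L)) {
    idx <- which(corpus$label == lab)
    k <- round(length(idx) * test_frac)
    if (k > 0) test_idx <- c(test_idx, draw_with(stream, sample(idx, k)))
  }
  if (length(test_idx) == 0) {
    return(list(train = corpus, test = corpus[0, ]))
  }
  list(train = corpus[-test_idx, ], test = corpus[test_idx, ])
}

#' Bag-of-words logistic features for a corpus
#'
#' Convenience pipeline for the convex stand-in classifier: token counts
#' over `vocab`, min-max normalized to [0, 1] (stats fitted on the
#' training matrix and re-applied to any later matrix).
#'
#' @param corpus A corpus tibble.
#' @param vocab Vocabulary tibble.
#' @param stats `NULL` to fit normalization stats, or previously fitted
#'   stats.
#' @return List with `x` (normalized matrix), `y` (labels), `stats`.
#' @export
corpus_features <- function(corpus, vocab, stats = NULL) {
  x <- bag_of_words(corpus, vocab)
  x <- suppressWarnings(minmax_normalize(x, stats))
  list(x = x, y = as.numeric(corpus$label), stats = attr(x, "stats"))
}

#' Reduced-scale federated text study setup
#'
#' The canonical desk-scale configuration used by the convergence and
#' privacy-noise studies: a synthetic user-post corpus (default 2,000
#' users at the cohort prevalence), a stratified 80/20 split, bag-of-words
#' features min-max fitted on the training split, the logistic stand-in
#' classifier, and an IID partition onto `n_devices` devices.
#'
#' @param seed Master seed (drives corpus, split, and partition).
#' @param n_users Corpus size (default 2,000).
#' @param n_devices Devices (default 10).
#' @param test_frac Held-out fraction (default 0.2).
#' @param vocab_size,signal_strength Corpus vocabulary parameters.
#' @param l2 Logistic l2 coefficient.
#' @return List with `model`, `shards`, `train`, `test` datasets and the
#'   `vocab`.
#' @export
corpus_study <- function(seed, n_users = 2000, n_devices = 10,
                         test_frac = 0.2, vocab_size = 500,
                         signal_strength = 1.2, l2 = 1e-4) {
  co <- gen_corpus(n_users = n_users, vocab_size = vocab_size,
                   signal_strength = signal_strength, seed = seed)
  sp <- split_corpus(co, test_frac, seed = seed)
  vocab <- build_vocabulary(sp$train)
  ftr <- corpus_features(sp$train, vocab)
  fte <- corpus_features(sp$test, vocab, stats = ftr$stats)
  parts <- partition_data(nrow(sp$train), "iid", n_devices, seed = seed)
  train <- list(x = ftr$x, y = ftr$y)
  shards <- lapply(parts, function(i)
    list(x = train$x[i, , drop = FALSE], y = train$y[i]))
  list(model = make_logistic_model(ncol(ftr$x), l2 = l2),
       shards = shards, train = train,
       test = list(x = fte$x, y = fte$y), vocab = vocab)
}
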