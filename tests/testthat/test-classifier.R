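# Shared tiny setup for CNN tests.
cnn_setup <- function(mode = "rand", dropout = 0, l2 = 0, d = 5, L = 12,
                      filter_sizes = c(2, 3), n_filters = 4, seed = 5) {
  co <- gen_corpus(n_users = 24, vocab_size = 40, signal_tokens = 8,
                   seed = seed, posts_per_user = c(2, 3),
                   post_length = c(3, 6))
  vocab <- build_vocabulary(co)
  tab <- gen_embedding_table(vocab$token, d = d, seed = seed)
  cfg <- textcnn_config(d = d, L = L, filter_sizes = filter_sizes,
                        n_filters = n_filters, dropout = dropout, l2 = l2,
                        mode = mode)
  model <- build_textcnn(cfg, vocab, tab)
  sm <- concat_posts(co, vocab, L = L)
  list(model = model, cfg = cfg, vocab = vocab, tab = tab,
       data = list(ids = sm$ids, y = as.numeric(co$label)))
}

test_that("architecture arithmetic and seeded init determinism", {
  s <- cnn_setup(n_filters = 128, filter_sizes = c(3, 4, 5))
  expect_equal(s$model$n_pooled, 128 * 3)          # 384 pooled features
  p <- unflatten_params(s$model$init(9))
  expect_length(p$denseW, 384)
  expect_identical(as.numeric(s$model$init(9)), as.numeric(s$model$init(9)))
  expect_false(identical(as.numeric(s$model$init(9)),
                         as.numeric(s$model$init(10))))
  expect_error(textcnn_config(d = 5, L = 4, filter_sizes = 5), "filter size")
})

test_that("all-pad input with zero conv bias flows only through the output bias", {
  s <- cnn_setup()
  pv <- s$model$init(3)
  p <- unflatten_params(pv)
  allpad <- list(ids = matrix(0L, 2, s$cfg$L), y = c(0, 1))
  # conv biases init to zero and pad embedding is zero, so pooled = 0 and
  # the prediction is sigmoid of the output bias alone
  expect_equal(s$model$predict(pv, allpad),
               rep(stats::plogis(p$denseb), 2))
})

test_that("predictions are deterministic probabilities with >= threshold labels", {
  s <- cnn_setup()
  pv <- s$model$init(4)
  p <- s$model$predict(pv, s$data)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, s$model$predict(pv, s$data))
  # two identical rows give identical probabilities
  dup <- list(ids = s$data$ids[c(1, 1), ], y = c(0, 0))
  pd <- s$model$predict(pv, dup)
  expect_identical(pd[1], pd[2])
  # boundary convention: probability exactly at threshold labels positive
  ev <- evaluate_model(s$model, pv, list(ids = s$data$ids[1, , drop = FALSE],
                                         y = 1), threshold = p[1])
  expect_equal(ev$accuracy, 1)
})

test_that("loss equals mean binary cross-entropy plus l2 penalty", {
  s <- cnn_setup(l2 = 0)
  pv0 <- s$model$init(2)
  zero <- new_param_vector(numeric(length(pv0)), attr(pv0, "keys"))
  # zero parameters (rand mode: embedding in the vector) -> p = 0.5 -> ln 2
  expect_equal(s$model$loss(zero, s$data), log(2))

  # per-example hand-summed cross-entropy
  p <- s$model$predict(pv0, s$data)
  hand <- -mean(s$data$y * log(p) + (1 - s$data$y) * log(1 - p))
  expect_equal(s$model$loss(pv0, s$data), hand, tolerance = 1e-6)

  # l2 adds the non-embedding penalty
  s2 <- cnn_setup(l2 = 0.01)
  pv <- s2$model$init(2)
  pl <- unflatten_params(pv)
  pen <- 0.01 * sum(vapply(setdiff(names(pl), "emb"),
                           function(nm) sum(pl[[nm]]^2), numeric(1)))
  expect_equal(s2$model$loss(pv, s2$data) - pen,
               cnn_setup(l2 = 0)$model$loss(pv, s2$data), tolerance = 1e-12)
})

test_that("backprop matches finite differences in every mode", {
  for (mode in c("rand", "static", "nostatic")) {
    s <- cnn_setup(mode = mode, l2 = 1e-3)
    pv <- s$model$init(7)
    g <- s$model$grad(pv, s$data)
    set.seed(31)
    ks <- sample(length(pv), 25)
    eps <- 1e-6
    num <- vapply(ks, function(k) {
      a <- as.numeric(pv); b <- as.numeric(pv)
      a[k] <- a[k] + eps; b[k] <- b[k] - eps
      keys <- attr(pv, "keys")
      (s$model$loss(new_param_vector(a, keys), s$data) -
         s$model$loss(new_param_vector(b, keys), s$data)) / (2 * eps)
    }, numeric(1))
    expect_equal(as.numeric(g)[ks], num, tolerance = 1e-5)
  }
})

test_that("dropout is train-only, seeded, and off at evaluation", {
  s <- cnn_setup(dropout = 0.5)
  pv <- s$model$init(1)
  g1 <- s$model$grad(pv, s$data, stream = rng_stream(3))
  g2 <- s$model$grad(pv, s$data, stream = rng_stream(3))
  g3 <- s$model$grad(pv, s$data, stream = rng_stream(4))
  expect_identical(as.numeric(g1), as.numeric(g2))
  expect_false(identical(as.numeric(g1), as.numeric(g3)))
  # evaluation path has no dropout: pure function of (params, input)
  expect_identical(s$model$predict(pv, s$data), s$model$predict(pv, s$data))
})

test_that("one SGD step with zero learning rate leaves parameters unchanged", {
  s <- tiny_logistic_setup()
  pv <- model_init(s$model, 5)
  out <- worker_local_round(s$model, pv, s$data, gamma = 0,
                            batch_size = 8, steps = 3,
                            stream = rng_stream(2))
  expect_identical(as.numeric(out), as.numeric(pv))
})

test_that("loss decreases over early training on a separable corpus", {
  co <- gen_corpus(n_users = 150, vocab_size = 60, signal_tokens = 15,
                   signal_strength = 2.5, seed = 17)
  vocab <- build_vocabulary(co)
  tab <- gen_embedding_table(vocab$token, d = 8, seed = 17)
  cfg <- textcnn_config(d = 8, L = 40, filter_sizes = c(3, 4), n_filters = 4,
                        dropout = 0, mode = "nostatic")
  m <- build_textcnn(cfg, vocab, tab)
  sm <- concat_posts(co, vocab, L = 40)
  data <- list(ids = sm$ids, y = as.numeric(co$label))
  pv0 <- m$init(17)
  l0 <- m$loss(pv0, data)
  pv1 <- worker_local_round(m, pv0, data, gamma = 0.3, batch_size = 16,
                            steps = 40, stream = rng_stream(17))
  expect_lt(m$loss(pv1, data), l0)
})
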