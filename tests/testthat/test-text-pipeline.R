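test_that("stopword removal filters by membership, preserves order, idempotent", {
  expect_equal(remove_stopwords(list(c("I", "oh", "sad")), "oh")[[1]],
               c("I", "sad"))
  posts <- list(c("a", "b", "a"), c("c"))
  expect_identical(remove_stopwords(posts, character(0)), posts)

  # random corpus against a per-token membership filter
  set.seed(3)
  vocab <- sprintf("w%02d", 1:30)
  sw <- sample(vocab, 8)
  corp <- gen_corpus(n_users = 25, vocab_size = 30, signal_tokens = 5, seed = 3)
  got <- remove_stopwords(corp, sw)
  for (i in seq_len(nrow(corp))) {
    for (j in seq_along(corp$posts[[i]])) {
      p <- corp$posts[[i]][[j]]
      expect_identical(got$posts[[i]][[j]], p[!vapply(p, `%in%`, logical(1), sw)])
    }
  }
  # never increases token count; idempotent
  count <- function(co) sum(lengths(unlist(co$posts, recursive = FALSE)))
  expect_lte(count(got), count(corp))
  expect_identical(remove_stopwords(got, sw)$posts, got$posts)
})

test_that("concat_posts truncates/right-pads to exactly L", {
  vocab <- tibble::tibble(token = c("a", "b", "c", "d"), id = 1:4,
                          count = c(4L, 3L, 2L, 1L))
  co <- toy_corpus()[1:2, ]
  out <- concat_posts(co, vocab, L = 5)
  expect_equal(out$ids[1, ], c(1L, 2L, 3L, 0L, 0L))   # [a,b],[c] -> a b c pad pad
  expect_equal(out$ids[2, ], c(4L, 1L, 1L, 2L, 3L))   # 7 tokens -> first 5
  expect_equal(ncol(out$ids), 5)

  # non-pad prefix length equals the summed post lengths when they fit
  co3 <- gen_corpus(n_users = 15, vocab_size = 25, signal_tokens = 5, seed = 5)
  v3 <- build_vocabulary(co3)
  big <- concat_posts(co3, v3, L = 500)
  expect_equal(rowSums(big$ids != 0), vapply(co3$posts, function(p)
    sum(lengths(p)), numeric(1)))

  # record with zero usable tokens -> all-pad row plus a warning
  expect_warning(res <- concat_posts(toy_corpus(), vocab, L = 4), "no usable")
  expect_equal(res$ids[3, ], rep(0L, 4))
})

test_that("min-max normalization maps to [0,1] and matches elementwise oracle", {
  expect_equal(as.numeric(minmax_normalize(matrix(c(2, 4, 6), ncol = 1))),
               c(0, 0.5, 1))

  set.seed(11)
  x <- matrix(rnorm(60, sd = 4), 12, 5)
  z <- minmax_normalize(x)
  expect_true(all(z >= 0 & z <= 1))
  oracle <- x
  for (j in 1:5) {
    oracle[, j] <- (x[, j] - min(x[, j])) / (max(x[, j]) - min(x[, j]))
  }
  expect_equal(unclass(z), oracle, ignore_attr = TRUE)

  # fit-then-apply on the same data is idempotent
  z2 <- minmax_normalize(z, attr(z, "stats") |> dplyr::mutate(min = 0, max = 1))
  expect_equal(unclass(z2), unclass(z), ignore_attr = TRUE)

  # constant columns map to 0
  zc <- minmax_normalize(cbind(rep(3, 4), 1:4))
  expect_equal(zc[, 1], rep(0, 4))

  # out-of-range values under fitted stats clip to [0,1] with a warning
  stats <- attr(minmax_normalize(matrix(c(0, 1), ncol = 1)), "stats")
  expect_warning(cl <- minmax_normalize(matrix(c(-1, 2), ncol = 1), stats),
                 "clipped")
  expect_equal(as.numeric(cl), c(0, 1))
})

test_that("word2vec text table round-trips and embedding modes behave", {
  tokens <- sprintf("t%02d", 1:12)
  tab <- gen_embedding_table(tokens, d = 6, seed = 2)
  path <- withr::local_tempfile()
  write_word2vec(tab, path)
  back <- read_word2vec(path)
  expect_identical(back$tokens, tokens)
  expect_identical(unname(back$matrix), unname(tab$matrix))

  vocab <- tibble::tibble(token = c(tokens[1:8], "unk1", "unk2"),
                          id = 1:10, count = 10:1)
  st <- embedding_init(vocab, "static", table = tab, seed = 5)
  expect_false(st$trainable)
  expect_equal(st$n_unknown, 2)
  # in-vocabulary rows equal table rows exactly; pad row zero
  expect_identical(st$weights[2:9, ], unname(tab$matrix[1:8, ]))
  expect_equal(st$weights[1, ], rep(0, 6))

  r1 <- embedding_init(vocab, "rand", d = 6, seed = 5)
  r2 <- embedding_init(vocab, "rand", d = 6, seed = 5)
  expect_identical(r1$weights, r2$weights)
  expect_true(r1$trainable)

  ns <- embedding_init(vocab, "nostatic", table = tab, seed = 5)
  expect_true(ns$trainable)
  expect_identical(ns$weights[2:9, ], unname(tab$matrix[1:8, ]))
})

test_that("static embeddings are frozen by training, nostatic ones move", {
  co <- gen_corpus(n_users = 40, vocab_size = 30, signal_tokens = 8,
                   signal_strength = 2, seed = 13)
  vocab <- build_vocabulary(co)
  tab <- gen_embedding_table(vocab$token, d = 4, seed = 13)
  sm <- concat_posts(co, vocab, L = 20)
  data <- list(ids = sm$ids, y = as.numeric(co$label))

  cfg_s <- textcnn_config(d = 4, L = 20, filter_sizes = 2, n_filters = 3,
                          dropout = 0, mode = "static")
  m_s <- build_textcnn(cfg_s, vocab, tab)
  pv <- m_s$init(1)
  before <- m_s$frozen_embedding()
  pv2 <- worker_local_round(m_s, pv, data, gamma = 0.5, batch_size = 8,
                            steps = 5, stream = rng_stream(1))
  expect_identical(m_s$frozen_embedding(), before)  # bit-identical
  expect_false(identical(as.numeric(pv2), as.numeric(pv)))

  cfg_n <- textcnn_config(d = 4, L = 20, filter_sizes = 2, n_filters = 3,
                          dropout = 0, mode = "nostatic")
  m_n <- build_textcnn(cfg_n, vocab, tab)
  pvn <- m_n$init(1)
  emb0 <- unflatten_params(pvn)$emb
  expect_identical(emb0[-1, ], unname(tab$matrix[vocab$id, ]))
  pvn2 <- worker_local_round(m_n, pvn, data, gamma = 0.5, batch_size = 8,
                             steps = 5, stream = rng_stream(1))
  emb1 <- unflatten_params(pvn2)$emb
  expect_false(identical(emb1, emb0))     # fine-tuned vectors moved
  expect_equal(emb1[1, ], rep(0, 4))      # pad row stays pinned
})

test_that("corpus JSONL round-trips byte-identically for a fixed seed", {
  co <- gen_corpus(n_users = 30, vocab_size = 50, signal_tokens = 10, seed = 77)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_corpus_jsonl(co, p1)
  write_corpus_jsonl(gen_corpus(n_users = 30, vocab_size = 50,
                                signal_tokens = 10, seed = 77), p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_corpus_jsonl(p1)
  expect_identical(back$posts, co$posts)
  expect_identical(back$label, co$label)
})
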