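# Shared in-code fixtures for the suite.

# Small labeled logistic problem derived from a synthetic corpus:
# bag-of-words features, min-max normalized, split across devices.
tiny_logistic_setup <- function(n_users = 120, n_devices = 3, seed = 7,
                                vocab_size = 40, signal_tokens = 10,
                                l2 = 0) {
  co <- gen_corpus(n_users = n_users, vocab_size = vocab_size,
                   signal_tokens = signal_tokens, seed = seed)
  vocab <- build_vocabulary(co)
  f <- corpus_features(co, vocab)
  parts <- partition_data(nrow(co), "iid", n_devices, seed = seed)
  shards <- lapply(parts, function(i) list(x = f$x[i, , drop = FALSE],
                                           y = f$y[i]))
  list(data = list(x = f$x, y = f$y), shards = shards,
       model = make_logistic_model(ncol(f$x), l2 = l2), corpus = co,
       vocab = vocab)
}

# Brute-force staleness recount over a stored pseudo-gradient log:
# the independent oracle for the incremental counter.
recount_staleness <- function(g_log, tau, t, theta = 0, k_len = NULL) {
  if (is.null(k_len)) k_len <- length(g_log[[1]])
  if (tau >= t) return(numeric(k_len))
  Reduce(`+`, lapply(g_log[(tau + 1):t], function(g) as.numeric(abs(g) > theta)))
}

# Tiny deterministic corpus for pipeline tests.
toy_corpus <- function() {
  tibble::tibble(
    user_id = c("u1", "u2", "u3"),
    posts = list(
      list(c("a", "b"), c("c")),
      list(c("d", "a", "a", "b", "c", "d", "a")),
      list(c("zzz"))          # all tokens out of any small vocabulary
    ),
    label = c(1L, 0L, 0L)
  )
}
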