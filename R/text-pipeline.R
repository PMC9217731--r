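# Text preprocessing: from a user-post corpus to fixed-size numeric inputs.
#
# A corpus is a tibble with one row per user: `user_id` (character),
# `posts` (list column; each element a list of character token vectors,
# one per post, already tokenized), and `label` (integer 0/1, 1 =
# depression-positive). Posts are kept in their stored (chronological)
# order; a user's input is the concatenation of all their posts, truncated
# or right-padded to a fixed length L.

#' Read / write a user-post corpus as JSONL
#'
#' One JSON object per line: `{"user_id": ..., "posts": [[tok,...],...],
#' "label": 0|1}`.
#'
#' @param path File path.
#' @return A corpus tibble (`user_id`, `posts`, `label`).
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
  tibble::tibble(
    user_id = vapply(recs, function(r) as.character(r$user_id), character(1)),
    posts = lapply(recs, function(r) lapply(r$posts, function(p)
      vapply(p, as.character, character(1)))),
    label = vapply(recs, function(r) as.integer(r$label), integer(1))
  )
}

#' @rdname read_corpus_jsonl
#' @param corpus A corpus tibble.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  check_corpus(corpus)
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(
      user_id = corpus$user_id[i],
      posts = corpus$posts[[i]],
      label = corpus$label[i]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

check_corpus <- function(corpus) {
  stopifnot(is.data.frame(corpus),
            all(c("user_id", "posts", "label") %in% names(corpus)),
            all(corpus$label %in% c(0L, 1L)))
  invisible(corpus)
}

#' Read a stopword list
#'
#' Plain UTF-8 text, one token per line; blank lines ignored. An empty file
#' yields an empty set (stopword removal becomes a no-op).
#'
#' @param path File path.
#' @return Character vector of stopword tokens.
#' @export
read_stopwords <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x[nzchar(x)]
}

#' Remove stopwords from posts
#'
#' Filters every post's token list by set membership, preserving order.
#' Operates on a corpus tibble (filtering the `posts` column) or directly
#' on a single user's list of token vectors.
#'
#' @param x A corpus tibble or a list of character token vectors.
#' @param stopwords Character vector of tokens to drop.
#' @return Same shape as `x` with stopword tokens removed.
#' @examples
#' remove_stopwords(list(c("I", "oh", "sad")), "oh")
#' @export
remove_stopwords <- function(x, stopwords) {
  stopwords <- as.character(stopwords)
  if (is.data.frame(x)) {
    check_corpus(x)
    dplyr::mutate(x, posts = lapply(.data$posts, filter_posts, stopwords))
  } else {
    filter_posts(x, stopwords)
  }
}

filter_posts <- function(posts, stopwords) {
  lapply(posts, function(p) p[!(p %in% stopwords)])
}

#' Build a token vocabulary from a corpus
#'
#' Tokens are ranked by corpus frequency (ties broken alphabetically) and
#' assigned ids 1..V; id 0 is reserved for padding.
#'
#' @param corpus A corpus tibble.
#' @param max_size Optional cap on vocabulary size.
#' @return Tibble with columns `token`, `id`, `count`.
#' @export
build_vocabulary <- function(corpus, max_size = Inf) {
  check_corpus(corpus)
  toks <- unlist(corpus$posts, use.names = FALSE)
  tab <- sort(table(toks), decreasing = TRUE)
  tokens <- names(tab)
  ord <- order(-as.integer(tab), tokens)
  tokens <- tokens[ord]
  counts <- as.integer(tab)[ord]
  if (is.finite(max_size) && length(tokens) > max_size) {
    tokens <- tokens[seq_len(max_size)]
    counts <- counts[seq_len(max_size)]
  }
  tibble::tibble(token = tokens, id = seq_along(tokens), count = counts)
}

#' Concatenate a user's posts into a fixed-length id sequence
#'
#' Posts are concatenated in stored order, mapped to vocabulary ids,
#' truncated to `L` or right-padded with `pad_id`. Out-of-vocabulary tokens
#' are dropped (they have no embedding row). A user with zero usable
#' tokens yields an all-pad row and a warning.
#'
#' @param corpus A corpus tibble.
#' @param vocab Vocabulary tibble from [build_vocabulary()].
#' @param L Sequence length (> 0).
#' @param pad_id Padding id (default 0, the reserved id).
#' @return List with `ids` (n x L integer matrix), `label` (integer
#'   vector), `n_tokens` (pre-truncation usable token counts).
#' @export
concat_posts <- function(corpus, vocab, L, pad_id = 0L) {
  check_corpus(corpus)
  stopifnot(L > 0)
  lookup <- stats::setNames(vocab$id, vocab$token)
  n <- nrow(corpus)
  ids <- matrix(as.integer(pad_id), n, L)
  n_tokens <- integer(n)
  empty <- 0L
  for (i in seq_len(n)) {
    toks <- unlist(corpus$posts[[i]], use.names = FALSE)
    seq_ids <- unname(lookup[toks])
    seq_ids <- seq_ids[!is.na(seq_ids)]
    n_tokens[i] <- length(seq_ids)
    if (length(seq_ids) == 0) {
      empty <- empty + 1L
      next
    }
    take <- min(L, length(seq_ids))
    ids[i, seq_len(take)] <- as.integer(seq_ids[seq_len(take)])
  }
  if (empty > 0) {
    warn(sprintf("%d record(s) had no usable tokens; emitted all-pad rows", empty))
  }
  list(ids = ids, label = as.integer(corpus$label), n_tokens = n_tokens)
}

#' Bag-of-words count features
#'
#' @param corpus A corpus tibble.
#' @param vocab Vocabulary tibble.
#' @return n x V numeric matrix of token counts (columns in vocabulary id
#'   order).
#' @export
bag_of_words <- function(corpus, vocab) {
  check_corpus(corpus)
  lookup <- stats::setNames(vocab$id, vocab$token)
  n <- nrow(corpus)
  m <- matrix(0, n, nrow(vocab), dimnames = list(NULL, vocab$token))
  for (i in seq_len(n)) {
    toks <- unlist(corpus$posts[[i]], use.names = FALSE)
    idx <- unname(lookup[toks])
    idx <- idx[!is.na(idx)]
    if (length(idx)) {
      tab <- tabulate(idx, nbins = nrow(vocab))
      m[i, ] <- tab
    }
  }
  m
}

#' Min-max normalize features to [0, 1]
#'
#' With `stats = NULL` the per-column min/max are fitted on `x` (which
#' should be the training matrix only, to avoid leakage) and attached to
#' the result; pass a previously fitted `stats` tibble to apply the same
#' affine map to new data. Constant columns map to 0. Out-of-range values
#' under pre-fitted stats are clipped to [0, 1] with a warning.
#'
#' @param x Numeric matrix.
#' @param stats `NULL` to fit, or a tibble with columns `col`, `min`,
#'   `max` as returned in the `stats` attribute.
#' @return Normalized matrix with attribute `"stats"`.
#' @examples
#' minmax_normalize(matrix(c(2, 4, 6), ncol = 1))
#' @export
minmax_normalize <- function(x, stats = NULL) {
  x <- as.matrix(x)
  fit <- is.null(stats)
  if (fit) {
    stats <- tibble::tibble(
      col = seq_len(ncol(x)),
      min = apply(x, 2, min),
      max = apply(x, 2, max)
    )
  }
  stopifnot(nrow(stats) == ncol(x))
  rng <- stats$max - stats$min
  rng[rng == 0] <- 1  # constant columns map to 0
  out <- sweep(sweep(x, 2, stats$min, "-"), 2, rng, "/")
  if (!fit && (any(out < 0) || any(out > 1))) {
    warn(sprintf("%d value(s) outside fitted range; clipped to [0, 1]",
                 sum(out < 0 | out > 1)))
    out[out < 0] <- 0
    out[out > 1] <- 1
  }
  dimnames(out) <- dimnames(x)
  attr(out, "stats") <- stats
  out
}
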