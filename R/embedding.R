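# Word-embedding tables (word2vec text format) and the embedding layer's
# three fine-tuning modes:
#   rand     - rows randomly initialized from the seed, trainable;
#   static   - rows copied from the pre-trained table, frozen (unknown
#              tokens get seeded random rows, also frozen);
#   nostatic - rows copied from the table, fine-tuned during training.

#' Read / write an embedding table in word2vec text format
#'
#' First line "|V| d", then one line per token: "token v1 ... vd".
#'
#' @param path File path.
#' @return An `embedding_table`: list with `tokens` (character) and
#'   `matrix` (|V| x d numeric, rownames = tokens).
#' @export
read_word2vec <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  v <- hdr[1]; d <- hdr[2]
  stopifnot(length(lines) >= v + 1, d > 0)
  parts <- strsplit(lines[1 + seq_len(v)], " ", fixed = TRUE)
  tokens <- vapply(parts, `[[`, character(1), 1)
  mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(d)))
  if (anyDuplicated(tokens)) abort("duplicate tokens in embedding table")
  rownames(mat) <- tokens
  structure(list(tokens = tokens, matrix = mat, d = d),
            class = "embedding_table")
}

#' @rdname read_word2vec
#' @param table An `embedding_table`.
#' @export
write_word2vec <- function(table, path) {
  stopifnot(inherits(table, "embedding_table"))
  m <- table$matrix
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(table$tokens[i], paste(sprintf("%.17g", m[i, ]), collapse = " "))
  }, character(1))
  writeLines(c(sprintf("%d %d", nrow(m), ncol(m)), body), path, useBytes = TRUE)
  invisible(path)
}

new_embedding_table <- function(tokens, matrix) {
  rownames(matrix) <- tokens
  structure(list(tokens = tokens, matrix = matrix, d = ncol(matrix)),
            class = "embedding_table")
}

#' Initialize embedding-layer weights for a vocabulary
#'
#' Builds the (V+1) x d weight matrix used by the text CNN: row 1 is the
#' padding row (always zero, never trained); rows 2..V+1 correspond to
#' vocabulary ids 1..V. In `static`/`nostatic` mode, rows are copied from
#' the pre-trained table; vocabulary tokens absent from the table get
#' seeded random rows (their count is recorded). In `rand` mode all rows
#' are seeded random draws and the table is ignored.
#'
#' @param vocab Vocabulary tibble ([build_vocabulary()]).
#' @param mode One of `"rand"`, `"static"`, `"nostatic"`.
#' @param table An `embedding_table` (required unless mode = "rand").
#' @param d Embedding dimension (taken from `table` when given).
#' @param seed Integer seed for random rows.
#' @param init_sd Standard deviation of random initial rows.
#' @return List with `weights` ((V+1) x d), `trainable` (logical),
#'   `n_unknown` (tokens not found in the table), `mode`.
#' @export
embedding_init <- function(vocab, mode = c("rand", "static", "nostatic"),
                           table = NULL, d = NULL, seed = 1L,
                           init_sd = 0.1) {
  mode <- match.arg(mode)
  v <- nrow(vocab)
  if (!is.null(table)) d <- table$d
  stopifnot(!is.null(d), d > 0)
  stream <- rng_stream(derive_seed(seed, 7001L))
  weights <- matrix(0, v + 1L, d)
  n_unknown <- 0L
  if (mode == "rand") {
    weights[-1, ] <- draw_with(stream, matrix(rnorm(v * d, sd = init_sd), v, d))
  } else {
    if (is.null(table)) abort("static/nostatic modes require an embedding table")
    hit <- match(vocab$token, table$tokens)
    known <- !is.na(hit)
    if (any(known)) weights[1L + which(known), ] <- table$matrix[hit[known], ]
    n_unknown <- sum(!known)
    if (n_unknown > 0) {
      weights[1L + which(!known), ] <-
        draw_with(stream, matrix(rnorm(n_unknown * d, sd = init_sd), n_unknown, d))
    }
  }
  list(weights = weights,
       trainable = mode %in% c("rand", "nostatic"),
       n_unknown = n_unknown,
       mode = mode)
}
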