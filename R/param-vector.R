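# Flat, key-indexed parameter container.
#
# All server-side arithmetic — the pseudo-gradient, per-entry staleness
# counting, adaptive weighting, and noise injection — operates entry-wise on
# a flat vector with a stable global index k. A param_vector is a numeric
# vector carrying a `keys` attribute: an ordered list of (name, dim)
# descriptors that defines the flattening and makes it invertible.

new_param_vector <- function(values, keys) {
  total <- sum(vapply(keys, function(k) prod(k$dim), numeric(1)))
  if (length(values) != total) {
    abort(sprintf("param_vector length %d does not match keys total %d",
                  length(values), total))
  }
  structure(as.numeric(values), keys = keys, class = "param_vector")
}

#' Flatten a list of parameter arrays into a param_vector
#'
#' Layers are flattened in registration (list) order, each in R's
#' column-major order, so the global entry index k is stable for a given
#' model class.
#'
#' @param params Named list of numeric vectors/matrices/arrays.
#' @return A `param_vector`.
#' @examples
#' pv <- flatten_params(list(w = matrix(1:6, 2, 3), b = rep(0, 3)))
#' length(pv) # 9
#' @export
flatten_params <- function(params) {
  stopifnot(is.list(params), length(params) > 0, !is.null(names(params)),
            all(nzchar(names(params))))
  keys <- purrr::map2(names(params), params, function(nm, p) {
    list(name = nm, dim = if (is.null(dim(p))) length(p) else dim(p))
  })
  new_param_vector(unlist(lapply(params, as.numeric), use.names = FALSE), keys)
}

#' Invert [flatten_params()]
#'
#' @param pv A `param_vector`.
#' @return The named list of arrays, bit-identical to the flattened input.
#' @export
unflatten_params <- function(pv) {
  stopifnot(inherits(pv, "param_vector"))
  keys <- attr(pv, "keys")
  out <- vector("list", length(keys))
  names(out) <- vapply(keys, `[[`, character(1), "name")
  offset <- 0L
  values <- as.numeric(pv)
  for (i in seq_along(keys)) {
    len <- prod(keys[[i]]$dim)
    block <- values[(offset + 1):(offset + len)]
    if (length(keys[[i]]$dim) > 1) dim(block) <- keys[[i]]$dim
    out[[i]] <- block
    offset <- offset + len
  }
  out
}

#' Are two param_vectors conformable?
#'
#' Conformable means the key lists (names and shapes, in order) match
#' exactly; entry-wise arithmetic is only defined between conformable
#' vectors.
#'
#' @param a,b `param_vector`s.
#' @return Logical scalar.
#' @export
conformable <- function(a, b) {
  inherits(a, "param_vector") && inherits(b, "param_vector") &&
    identical(attr(a, "keys"), attr(b, "keys"))
}

check_conformable <- function(a, b) {
  if (!conformable(a, b)) abort("param_vectors are not conformable")
  invisible(TRUE)
}

#' Entry-wise damped update w - coeffs * g
#'
#' The elementary server update: each entry k of the increment `g` is scaled
#' by its own coefficient (the adaptive staleness weight) before being
#' subtracted from `w`.
#'
#' @param w,g Conformable `param_vector`s.
#' @param coeffs Scalar or per-entry numeric vector of coefficients.
#' @return A `param_vector` with `out[k] = w[k] - coeffs[k] * g[k]`.
#' @export
axpy <- function(w, g, coeffs = 1) {
  check_conformable(w, g)
  if (!(length(coeffs) %in% c(1L, length(w)))) {
    abort("coeffs must be scalar or one per entry")
  }
  new_param_vector(as.numeric(w) - coeffs * as.numeric(g), attr(w, "keys"))
}

#' @export
print.param_vector <- function(x, ...) {
  keys <- attr(x, "keys")
  cat(sprintf("<param_vector: %d entries, %d layers>\n", length(x), length(keys)))
  for (k in keys) {
    cat(sprintf("  %s [%s]\n", k$name, paste(k$dim, collapse = "x")))
  }
  invisible(x)
}

#' Tidy a param_vector into a tibble
#'
#' @param x A `param_vector`.
#' @param ... Unused.
#' @return Tibble with columns `layer`, `index` (within layer), `k` (global
#'   entry index), `value`.
#' @export
tidy.param_vector <- function(x, ...) {
  keys <- attr(x, "keys")
  lens <- vapply(keys, function(k) prod(k$dim), numeric(1))
  tibble::tibble(
    layer = rep(vapply(keys, `[[`, character(1), "name"), lens),
    index = unlist(lapply(lens, seq_len)),
    k = seq_along(x),
    value = as.numeric(x)
  )
}

#' Write / read a param_vector checkpoint
#'
#' All-text container: a header recording layer names, shapes and dtype,
#' then one value per line printed with 17 significant digits, which
#' round-trips IEEE doubles exactly.
#'
#' @param pv A `param_vector`.
#' @param path File path.
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   the restored `param_vector`.
#' @export
write_checkpoint <- function(pv, path) {
  stopifnot(inherits(pv, "param_vector"))
  keys <- attr(pv, "keys")
  header <- c(
    "# asyncfed checkpoint v1",
    "# dtype double",
    sprintf("# layer %s %s", vapply(keys, `[[`, character(1), "name"),
            vapply(keys, function(k) paste(k$dim, collapse = "x"), character(1)))
  )
  writeLines(c(header, sprintf("%.17g", as.numeric(pv))), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  layer_lines <- lines[hdr][grepl("^# layer ", lines[hdr])]
  keys <- lapply(layer_lines, function(l) {
    parts <- strsplit(sub("^# layer ", "", l), " ")[[1]]
    list(name = parts[1],
         dim = as.integer(strsplit(parts[2], "x")[[1]]))
  })
  new_param_vector(as.numeric(lines[!hdr]), keys)
}

#' Export a param_vector as CSV for debugging
#'
#' @param pv A `param_vector`.
#' @param path File path.
#' @export
write_param_csv <- function(pv, path) {
  utils::write.csv(tidy.param_vector(pv), path, row.names = FALSE)
  invisible(path)
}
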