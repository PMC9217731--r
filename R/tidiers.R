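# broom-style accessors and plots for fed_run objects.

#' @export
print.fed_run <- function(x, ...) {
  cat(sprintf("<fed_run: %s, %d devices, %d global epochs>\n",
              x$algo, x$n_devices, x$T))
  cat(sprintf("  uploads %d, downloads %d, drops %d\n",
              x$uploads, x$downloads, x$drops))
  fin <- utils::tail(x$metrics, 1)
  if (nrow(fin) && !is.na(fin$accuracy)) {
    cat(sprintf("  final test accuracy %.4f\n", fin$accuracy))
  }
  invisible(x)
}

#' Tidy a federated run into its per-epoch metrics
#'
#' @param x A `fed_run`.
#' @param ... Unused.
#' @return Tibble with one row per evaluated global epoch: `epoch`,
#'   `sim_time`, `accuracy`, `loss`, cumulative `uploads`, `downloads`,
#'   `drops`.
#' @export
tidy.fed_run <- function(x, ...) x$metrics

#' One-row summary of a federated run
#'
#' @param x A `fed_run`.
#' @param ... Unused.
#' @return Tibble with `algo`, `n_devices`, `updates`, final `accuracy`
#'   and `loss`, and communication totals.
#' @export
glance.fed_run <- function(x, ...) {
  fin <- utils::tail(x$metrics, 1)
  tibble::tibble(
    algo = x$algo,
    n_devices = x$n_devices,
    updates = sum(x$events$kind == "global_update"),
    accuracy = if (nrow(fin)) fin$accuracy else NA_real_,
    loss = if (nrow(fin)) fin$loss else NA_real_,
    uploads = x$uploads,
    downloads = x$downloads,
    drops = x$drops,
    seed = x$seed
  )
}

#' Plot test accuracy against global epochs
#'
#' @param object A `fed_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fed_run <- function(object, ...) {
  m <- dplyr::filter(object$metrics, !is.na(.data$accuracy))
  ggplot2::ggplot(m, ggplot2::aes(x = .data$epoch, y = .data$accuracy)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "global epoch", y = "test accuracy",
                  title = sprintf("%s (%d devices)", object$algo,
                                  object$n_devices)) +
    ggplot2::theme_minimal()
}

#' Convergence comparison plot across runs
#'
#' Accuracy against cumulative uploads, the communication-matched view in
#' which asynchronous and synchronous trainers are comparable.
#'
#' @param ... Named `fed_run` objects or a single named list of them.
#' @param x_axis `"epoch"` or `"uploads"`.
#' @return A ggplot.
#' @export
plot_convergence <- function(..., x_axis = c("uploads", "epoch")) {
  x_axis <- match.arg(x_axis)
  d <- compare_runs(...)
  d <- dplyr::filter(d, !is.na(.data$accuracy))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[x_axis]], y = .data$accuracy,
                                  colour = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = if (x_axis == "uploads") "cumulative uploads"
                      else "global epoch",
                  y = "test accuracy", colour = NULL) +
    ggplot2::theme_minimal()
}
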