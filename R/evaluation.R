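# Confusion-matrix metrics and run summaries.
#
# Conventions: the positive class is the depression label (1). Metrics
# are kept at full precision and reported on the percent scale;
# `format_metrics()` rounds half-up to two decimals the way results
# tables are usually printed. Undefined metrics (zero denominator) are NA,
# never silently 0.

#' Build a confusion matrix from labels
#'
#' @param truth True 0/1 labels.
#' @param estimate Predicted 0/1 labels.
#' @return A `confusion_matrix`: list with integer `TP`, `FP`, `FN`, `TN`.
#' @export
confusion_matrix <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate),
            all(truth %in% c(0, 1)), all(estimate %in% c(0, 1)))
  new_confusion_matrix(
    TP = sum(truth == 1 & estimate == 1),
    FP = sum(truth == 0 & estimate == 1),
    FN = sum(truth == 1 & estimate == 0),
    TN = sum(truth == 0 & estimate == 0)
  )
}

#' @rdname confusion_matrix
#' @param TP,FP,FN,TN Cell counts (all >= 0).
#' @export
new_confusion_matrix <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0, TP + FP + FN + TN > 0)
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 FN = as.integer(FN), TN = as.integer(TN)),
            class = "confusion_matrix")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Precision, recall, F-measure and accuracy (percent)
#'
#' precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F = 2PR/(P+R), accuracy = (TP+TN)/total; all on the 0-100 scale at
#' full precision. A zero denominator yields NA.
#'
#' @param cm A `confusion_matrix`.
#' @return One-row tibble with `precision`, `recall`, `f_measure`,
#'   `accuracy`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  p <- safe_ratio(cm$TP, cm$TP + cm$FP)
  r <- safe_ratio(cm$TP, cm$TP + cm$FN)
  f <- f_measure(100 * p, 100 * r) / 100
  acc <- (cm$TP + cm$TN) / (cm$TP + cm$FP + cm$FN + cm$TN)
  tibble::tibble(precision = 100 * p, recall = 100 * r,
                 f_measure = 100 * f, accuracy = 100 * acc)
}

#' F-measure from precision and recall
#'
#' Harmonic mean 2PR/(P+R), on whatever common scale P and R are given
#' (fractions or percent). NA if either is NA or both are zero.
#'
#' @param precision,recall Precision and recall.
#' @return F-measure on the same scale.
#' @export
f_measure <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | (precision + recall) == 0,
         NA_real_,
         2 * precision * recall / (precision + recall))
}

#' Round half-up to a fixed number of decimals
#'
#' Table-style display rounding (R's `round()` rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Format metrics the way results tables print them
#'
#' @param metrics One-row tibble from [classification_metrics()].
#' @return The tibble with values rounded half-up to 2 decimals.
#' @export
format_metrics <- function(metrics) {
  dplyr::mutate(metrics, dplyr::across(dplyr::everything(),
                                       ~ round_half_up(.x, 2)))
}

#' First global epoch reaching a target accuracy
#'
#' @param run A `fed_run` object, or its per-epoch metrics tibble (columns
#'   `epoch`, `accuracy`).
#' @param target Target accuracy on the 0-1 scale.
#' @return The first epoch index with accuracy >= target, or `NA` if
#'   never reached.
#' @export
epochs_to_accuracy <- function(run, target) {
  m <- if (inherits(run, "fed_run")) run$metrics else run
  stopifnot(all(c("epoch", "accuracy") %in% names(m)))
  hit <- which(!is.na(m$accuracy) & m$accuracy >= target)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(m$epoch[hit[1]])
}

#' Communication cost summary of a run
#'
#' Exact event counts: uploads (accepted pushes for the asynchronous
#' trainer; participant models per round for FedAvg), downloads (model
#' pulls), drops (gated-out push attempts), and applied global updates.
#'
#' @param run A `fed_run` object.
#' @return One-row tibble with `uploads`, `downloads`, `drops`, `updates`.
#' @export
communication_summary <- function(run) {
  stopifnot(inherits(run, "fed_run"))
  tibble::tibble(
    uploads = run$uploads,
    downloads = run$downloads,
    drops = run$drops,
    updates = sum(run$events$kind == "global_update")
  )
}

#' Combine runs into one comparison table
#'
#' @param ... Named `fed_run` objects (names label the runs), or a single
#'   named list of them.
#' @return Tibble with `run`, `algo`, and the per-epoch metrics of each
#'   run, ready for plotting or CSV export.
#' @export
compare_runs <- function(...) {
  runs <- list(...)
  if (length(runs) == 1 && !inherits(runs[[1]], "fed_run")) runs <- runs[[1]]
  if (is.null(names(runs)) || any(!nzchar(names(runs)))) {
    names(runs) <- vapply(runs, `[[`, character(1), "algo")
  }
  purrr::imap_dfr(runs, function(r, nm) {
    dplyr::mutate(r$metrics, run = nm, algo = r$algo, .before = 1)
  })
}
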