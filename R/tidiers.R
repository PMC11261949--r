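# broom-style tidiers for fitted models and metric objects.

#' Tidy an HRD model
#'
#' @param x An `hrd_model`.
#' @param ... Unused.
#' @return One row per feature: `feature`, `weight` (mean over CV folds,
#'   the reported weight vector), `weight_sd` (across folds), and
#'   `weight_refit` (from the final refit on all training data).
#' @export
tidy.hrd_model <- function(x, ...) {
  tibble::tibble(
    feature = x$feature_order,
    weight = unname(colMeans(x$cv_weights)),
    weight_sd = unname(apply(x$cv_weights, 2, stats::sd)),
    weight_refit = unname(x$weights)
  )
}

#' Glance at an HRD model
#'
#' @param x An `hrd_model`.
#' @param ... Unused.
#' @return A one-row tibble: tissue, assay, training size and class
#'   counts, selected regularization strength, and mean CV AUC.
#' @export
glance.hrd_model <- function(x, ...) {
  tibble::tibble(
    tissue = x$tissue, assay = x$assay,
    n_train = x$n_train,
    n_hrd = as.integer(x$class_counts[["HRD"]]),
    n_hrp = as.integer(x$class_counts[["HRP"]]),
    cost = x$cost,
    cv_auc = x$cv_auc,
    folds = x$folds
  )
}

#' Tidy / glance classification metrics
#'
#' @param x An `hrd_metrics` object from [hrd_evaluate()].
#' @param ... Unused.
#' @return `tidy()`: the confusion matrix in long form; `glance()`: a
#'   one-row tibble of AUC, sensitivity, precision, and F1.
#' @export
tidy.hrd_metrics <- function(x, ...) {
  as.data.frame(as.table(x$confusion)) |>
    tibble::as_tibble() |>
    dplyr::rename(n = "Freq")
}

#' @rdname tidy.hrd_metrics
#' @export
glance.hrd_metrics <- function(x, ...) {
  tibble::tibble(auc = x$auc, sensitivity = x$sensitivity,
                 precision = x$precision, f1 = x$f1, n = x$n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
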