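# Ground-truth labelling, feature standardization, the cross-validated
# linear support vector machine, Platt-style probability calibration, and
# classification metrics.

#' Ground-truth HRD labels from scar score and BRCA1/2 status
#'
#' A sample is labelled HRD when its genomic-instability (HRD scar) score
#' reaches the tissue threshold - at least 42 for breast, at least 63 for
#' ovarian - or when it harbours a germline/somatic BRCA1 or BRCA2
#' alteration (including promoter methylation where known).  All other
#' samples are HRP.  A missing scar score is only acceptable when
#' `brca_altered` is `TRUE` (the OR-rule already decides); a missing score
#' with `brca_altered = FALSE` is insufficient evidence and raises an error
#' rather than defaulting to HRP.
#'
#' @param hrd_score Numeric HRD scar score (sum of LOH/TAI/LST event
#'   counts), possibly `NA`.
#' @param brca_altered Logical BRCA1/2 alteration flag.
#' @param tissue `"breast"` or `"ovarian"` (scalar or vector).
#' @return Character vector of `"HRD"` / `"HRP"` labels.
#' @export
#' @examples
#' label_ground_truth(c(42, 41.99), FALSE, "breast")  # "HRD" "HRP"
label_ground_truth <- function(hrd_score, brca_altered, tissue) {
  n <- max(length(hrd_score), length(brca_altered), length(tissue))
  hrd_score <- rep_len(hrd_score, n)
  brca_altered <- rep_len(as.logical(brca_altered), n)
  tissue <- rep_len(as.character(tissue), n)
  stopifnot(all(tissue %in% c("breast", "ovarian")))
  if (any(is.na(brca_altered))) stop("brca_altered must be TRUE or FALSE")
  insufficient <- is.na(hrd_score) & !brca_altered
  if (any(insufficient)) {
    stop("missing HRD score without a BRCA1/2 alteration for ",
         sum(insufficient), " sample(s); cannot label")
  }
  threshold <- ifelse(tissue == "breast", 42, 63)
  ifelse(brca_altered | (!is.na(hrd_score) & hrd_score >= threshold),
         "HRD", "HRP")
}

#' Fit / apply z-score standardization
#'
#' `feature_scaler()` learns per-feature means and standard deviations from
#' a training feature table; `scale_features()` applies them (training
#' parameters only - never refit on test data).  A feature with zero
#' standard deviation falls back to sd 1 with a warning, so constant
#' features standardize to 0.
#'
#' @param features Feature tibble from [extract_features()] (or any data
#'   frame containing the six feature columns).
#' @return `feature_scaler()`: a list with `mean`, `sd`, `feature_order`;
#'   `scale_features()`: a numeric samples-by-features matrix.
#' @export
feature_scaler <- function(features) {
  x <- feature_matrix(features)
  stopifnot(nrow(x) >= 2)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  if (any(sdv == 0)) {
    warning("constant feature(s): ",
            paste(colnames(x)[sdv == 0], collapse = ", "),
            "; standard deviation set to 1")
    sdv[sdv == 0] <- 1
  }
  list(mean = mu, sd = sdv, feature_order = colnames(x))
}

#' @rdname feature_scaler
#' @param scaler A scaler from `feature_scaler()`.
#' @export
scale_features <- function(features, scaler) {
  x <- feature_matrix(features, scaler$feature_order)
  scale(x, center = scaler$mean, scale = scaler$sd)[, , drop = FALSE]
}

feature_matrix <- function(features, order = FEATURE_ORDER) {
  missing <- setdiff(order, names(features))
  if (length(missing)) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  }
  x <- as.matrix(as.data.frame(features)[, order, drop = FALSE])
  rownames(x) <- if ("sample_id" %in% names(features)) features$sample_id else
    as.character(seq_len(nrow(x)))
  x
}

# Linear SVM fit (hinge loss, L2 penalty) returning the decision function
# w.x + b oriented so that HRD scores positive.
fit_linear_svm <- function(x, y, cost) {
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  positive_class <- fit$levels[fit$labels[1]]
  if (positive_class != "HRD") {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}

make_stratified_folds <- function(y, k) {
  if (min(table(y)) < k) {
    stop("each class needs at least `folds` samples for stratified CV")
  }
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Train the HRD classifier
#'
#' Fits a linear-kernel support vector machine (hinge loss with L2
#' regularization) on z-score standardized features.  Stratified k-fold
#' cross-validation selects the regularization strength from `c_grid` by
#' mean held-out AUC; the per-fold weight vectors at the selected strength
#' are recorded (their average is the reported feature-weight vector), a
#' Platt-style logistic calibration is fitted on the out-of-fold decision
#' values, and the final decision function is refit on all training data.
#'
#' @param features Feature tibble from [extract_features()].
#' @param labels `"HRD"`/`"HRP"` labels: a named character vector (names =
#'   sample ids) or an unnamed vector aligned with `features` rows.
#' @param tissue `"breast"` or `"ovarian"` (metadata carried on the model).
#' @param assay `"WGS"` or `"WES"`; defaults to the feature table's assay.
#' @param folds Number of cross-validation folds (default 10).
#' @param c_grid Candidate regularization strengths.
#' @param seed Integer seed controlling fold assignment; the fit is fully
#'   deterministic given the seed.
#' @return An object of class `hrd_model`; see [predict.hrd_model()],
#'   [tidy.hrd_model()], [glance.hrd_model()].
#' @export
hrd_train <- function(features, labels, tissue = "breast", assay = NULL,
                      folds = 10, c_grid = c(0.01, 0.1, 1, 10, 100),
                      seed = 1) {
  if (is.null(assay)) {
    assay <- if ("assay" %in% names(features)) features$assay[1] else "WGS"
  }
  x_raw <- feature_matrix(features)
  y <- resolve_labels(labels, rownames(x_raw))
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  y <- factor(y, levels = c("HRP", "HRD"))
  stopifnot(nrow(x_raw) >= folds)

  fold <- with_seed(seed, make_stratified_folds(y, folds))
  cv <- lapply(c_grid, function(cost) {
    per_fold <- lapply(seq_len(folds), function(k) {
      tr <- fold != k
      scaler <- suppressWarnings(feature_scaler(as.data.frame(x_raw[tr, , drop = FALSE])))
      xs_tr <- scale_features(as.data.frame(x_raw[tr, , drop = FALSE]), scaler)
      xs_te <- scale_features(as.data.frame(x_raw[!tr, , drop = FALSE]), scaler)
      f <- fit_linear_svm(xs_tr, y[tr], cost)
      dv <- drop(xs_te %*% f$w) + f$b
      list(auc = auc_rank(dv, y[!tr] == "HRD"), dv = dv,
           idx = which(!tr), w = f$w)
    })
    list(mean_auc = mean(vapply(per_fold, `[[`, numeric(1), "auc")),
         per_fold = per_fold)
  })
  mean_aucs <- vapply(cv, `[[`, numeric(1), "mean_auc")
  best <- which.max(mean_aucs)
  sel <- cv[[best]]$per_fold

  cv_weights <- do.call(rbind, lapply(sel, `[[`, "w"))
  rownames(cv_weights) <- paste0("fold", seq_len(folds))
  oof_dv <- numeric(nrow(x_raw))
  for (f in sel) oof_dv[f$idx] <- f$dv
  calib <- suppressWarnings(
    stats::glm((y == "HRD") ~ oof_dv, family = stats::binomial())
  )
  calib_coef <- unname(stats::coef(calib))

  scaler <- feature_scaler(features)
  xs <- scale_features(features, scaler)
  final <- fit_linear_svm(xs, y, c_grid[best])

  structure(list(
    tissue = tissue, assay = assay,
    feature_order = FEATURE_ORDER,
    scaler = scaler,
    weights = final$w, bias = final$b,
    cv_weights = cv_weights,
    calib_intercept = calib_coef[1], calib_slope = calib_coef[2],
    cost = c_grid[best], c_grid = c_grid, cv_auc_grid = mean_aucs,
    cv_auc = mean_aucs[best],
    folds = folds, seed = seed,
    n_train = nrow(x_raw),
    class_counts = table(y)
  ), class = "hrd_model")
}

resolve_labels <- function(labels, sample_ids) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$label, labels$sample_id)
  }
  if (!is.null(names(labels)) && all(sample_ids %in% names(labels))) {
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    stop("labels must be named by sample id or aligned with the feature rows")
  }
  labels <- as.character(labels)
  stopifnot(all(labels %in% c("HRD", "HRP")))
  labels
}

#' Average cross-validation feature weights
#'
#' @param model An `hrd_model`.
#' @return Named numeric vector: the mean over folds of the per-fold SVM
#'   weights (the weight vector reported for interpretation).
#' @export
feature_weights <- function(model) {
  stats::setNames(colMeans(model$cv_weights), model$feature_order)
}

#' @export
print.hrd_model <- function(x, ...) {
  cat("<hrd_model> ", x$tissue, "/", x$assay, ", n = ", x$n_train,
      " (HRD ", x$class_counts[["HRD"]], ", HRP ", x$class_counts[["HRP"]],
      ")\n  cost = ", x$cost, ", mean ", x$folds, "-fold CV AUC = ",
      round(x$cv_auc, 3), "\n  mean CV weights:\n", sep = "")
  print(round(feature_weights(x), 3))
  invisible(x)
}

#' Predict HRD status
#'
#' Standardizes the new features with the model's training scaler, applies
#' the linear decision function, maps decision values to probabilities via
#' the fitted Platt calibration, and calls HRD for probabilities of at
#' least 0.50 (the threshold is inclusive).
#'
#' @param object An `hrd_model`.
#' @param features Feature tibble from [extract_features()].
#' @param threshold Probability call threshold (default 0.50, inclusive).
#' @param ... Unused.
#' @return Tibble with `sample_id`, `decision_value`, `probability`,
#'   `call`.
#' @export
predict.hrd_model <- function(object, features, threshold = 0.5, ...) {
  xs <- scale_features(features, object$scaler)
  dv <- unname(drop(xs %*% object$weights)) + object$bias
  prob <- stats::plogis(object$calib_intercept + object$calib_slope * dv)
  tibble::tibble(
    sample_id = rownames(xs),
    decision_value = unname(dv),
    probability = unname(prob),
    call = ifelse(prob >= threshold, "HRD", "HRP")
  )
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney formulation: ties in the score contribute half.
#'
#' @param scores Numeric predictions (higher = more HRD-like).
#' @param positive Logical vector, `TRUE` for truly HRD samples.
#' @return AUC in [0, 1]; `NA` with a warning when either class is absent.
#' @export
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one truth class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics against ground truth
#'
#' @param predictions Prediction tibble from [predict.hrd_model()].
#' @param truth `"HRD"`/`"HRP"` truth labels: named vector or tibble with
#'   `sample_id` and `label`.
#' @return List of class `hrd_metrics`: `auc`, `sensitivity`, `precision`,
#'   `f1`, `confusion` (2x2 table, truth in rows), `n`.  Ratios with zero
#'   denominators are reported as `NA`, not 0.
#' @export
hrd_evaluate <- function(predictions, truth) {
  y <- resolve_labels(truth, predictions$sample_id)
  pos <- y == "HRD"
  pred_pos <- predictions$call == "HRD"
  tp <- sum(pos & pred_pos); fn <- sum(pos & !pred_pos)
  fp <- sum(!pos & pred_pos); tn <- sum(!pos & !pred_pos)
  safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_ratio(tp, tp + fn)
  prec <- safe_ratio(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(prec) || sens + prec == 0) NA_real_ else
    2 * sens * prec / (sens + prec)
  auc <- auc_rank(predictions$probability, pos)
  confusion <- matrix(c(tp, fn, fp, tn), 2, 2, byrow = TRUE,
                      dimnames = list(truth = c("HRD", "HRP"),
                                      predicted = c("HRD", "HRP")))
  structure(list(auc = auc, sensitivity = sens, precision = prec, f1 = f1,
                 confusion = confusion, n = length(y)),
            class = "hrd_metrics")
}

#' @export
print.hrd_metrics <- function(x, ...) {
  cat("<hrd_metrics> n =", x$n, "\n")
  cat(sprintf("  AUC %.3f | sensitivity %.3f | precision %.3f | F1 %.3f\n",
              x$auc, x$sensitivity, x$precision, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Serialize / restore a trained model as JSON
#'
#' @param model An `hrd_model`.
#' @param path Output / input path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   restored `hrd_model`.
#' @export
write_model <- function(model, path) {
  doc <- list(
    format = "hrdsix-model", format_version = 1L,
    tissue = model$tissue, assay = model$assay,
    feature_order = model$feature_order,
    scaler_mean = as.list(model$scaler$mean),
    scaler_sd = as.list(model$scaler$sd),
    weights = model$weights, bias = model$bias,
    cv_weights = unname(apply(model$cv_weights, 1, identity, simplify = FALSE)),
    calib_intercept = model$calib_intercept,
    calib_slope = model$calib_slope,
    cost = model$cost, c_grid = model$c_grid,
    cv_auc_grid = model$cv_auc_grid, cv_auc = model$cv_auc,
    folds = model$folds, seed = model$seed, n_train = model$n_train,
    class_counts = as.list(model$class_counts)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "hrdsix-model")) stop("not an hrdsix model file")
  cw <- if (is.matrix(doc$cv_weights)) doc$cv_weights else
    do.call(rbind, doc$cv_weights)
  rownames(cw) <- paste0("fold", seq_len(nrow(cw)))
  colnames(cw) <- doc$feature_order
  structure(list(
    tissue = doc$tissue, assay = doc$assay,
    feature_order = doc$feature_order,
    scaler = list(mean = unlist(doc$scaler_mean),
                  sd = unlist(doc$scaler_sd),
                  feature_order = doc$feature_order),
    weights = stats::setNames(doc$weights, doc$feature_order),
    bias = doc$bias, cv_weights = cw,
    calib_intercept = doc$calib_intercept, calib_slope = doc$calib_slope,
    cost = doc$cost, c_grid = doc$c_grid, cv_auc_grid = doc$cv_auc_grid,
    cv_auc = doc$cv_auc, folds = doc$folds, seed = doc$seed,
    n_train = doc$n_train,
    class_counts = unlist(doc$class_counts)
  ), class = "hrd_model")
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}
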