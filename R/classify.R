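#' Fit a skewness-correcting normalization transform
#'
#' Electrogram powers and amplitudes are strongly right-skewed; features
#' whose training-sample skewness exceeds 1 in absolute value are
#' log-transformed (`log(x + 1e-12)`, applicable only to non-negative
#' features) and every feature is then centred and scaled to zero mean and
#' unit variance. Parameters are frozen from the training rows only, so
#' the transform can be applied unchanged to held-out data.
#'
#' @param table data.frame containing at least the columns in `features`.
#' @param features character vector of feature columns to normalize
#'   (default: the six electrogram features).
#' @return a `pv_normalization` object: per-feature `log_applied`,
#'   `center`, `scale`.
#' @export
fit_normalization <- function(table, features = feature_names) {
  if (nrow(table) < 2) stop("need at least 2 rows to fit a normalization")
  params <- lapply(features, function(f) {
    x <- table[[f]]
    if (is.null(x)) stop("feature column missing: ", f)
    if (any(!is.finite(x))) stop("non-finite values in feature: ", f)
    if (stats::sd(x) == 0) stop("zero-variance feature: ", f)
    log_applied <- FALSE
    if (abs(e1071::skewness(x)) > 1 && min(x) >= 0) {
      x <- log(x + 1e-12)
      log_applied <- TRUE
    }
    s <- stats::sd(x)
    if (s == 0) stop("zero-variance feature after log transform: ", f)
    list(log_applied = log_applied, center = mean(x), scale = s)
  })
  structure(stats::setNames(params, features), class = "pv_normalization")
}

#' Apply a fitted normalization to a feature table
#' @param norm a `pv_normalization` from [fit_normalization()].
#' @param table data.frame with the transform's feature columns.
#' @return data.frame with the listed features transformed in place.
#' @export
apply_normalization <- function(norm, table) {
  stopifnot(inherits(norm, "pv_normalization"))
  for (f in names(norm)) {
    p <- norm[[f]]
    x <- table[[f]]
    if (p$log_applied) x <- log(x + 1e-12)
    table[[f]] <- (x - p$center) / p$scale
  }
  table
}

pv_algorithms <- c("decision_tree", "lda", "svm", "knn")

default_hyperparameters <- function(algorithm) {
  switch(algorithm,
         decision_tree = list(max_depth = 4),
         lda = list(),
         svm = list(kernel = "linear", cost = 1),
         knn = list(k = 5),
         stop("unknown algorithm: ", algorithm))
}

#' Train a single-beat nearfield/farfield classifier
#'
#' Fits one of the four classifier families on a feature table. Beats
#' labelled `PV-NF` or `combined` form the nearfield-positive class,
#' `atrial-FF` the farfield class. The model embeds the normalization
#' fitted on its own training rows, so prediction needs only raw features.
#'
#' @param table training feature table (data.frame with the feature columns
#'   and a `label` column, or a logical `nearfield` column).
#' @param algorithm `"decision_tree"`, `"lda"`, `"svm"` or `"knn"`.
#' @param features feature subset to use (default: all six).
#' @param hyperparameters optional list overriding the defaults
#'   (`max_depth` for the tree; `kernel`, `cost` for the SVM; `k` for KNN).
#' @return a `pv_classifier` object.
#' @export
train_classifier <- function(table, algorithm = "svm",
                             features = feature_names,
                             hyperparameters = list()) {
  algorithm <- match.arg(algorithm, pv_algorithms)
  if (length(features) < 1) stop("need at least one feature")
  hp <- utils::modifyList(default_hyperparameters(algorithm), hyperparameters)
  y <- binary_labels(table)
  if (length(unique(y)) < 2)
    stop("training set contains a single class; both nearfield and ",
         "farfield beats are required")
  norm <- fit_normalization(table, features)
  xt <- apply_normalization(norm, table)[, features, drop = FALSE]
  yf <- factor(ifelse(y, "nearfield", "farfield"),
               levels = c("farfield", "nearfield"))
  fit <- switch(algorithm,
    decision_tree = rpart::rpart(
      y ~ ., data = cbind(xt, y = yf), method = "class",
      control = rpart::rpart.control(maxdepth = hp$max_depth, cp = 0,
                                     minsplit = 5, xval = 0)),
    lda = MASS::lda(x = xt, grouping = yf),
    svm = e1071::svm(x = as.matrix(xt), y = yf, kernel = hp$kernel,
                     cost = hp$cost, scale = FALSE),
    knn = list(x = as.matrix(xt), y = yf, k = hp$k))
  train_data <- cbind(table[, features, drop = FALSE],
                      data.frame(nearfield = y))
  structure(list(algorithm = algorithm, hyperparameters = hp, fit = fit,
                 normalization = norm, features = features,
                 training_data = train_data),
            class = "pv_classifier")
}

binary_labels <- function(table) {
  if (!is.null(table$nearfield)) return(as.logical(table$nearfield))
  if (is.null(table$label)) stop("table needs a 'label' or 'nearfield' column")
  is_nearfield_label(table$label)
}

#' Predict nearfield presence for feature rows
#'
#' Returns a hard label and a continuous score in which higher means more
#' nearfield: the signed decision value for SVM, the nearfield posterior
#' for LDA, and the nearfield class fraction for the tree and KNN.
#' Prediction is deterministic for a fitted model (the default odd KNN `k`
#' rules out voting ties).
#'
#' @param object a `pv_classifier`.
#' @param newdata data.frame with the model's feature columns.
#' @param ... unused.
#' @return data.frame with columns `label` (`"nearfield"`/`"farfield"`)
#'   and `score`.
#' @export
predict.pv_classifier <- function(object, newdata, ...) {
  miss <- setdiff(object$features, names(newdata))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  xt <- apply_normalization(object$normalization, newdata)[
    , object$features, drop = FALSE]
  score <- switch(object$algorithm,
    decision_tree = stats::predict(object$fit, xt, type = "prob")[, "nearfield"],
    lda = stats::predict(object$fit, xt)$posterior[, "nearfield"],
    svm = {
      p <- stats::predict(object$fit, as.matrix(xt), decision.values = TRUE)
      dv <- attr(p, "decision.values")[, 1]
      # e1071 orients the decision value toward the first class seen in
      # training; flip so that higher always means nearfield
      if (grepl("^nearfield", colnames(attr(p, "decision.values"))[1])) dv else -dv
    },
    knn = {
      pr <- class::knn(train = object$fit$x, test = as.matrix(xt),
                       cl = object$fit$y, k = object$fit$k,
                       prob = TRUE, use.all = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == "nearfield", p_win, 1 - p_win)
    })
  thr <- switch(object$algorithm, svm = 0, 0.5)
  data.frame(label = ifelse(score > thr, "nearfield", "farfield"),
             score = as.numeric(score), stringsAsFactors = FALSE)
}

#' Classify a single beat's feature vector
#' @param model a `pv_classifier`.
#' @param fv one-row data.frame from [extract_feature_vector()].
#' @return list with `label` and `score`.
#' @export
classify_beat <- function(model, fv) {
  p <- predict(model, fv)
  list(label = p$label[1], score = p$score[1])
}

#' @export
print.pv_classifier <- function(x, ...) {
  cat(sprintf("<pv_classifier %s on {%s}>\n", x$algorithm,
              paste(x$features, collapse = ", ")))
  invisible(x)
}

patient_folds <- function(patients, k, seed = NULL) {
  ids <- unique(patients)
  if (!is.null(seed)) {
    ids <- withr::with_seed(seed, sample(ids))
  } else ids <- sample(ids)
  fold_of <- rep(seq_len(k), length.out = length(ids))
  stats::setNames(fold_of, ids)[patients]
}

cv_accuracy <- function(table, algorithm, features, k, hyperparameters = list()) {
  folds <- patient_folds(table$patient_id, k)
  y <- binary_labels(table)
  correct <- 0L
  for (f in sort(unique(folds))) {
    tr <- table[folds != f, , drop = FALSE]
    te <- table[folds == f, , drop = FALSE]
    if (length(unique(binary_labels(tr))) < 2 || nrow(te) == 0) next
    m <- train_classifier(tr, algorithm, features, hyperparameters)
    p <- predict(m, te)
    correct <- correct + sum((p$label == "nearfield") == binary_labels(te))
  }
  100 * correct / nrow(table)
}

#' Greedy forward feature selection
#'
#' Starting from an empty set, repeatedly adds the candidate feature that
#' maximizes cross-validated overall accuracy (patient-grouped folds), and
#' stops when no addition improves accuracy by more than `stop_delta`
#' percentage points. Ties break to the candidate with the lower index in
#' `candidates`.
#'
#' @param table feature table with `label` and `patient_id` columns.
#' @param algorithm classifier family (see [train_classifier()]).
#' @param cv_folds number of cross-validation folds (default 4).
#' @param candidates candidate feature columns (default: the six features).
#' @param stop_delta minimum accuracy gain in percentage points to continue
#'   (default 0.5).
#' @param seed integer controlling the fold assignment.
#' @return list with `features` (ordered as selected) and `accuracy`
#'   (cross-validated accuracy after each step, percent).
#' @export
forward_select <- function(table, algorithm = "svm", cv_folds = 4,
                           candidates = feature_names, stop_delta = 0.5,
                           seed = 1L) {
  if (length(candidates) < 2) stop("need at least 2 candidate features")
  selected <- character(0)
  acc_path <- numeric(0)
  best_acc <- -Inf
  set.seed(seed)
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    accs <- vapply(remaining, function(f)
      cv_accuracy(table, algorithm, c(selected, f), cv_folds), numeric(1))
    # which.max returns the first maximum, i.e. the lowest-index candidate
    if (length(selected) > 0 && max(accs) - best_acc <= stop_delta) break
    selected <- c(selected, remaining[which.max(accs)])
    best_acc <- max(accs)
    acc_path <- c(acc_path, best_acc)
  }
  list(features = selected, accuracy = acc_path)
}

#' Metrics from confusion counts
#'
#' Nearfield is the positive class: sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), accuracy = (TP+TN)/n, in percent.
#'
#' @param tp,fn,fp,tn confusion counts.
#' @return list with the counts, `n`, and `accuracy`, `sensitivity`,
#'   `specificity` in percent (unrounded; [format_report()] rounds for
#'   display).
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  n <- tp + fn + fp + tn
  list(tp = tp, fn = fn, fp = fp, tn = tn, n = n,
       accuracy = 100 * (tp + tn) / n,
       sensitivity = 100 * tp / (tp + fn),
       specificity = 100 * tn / (tn + fp))
}

#' Empirical ROC curve and AUC with a bootstrap confidence interval
#'
#' The AUC is the rank statistic (probability that a random nearfield beat
#' scores above a random farfield beat, ties counted half), equal to the
#' trapezoidal area under the empirical ROC curve with tied scores
#' averaged. The CI is the percentile interval of the AUC over `n_boot`
#' resamples of beats, stratified by class so both classes survive every
#' resample.
#'
#' @param scores numeric scores, higher = more nearfield.
#' @param labels logical (TRUE = nearfield) or `"nearfield"`/`"farfield"`.
#' @param n_boot number of bootstrap resamples (default 1000, minimum 100).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the resampling.
#' @return list with `roc` (data.frame `fpr`, `tpr`, `threshold`), `auc`,
#'   `ci` (lower, upper), `level`, `n_boot`.
#' @export
bootstrap_roc <- function(scores, labels, n_boot = 1000, level = 0.95,
                          seed = 1L) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.character(labels) == "nearfield"
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2)
    stop("both classes are required to form a ROC curve")
  if (n_boot < 100) stop("n_boot must be at least 100")
  auc <- rank_auc(scores, labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[labels] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1)))
  pos <- which(labels); neg <- which(!labels)
  boot <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
    i <- c(sample(pos, length(pos), replace = TRUE),
           sample(neg, length(neg), replace = TRUE))
    rank_auc(scores[i], labels[i])
  }, numeric(1)))
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(boot, c(a, 1 - a), type = 6))
  # percentile intervals from a finite resample can exclude the point
  # estimate by a hair; widen so the interval always contains it
  ci[1] <- min(ci[1], auc); ci[2] <- max(ci[2], auc)
  list(roc = roc[, c("fpr", "tpr", "threshold")], auc = auc, ci = ci,
       level = level, n_boot = n_boot)
}

rank_auc <- function(scores, labels) {
  n_pos <- sum(labels); n_neg <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Patient-level holdout validation with cross-validation
#'
#' Patients — never beats — are the unit of splitting: a holdout fraction
#' of patients is set aside, the classifier family is cross-validated on
#' the remaining patients (patient-grouped folds), a final model is fitted
#' on all non-holdout beats, and the evaluation report is computed on the
#' holdout predictions. A pooled mode re-predicts every beat through the
#' cross-validation folds instead of using the holdout only; both modes
#' are labelled in the report.
#'
#' @param table feature table with `label` and `patient_id` (and optionally
#'   `vein`) columns.
#' @param algorithm classifier family (see [train_classifier()]).
#' @param features feature subset (default `c("p_hf", "v_max")`, the
#'   two-feature model).
#' @param scheme list: `cv_folds` (4), `holdout_fraction` (0.25),
#'   `split_unit` (`"patient"`), `seed`.
#' @param hyperparameters passed to [train_classifier()].
#' @param n_boot bootstrap resamples for the AUC CI.
#' @param predictions `"holdout"` (default) or `"pooled"`.
#' @return a `pv_report`: confusion counts and metrics, ROC + AUC with CI,
#'   per-vein accuracy, `cv_accuracy`, `n_beats`, `n_patients`, the fitted
#'   `model`, and the holdout patient ids.
#' @export
run_validation <- function(table, algorithm = "svm",
                           features = c("p_hf", "v_max"),
                           scheme = list(), hyperparameters = list(),
                           n_boot = 1000,
                           predictions = c("holdout", "pooled")) {
  predictions <- match.arg(predictions)
  sch <- utils::modifyList(list(cv_folds = 4, holdout_fraction = 0.25,
                                split_unit = "patient", seed = 1L), scheme)
  if (!identical(sch$split_unit, "patient"))
    stop("only patient-level splitting is supported")
  if (is.null(table$patient_id)) stop("every beat must carry a patient_id")
  patients <- unique(table$patient_id)
  n_hold <- max(1L, round(sch$holdout_fraction * length(patients)))
  hold_pat <- withr::with_seed(sch$seed, sample(patients, n_hold))
  in_hold <- table$patient_id %in% hold_pat
  train_tab <- table[!in_hold, , drop = FALSE]
  hold_tab <- table[in_hold, , drop = FALSE]
  stopifnot(!any(train_tab$patient_id %in% hold_tab$patient_id))
  set.seed(sch$seed + 1L)
  cv_acc <- cv_accuracy(train_tab, algorithm, features, sch$cv_folds,
                        hyperparameters)
  model <- train_classifier(train_tab, algorithm, features, hyperparameters)
  if (predictions == "holdout") {
    eval_tab <- hold_tab
    pred <- predict(model, hold_tab)
  } else {
    eval_tab <- train_tab
    pred <- pooled_cv_predictions(train_tab, algorithm, features,
                                  sch$cv_folds, hyperparameters,
                                  seed = sch$seed + 2L)
  }
  truth <- binary_labels(eval_tab)
  est <- pred$label == "nearfield"
  cm <- confusion_metrics(tp = sum(est & truth), fn = sum(!est & truth),
                          fp = sum(est & !truth), tn = sum(!est & !truth))
  roc <- bootstrap_roc(pred$score, truth, n_boot = n_boot,
                       seed = sch$seed + 3L)
  per_vein <- NULL
  if (!is.null(eval_tab$vein)) {
    per_vein <- do.call(rbind, lapply(split(seq_len(nrow(eval_tab)),
                                            eval_tab$vein), function(i)
      data.frame(n = length(i),
                 accuracy = 100 * mean(est[i] == truth[i]))))
    per_vein <- cbind(vein = rownames(per_vein), per_vein)
    rownames(per_vein) <- NULL
  }
  structure(list(
    predictions = predictions, algorithm = algorithm, features = features,
    confusion = cm, roc = roc$roc, auc = roc$auc, auc_ci = roc$ci,
    ci_level = roc$level, per_vein = per_vein, cv_accuracy = cv_acc,
    n_beats = nrow(eval_tab), n_patients = length(unique(eval_tab$patient_id)),
    holdout_patients = sort(hold_pat), scheme = sch, model = model),
    class = "pv_report")
}

pooled_cv_predictions <- function(table, algorithm, features, k,
                                  hyperparameters, seed) {
  folds <- withr::with_seed(seed,
                            patient_folds(table$patient_id, k))
  out <- data.frame(label = rep(NA_character_, nrow(table)),
                    score = NA_real_)
  for (f in sort(unique(folds))) {
    tr <- table[folds != f, , drop = FALSE]
    m <- train_classifier(tr, algorithm, features, hyperparameters)
    out[folds == f, ] <- predict(m, table[folds == f, , drop = FALSE])
  }
  out
}

#' @export
print.pv_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable evaluation report
#'
#' Percentages are rounded to one decimal for display.
#'
#' @param report a `pv_report` from [run_validation()].
#' @return character vector of report lines.
#' @export
format_report <- function(report) {
  cm <- report$confusion
  lines <- c(
    sprintf("Single-beat nearfield/farfield classification (%s on %s; %s predictions)",
            report$algorithm, paste(report$features, collapse = " + "),
            report$predictions),
    sprintf("  beats: %d from %d patients", report$n_beats, report$n_patients),
    sprintf("  confusion (nearfield positive): TP=%d FN=%d FP=%d TN=%d",
            cm$tp, cm$fn, cm$fp, cm$tn),
    sprintf("  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%",
            cm$accuracy, cm$sensitivity, cm$specificity),
    sprintf("  AUC %.3f (%g%% CI %.3f to %.3f)", report$auc,
            100 * report$ci_level, report$auc_ci[1], report$auc_ci[2]),
    sprintf("  cross-validated accuracy (training patients): %.1f%%",
            report$cv_accuracy))
  if (!is.null(report$per_vein))
    lines <- c(lines, "  per-vein accuracy:",
               sprintf("    %s: %.1f%% (n=%d)", report$per_vein$vein,
                       report$per_vein$accuracy, report$per_vein$n))
  lines
}

#' Serialize an evaluation report to JSON
#' @param report a `pv_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- report[c("predictions", "algorithm", "features", "confusion",
                  "auc", "ci_level", "cv_accuracy", "n_beats", "n_patients",
                  "holdout_patients")]
  out$auc_ci <- list(lower = report$auc_ci[1], upper = report$auc_ci[2])
  if (!is.null(report$per_vein)) out$per_vein <- report$per_vein
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
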