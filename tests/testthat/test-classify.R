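make_cloud_table <- function(n = 200, sep = 6, seed = 17, n_patients = 10) {
  set.seed(seed)
  half <- n / 2
  data.frame(
    p_hf = c(rnorm(half, sep), rnorm(half, 0)),
    v_max = c(rnorm(half, sep), rnorm(half, 0)),
    label = rep(c("PV-NF", "atrial-FF"), each = half),
    patient_id = sample(sprintf("p%02d", 1:n_patients), n, replace = TRUE),
    vein = sample(c("LSPV", "LIPV", "RSPV", "RIPV"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

test_that("normalization leaves a near-normal feature alone and standardizes it", {
  set.seed(18)
  tab <- data.frame(f = rnorm(1000, 5, 2))
  nt <- fit_normalization(tab, "f")
  expect_false(nt$f$log_applied)
  expect_equal(nt$f$center, 5, tolerance = 0.2)
  expect_equal(nt$f$scale, 2, tolerance = 0.2)
  z <- apply_normalization(nt, tab)$f
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
})

test_that("a log-normal feature is log-transformed and its skewness drops", {
  set.seed(19)
  tab <- data.frame(f = rlnorm(1000, 0, 1))
  nt <- fit_normalization(tab, "f")
  expect_true(nt$f$log_applied)
  z <- apply_normalization(nt, tab)$f
  expect_lt(abs(e1071::skewness(z)), abs(e1071::skewness(tab$f)))
})

test_that("degenerate normalization inputs are errors naming the feature", {
  expect_error(fit_normalization(data.frame(bad = rep(2, 50)), "bad"), "bad")
  expect_error(fit_normalization(data.frame(f = 1), "f"), "2 rows")
  expect_error(fit_normalization(data.frame(f = c(1, NA, 3)), "f"),
               "non-finite")
})

test_that("an SVM separates well-separated clouds near-perfectly", {
  tab <- make_cloud_table(n = 200, sep = 6)
  m <- train_classifier(tab, "svm", c("p_hf", "v_max"))
  p <- predict(m, tab)
  acc <- mean((p$label == "nearfield") == is_nearfield_label(tab$label))
  expect_gte(acc, 0.99)
})

test_that("single-class training sets and unknown algorithms are rejected", {
  tab <- make_cloud_table()
  expect_error(train_classifier(tab[tab$label == "PV-NF", ], "svm",
                                c("p_hf", "v_max")), "single class")
  expect_error(train_classifier(tab, "random_forest"), "arg")
})

test_that("KNN with k equal to the training size predicts the majority class", {
  tab <- make_cloud_table(n = 100)
  tab <- tab[c(1:40, 51:100), ]           # 40 nearfield, 50 farfield
  m <- train_classifier(tab, "knn", c("p_hf", "v_max"),
                        hyperparameters = list(k = nrow(tab)))
  p <- predict(m, tab)
  expect_true(all(p$label == "farfield"))
})

test_that("a 1-NN model recalls its own training rows", {
  tab <- make_cloud_table(n = 60, sep = 3)
  m <- train_classifier(tab, "knn", c("p_hf", "v_max"),
                        hyperparameters = list(k = 1))
  p <- predict(m, tab)
  expect_identical(p$label == "nearfield",
                   unname(is_nearfield_label(tab$label)))
})

test_that("classification is deterministic and requires the model features", {
  tab <- make_cloud_table()
  m <- train_classifier(tab, "svm", c("p_hf", "v_max"))
  fv <- tab[7, ]
  r1 <- classify_beat(m, fv)
  r2 <- classify_beat(m, fv)
  expect_identical(r1$score, r2$score)
  expect_error(predict(m, tab[, "p_hf", drop = FALSE]), "v_max")
})

test_that("forward selection finds the only informative feature first", {
  set.seed(20)
  n <- 240
  tab <- data.frame(
    p_hf = c(rnorm(n / 2, 4), rnorm(n / 2, 0)),
    p_lf = rnorm(n), p_hf_rel = rnorm(n), v_max = rnorm(n),
    label = rep(c("PV-NF", "atrial-FF"), each = n / 2),
    patient_id = sample(sprintf("p%02d", 1:12), n, replace = TRUE),
    stringsAsFactors = FALSE)
  fs <- forward_select(tab, "lda",
                       candidates = c("p_lf", "p_hf", "p_hf_rel", "v_max"),
                       seed = 3)
  expect_identical(fs$features[1], "p_hf")
  # oracle: exhaustive single-feature cross-validation ranks p_hf best
  set.seed(3)
  single <- vapply(c("p_lf", "p_hf", "p_hf_rel", "v_max"), function(f)
    pvnf:::cv_accuracy(tab, "lda", f, 4), numeric(1))
  expect_identical(names(which.max(single)), "p_hf")
})

test_that("forward selection stops early on pure noise near chance accuracy", {
  set.seed(21)
  n <- 400
  tab <- data.frame(
    a = rnorm(n), b = rnorm(n), c = rnorm(n),
    label = rep(c("PV-NF", "atrial-FF"), each = n / 2),
    patient_id = sample(sprintf("p%02d", 1:20), n, replace = TRUE),
    stringsAsFactors = FALSE)
  fs <- forward_select(tab, "lda", candidates = c("a", "b", "c"), seed = 4)
  expect_lte(length(fs$features), 2)
  expect_lt(abs(fs$accuracy[1] - 50), 8)
})

test_that("a duplicated informative feature is selected only once", {
  set.seed(22)
  n <- 240
  tab <- data.frame(
    a = c(rnorm(n / 2, 4), rnorm(n / 2, 0)),
    label = rep(c("PV-NF", "atrial-FF"), each = n / 2),
    patient_id = sample(sprintf("p%02d", 1:12), n, replace = TRUE),
    stringsAsFactors = FALSE)
  tab$a_copy <- tab$a
  # probing the duplicate makes LDA warn about collinearity; that probe is
  # exactly what the selector must reject
  fs <- suppressWarnings(
    forward_select(tab, "lda", candidates = c("a", "a_copy"), seed = 5))
  expect_identical(fs$features, "a")
})

test_that("confusion metrics satisfy their defining identities", {
  cm <- confusion_metrics(132, 40, 18, 145)
  expect_identical(cm$n, 335)
  expect_equal(cm$sensitivity, 100 * 132 / 172)
  expect_equal(cm$specificity, 100 * 145 / 163)
  expect_equal(cm$accuracy, 100 * 277 / 335)
})

test_that("perfectly separating scores give AUC 1 with a degenerate CI", {
  roc <- bootstrap_roc(c(1:10, 21:30), rep(c(FALSE, TRUE), each = 10),
                       n_boot = 200, seed = 6)
  expect_equal(roc$auc, 1)
  expect_equal(unname(roc$ci), c(1, 1))
})

test_that("scores independent of the labels give AUC near one half", {
  set.seed(23)
  roc <- bootstrap_roc(rnorm(2000), rep(c(TRUE, FALSE), 1000),
                       n_boot = 200, seed = 7)
  expect_lt(abs(roc$auc - 0.5), 0.03)
  expect_gte(roc$ci[1], roc$auc - 0.1)
  expect_lte(roc$ci[1], roc$auc)
  expect_gte(roc$ci[2], roc$auc)
})

test_that("the AUC is invariant under strictly increasing score transforms", {
  set.seed(24)
  s <- rnorm(200)
  y <- s + rnorm(200) > 0
  r1 <- bootstrap_roc(s, y, n_boot = 100, seed = 8)
  r2 <- bootstrap_roc(exp(s), y, n_boot = 100, seed = 8)
  expect_identical(r1$auc, r2$auc)
})

test_that("the rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(25)
  s <- round(rnorm(150), 1)               # induce ties
  y <- s + rnorm(150) > 0
  want <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                         quiet = TRUE, direction = "<")))
  expect_equal(pvnf:::rank_auc(s, y), want, tolerance = 1e-12)
})

test_that("patient-level validation never mixes holdout patients into training", {
  tab <- make_cloud_table(n = 300, sep = 2, n_patients = 20)
  rep <- run_validation(tab, "lda", c("p_hf", "v_max"),
                        scheme = list(seed = 9), n_boot = 100)
  train_pat <- setdiff(unique(tab$patient_id), rep$holdout_patients)
  eval_n <- sum(tab$patient_id %in% rep$holdout_patients)
  expect_identical(rep$n_beats, eval_n)
  expect_length(intersect(rep$holdout_patients, train_pat), 0)
  cm <- rep$confusion
  expect_identical(cm$tp + cm$fn + cm$fp + cm$tn, rep$n_beats)
  expect_equal(cm$accuracy, 100 * (cm$tp + cm$tn) / cm$n)
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_true(rep$auc_ci[1] <= rep$auc && rep$auc <= rep$auc_ci[2])
})

test_that("a perfectly separable problem yields a perfect holdout report", {
  tab <- make_cloud_table(n = 240, sep = 10, n_patients = 16)
  rep <- run_validation(tab, "svm", c("p_hf", "v_max"),
                        scheme = list(seed = 10), n_boot = 100)
  expect_equal(rep$confusion$accuracy, 100)
  expect_equal(rep$auc, 1)
})

test_that("pooled cross-validation predictions are labelled and complete", {
  tab <- make_cloud_table(n = 200, sep = 4, n_patients = 16)
  rep <- run_validation(tab, "lda", c("p_hf", "v_max"),
                        scheme = list(seed = 11), n_boot = 100,
                        predictions = "pooled")
  expect_identical(rep$predictions, "pooled")
  expect_identical(rep$n_beats,
                   sum(!tab$patient_id %in% rep$holdout_patients))
})

test_that("reports survive the JSON round trip", {
  tab <- make_cloud_table(n = 120, sep = 5, n_patients = 10)
  rep <- run_validation(tab, "svm", c("p_hf", "v_max"),
                        scheme = list(seed = 12), n_boot = 100)
  path <- file.path(tempdir(), "report.json")
  write_report_json(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$confusion$accuracy, rep$confusion$accuracy)
  expect_equal(back$auc, rep$auc)
  expect_identical(back$algorithm, "svm")
})
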