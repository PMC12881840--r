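cm3 <- function(...) {
  matrix(c(...), nrow = 3, byrow = TRUE,
         dimnames = list(true = net_origins(),
                         predicted = c("pancreas", "small_intestine",
                                       "uncertain")))
}
# Confusion matrices of the published evaluation at confidences 0.875 and
# 1.0 (internal leave-one-out) and 0.875 (external test set); used to pin
# down the package's metric conventions.
cm_internal_0875 <- cm3(17, 5, 18,  2, 47, 2,  3, 0, 5)
cm_internal_10   <- cm3(7, 5, 28,   0, 47, 4,  1, 0, 7)
cm_external_0875 <- cm3(3, 0, 6,    1, 10, 3,  0, 0, 3)

test_that("class_metrics reproduces the published derived percentages", {
  si_10 <- class_metrics(cm_internal_10, "small_intestine")
  expect_equal(si_10$sensitivity, 47 / 51)   # 92.2%
  expect_equal(si_10$ppv, 47 / 52)           # 90.4%
  expect_equal(si_10$specificity, 43 / 48)   # 89.6%

  pa_0875 <- class_metrics(cm_internal_0875, "pancreas")
  expect_equal(pa_0875$sensitivity, 17 / 40) # 42.5%
  expect_equal(pa_0875$specificity, 54 / 59) # 91.5%
  expect_equal(pa_0875$ppv, 17 / 22)         # 77.3%

  pa_10 <- class_metrics(cm_internal_10, "pancreas")
  expect_equal(pa_10$sensitivity, 7 / 40)    # 17.5%
  expect_equal(pa_10$specificity, 58 / 59)   # 98.3%
  expect_equal(pa_10$ppv, 7 / 8)             # 87.5%

  si_ext <- class_metrics(cm_external_0875, "small_intestine")
  expect_equal(si_ext$sensitivity, 10 / 14)  # 71.4%
  expect_equal(si_ext$specificity, 1.0)      # 100%
  expect_equal(si_ext$ppv, 1.0)              # 100%

  pa_ext <- class_metrics(cm_external_0875, "pancreas")
  expect_equal(pa_ext$sensitivity, 3 / 9)    # 33.3%
  expect_equal(pa_ext$specificity, 16 / 17)  # 94.1%
})

test_that("class_metrics handles perfect and degenerate matrices", {
  perfect <- cm3(10, 0, 0,  0, 12, 0,  0, 0, 3)
  for (k in c("pancreas", "small_intestine")) {
    m <- class_metrics(perfect, k)
    expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv")]),
                 c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
    expect_length(m$undefined, 0)
  }
  # no true pancreas cases and nothing predicted pancreas: sensitivity and
  # PPV undefined, flagged rather than NaN
  none <- cm3(0, 0, 0,  0, 5, 0,  0, 0, 2)
  m <- class_metrics(none, "pancreas")
  expect_true(is.na(m$ppv))
  expect_true("ppv" %in% m$undefined)
  expect_true(is.na(m$sensitivity))
})

test_that("confusion_matrix3 conserves the cohort composition", {
  set.seed(9)
  true <- sample(net_origins(), 50, replace = TRUE)
  pred <- sample(c("pancreas", "small_intestine", "uncertain"), 50,
                 replace = TRUE)
  m <- confusion_matrix3(true, pred)
  expect_equal(unname(rowSums(m)),
               unname(as.vector(table(factor(true, net_origins())))))
  expect_equal(sum(m), 50)
})

test_that("leave-one-out runs on a 2+2+1 micro-cohort", {
  sc <- simulate_cohort(simulation_config(2, 2, 1, patches_per_patient = 20,
                                          dim = 3, delta = 8, seed = 4))
  res <- suppressWarnings(
    loo_evaluate(sc$embeddings, sc$manifest, classifier_config("svm_linear"),
                 confidence = 1.0, seed = 4))
  expect_equal(nrow(res$predictions), 5)
  expect_equal(sum(res$confusion), 5)
  expect_length(res$thresholds, 5)
})

test_that("confidence 0 forces an all-zero uncertain column", {
  sc <- simulate_cohort(simulation_config(3, 3, 2, patches_per_patient = 20,
                                          dim = 3, delta = 8, seed = 6))
  res <- loo_evaluate(sc$embeddings, sc$manifest,
                      classifier_config("svm_linear"), confidence = 0,
                      seed = 6)
  expect_equal(unname(res$confusion[, "uncertain"]), c(0, 0, 0))
  # binary classes perfectly separated at this separation
  expect_equal(res$confusion["pancreas", "pancreas"], 3L, ignore_attr = TRUE)
  expect_equal(res$confusion["small_intestine", "small_intestine"], 3L,
               ignore_attr = TRUE)
})

test_that("external evaluation conserves composition and rejects overlap", {
  train <- simulate_cohort(simulation_config(5, 5, 3, patches_per_patient = 20,
                                             dim = 3, delta = 8, seed = 7))
  test <- simulate_cohort(simulation_config(3, 4, 2, patches_per_patient = 20,
                                            dim = 3, delta = 8,
                                            sigma_patch = 1.5, seed = 8))
  # make test patient ids disjoint
  for (tbl in list(test$manifest, test$embeddings))
    tbl[, patient_id := paste0("ext_", patient_id)]
  res <- suppressWarnings(
    external_evaluate(train$embeddings, train$manifest, test$embeddings,
                      test$manifest, classifier_config("svm_linear"),
                      confidence = 0.875, seed = 7))
  expect_equal(unname(rowSums(res$confusion)), c(3, 4, 2))

  # identical cohorts must be rejected
  expect_error(
    external_evaluate(train$embeddings, train$manifest, train$embeddings,
                      train$manifest, classifier_config("svm_linear")),
    "share patient")

  # empty test cohort: empty matrix, no error
  empty_emb <- test$embeddings[0, ]
  empty_man <- test$manifest[0, ]
  res0 <- suppressWarnings(
    external_evaluate(train$embeddings, train$manifest, empty_emb, empty_man,
                      classifier_config("svm_linear"), confidence = 0.875,
                      seed = 7))
  expect_equal(sum(res0$confusion), 0)
})

test_that("binary accuracy: patient level benefits from aggregation", {
  sc <- simulate_cohort(simulation_config(5, 5, 0, patches_per_patient = 30,
                                          dim = 4, delta = 3, sigma_patch = 1.5,
                                          seed = 10))
  res <- loo_binary_evaluate(sc$embeddings, sc$manifest,
                             classifier_config("svm_linear"))
  patch_acc <- binary_accuracy(res, "patch")
  patient_acc <- binary_accuracy(res, "patient")
  expect_gte(patient_acc, patch_acc)   # majority vote aggregation gain
  expect_lt(patch_acc, 1)              # noise makes patches imperfect here

  # trivial accuracy cases
  fake <- list(patient_predictions = data.table::data.table(
    patient_id = c("a", "b"), true_origin = c("pancreas", "pancreas"),
    predicted = c("pancreas", "small_intestine")))
  expect_equal(binary_accuracy(fake, "patient"), 0.5)
})

test_that("leave-one-out is deterministic given seeds", {
  sc <- simulate_cohort(simulation_config(3, 3, 2, patches_per_patient = 15,
                                          dim = 3, delta = 6, seed = 12))
  r1 <- suppressWarnings(loo_evaluate(sc$embeddings, sc$manifest,
                                      classifier_config("svm_linear"),
                                      0.5, seed = 12))
  r2 <- suppressWarnings(loo_evaluate(sc$embeddings, sc$manifest,
                                      classifier_config("svm_linear"),
                                      0.5, seed = 12))
  expect_identical(as.data.frame(r1$predictions), as.data.frame(r2$predictions))
})
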