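# Reference decision values below were computed once with scikit-learn 1.9
# (SVC(C = 1, gamma = "auto") and LogisticRegression() defaults) on the same
# deterministic dataset this test regenerates, and frozen. They are the
# independent oracle for the package's own solvers.
make_oracle_data <- function() {
  set.seed(42)
  n <- 60; d <- 5
  X <- rbind(matrix(rnorm(n * d, -0.8, 1), n), matrix(rnorm(n * d, 0.8, 1), n))
  y <- c(rep(-1, n), rep(1, n))
  set.seed(7)
  Xt <- matrix(rnorm(20 * d, 0, 1.5), 20)
  list(X = X, y = y, Xt = Xt, d = d)
}

test_that("SVM and logistic solvers reproduce the reference decision values", {
  dat <- make_oracle_data()
  cases <- list(
    list(rbf = TRUE, expected = c(0.641370, -0.430301, 0.727097, -0.996114,
                                  0.131067), tol = 5e-3),
    list(rbf = FALSE, expected = c(8.720185, -2.346404, 0.814097, -3.533177,
                                   -1.162626), tol = 1e-2))
  for (cs in cases) {
    fit <- netorigin:::.svm_smo_fit(dat$X, dat$y, 1.0, 1 / dat$d, cs$rbf,
                                    tol = 1e-6)
    dv <- netorigin:::.svm_decision_values(dat$X, fit$coef, fit$rho, dat$Xt,
                                           1 / dat$d, cs$rbf)
    expect_equal(dv[1:5], cs$expected, tolerance = cs$tol,
                 ignore_attr = TRUE)
  }
  lr <- netorigin:::.fit_logreg(dat$X, dat$y, 1.0, 100)
  dv <- drop(dat$Xt %*% lr$w + lr$b)
  expect_equal(dv[1:5], c(10.197966, -2.486803, 1.410231, -4.447177,
                          -1.249357),
               tolerance = 2e-2, ignore_attr = TRUE)
})

test_that("training on a separable cohort reaches accuracy 1 for all models", {
  sc <- make_separable_cohort(seed = 21, delta = 10)
  origin_of <- setNames(manifest_patients(sc$manifest)$origin,
                        manifest_patients(sc$manifest)$patient_id)
  for (kind in c("svm_linear", "svm_rbf", "logreg")) {
    scorer <- train_patch_classifier(sc$embeddings, sc$manifest,
                                     classifier_config(kind))
    sp <- score_patches(scorer, sc$embeddings)
    expect_equal(mean(sp$predicted_label == origin_of[sp$patient_id]), 1.0,
                 info = kind)
  }
})

test_that("flipping the class labels negates linear-SVM scores", {
  sc <- make_separable_cohort(seed = 8, delta = 4)
  m_flip <- data.table::copy(as.data.table(sc$manifest))
  m_flip$origin <- ifelse(m_flip$origin == "pancreas", "small_intestine",
                          "pancreas")
  cfg <- classifier_config("svm_linear", svm_tol = 1e-8)
  s1 <- train_patch_classifier(sc$embeddings, sc$manifest, cfg)
  s2 <- train_patch_classifier(sc$embeddings, as_manifest(m_flip), cfg)
  v1 <- signed_scores(s1, embedding_matrix(sc$embeddings))
  v2 <- signed_scores(s2, embedding_matrix(sc$embeddings))
  expect_lt(max(abs(v1 + v2)), 1e-6)
})

test_that("margin and symmetry properties hold on the fitted toy model", {
  sc <- make_separable_cohort(seed = 13, delta = 10)
  scorer <- train_patch_classifier(sc$embeddings, sc$manifest,
                                   classifier_config("svm_linear"))
  # free support vectors (0 < alpha < C) sit on the margin: |score| = 1
  free <- abs(scorer$fit$coef) < 1 - 1e-8
  expect_true(any(free))
  sv_scores <- signed_scores(scorer, scorer$fit$sv[free, , drop = FALSE])
  expect_equal(abs(sv_scores), rep(1, sum(free)), tolerance = 1e-3,
               ignore_attr = TRUE)

  # exactly symmetric classes: the centroid midpoint scores ~0
  set.seed(31)
  Xp <- matrix(rnorm(40 * 3, 2, 1), 40)
  X <- rbind(Xp, -Xp)
  prov <- data.frame(patient_id = rep(c("a", "b"), each = 40),
                     specimen_id = "s", slide_id = c("sa", "sb")[rep(1:2, each = 40)],
                     x = 0L, y = 0L, size_px = 64L)
  prov$specimen_id <- paste0(prov$patient_id, "_s")
  prov$slide_id <- paste0(prov$patient_id, "_sl")
  emb <- as_embeddings(prov, X)
  man <- as_manifest(data.frame(patient_id = c("a", "b"),
                                specimen_id = c("a_s", "b_s"),
                                slide_id = c("a_sl", "b_sl"),
                                origin = c("small_intestine", "pancreas"),
                                specimen_kind = "resection"))
  sym <- train_patch_classifier(emb, man, classifier_config("svm_linear"))
  expect_lt(abs(signed_scores(sym, matrix(0, 1, 3))), 0.05)

  # scoring is deterministic
  v <- signed_scores(scorer, embedding_matrix(sc$embeddings))
  expect_identical(v, signed_scores(scorer, embedding_matrix(sc$embeddings)))
})

test_that("single-class input and dimension mismatches are rejected", {
  sc <- make_separable_cohort(seed = 5)
  pats <- manifest_patients(sc$manifest)
  panc <- pats$patient_id[pats$origin == "pancreas"]
  expect_error(train_patch_classifier(sc$embeddings, sc$manifest,
                                      train_patients = panc),
               "single class")
  scorer <- train_patch_classifier(sc$embeddings, sc$manifest)
  expect_error(signed_scores(scorer, matrix(0, 2, 7)), "dimension")

  # training is restricted to binary-origin patients
  sc2 <- simulate_cohort(simulation_config(2, 2, 1, patches_per_patient = 5,
                                           dim = 3, seed = 2))
  ids <- manifest_patients(sc2$manifest)$patient_id
  expect_error(train_patch_classifier(sc2$embeddings, sc2$manifest,
                                      train_patients = ids),
               "other-origin")
})

test_that("majority vote follows votes, then summed-score tie-break", {
  mk <- function(scores) {
    data.table::data.table(
      patient_id = "p", specimen_id = "s", slide_id = "sl",
      x = 0L, y = 0L, size_px = 64L, signed_score = scores,
      predicted_label = ifelse(scores > 0, "small_intestine", "pancreas"))
  }
  # 60/40 vote
  expect_equal(majority_vote(mk(c(rep(1, 60), rep(-1, 40)))),
               "small_intestine")
  # 50/50 vote, summed score positive
  expect_equal(majority_vote(mk(c(rep(2.1, 50), rep(-2, 50)))),
               "small_intestine")
  # single patch decides
  expect_equal(majority_vote(mk(-0.1)), "pancreas")
  # exact zero sum falls back to pancreas with a message
  expect_message(out <- majority_vote(mk(c(1, -1))), "defaulting")
  expect_equal(out, "pancreas")
  expect_error(majority_vote(mk(numeric(0))), "empty")
})

test_that("vote agrees with the shared sign when all patches agree", {
  set.seed(17)
  for (rep in 1:5) {
    s <- abs(rnorm(21)) * sample(c(-1, 1), 1)
    tab <- data.table::data.table(
      patient_id = "p", specimen_id = "s", slide_id = "sl", x = 0L, y = 0L,
      size_px = 64L, signed_score = s,
      predicted_label = ifelse(s > 0, "small_intestine", "pancreas"))
    expect_equal(majority_vote(tab),
                 if (s[1] > 0) "small_intestine" else "pancreas")
  }
})
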