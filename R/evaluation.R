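#' Train/calibration split protocol
#'
#' 60% of the pancreas/small-intestine patients train the patch classifier;
#' the remaining 40% plus all other-origin patients calibrate the abstention
#' thresholds. The split is stratified by origin and deterministic given the
#' seed.
#'
#' @param train_fraction Fraction of binary-origin patients used for
#'   classifier training (default 0.60).
#' @param seed Integer seed for the shuffle.
#' @return A `split_protocol` list.
#' @export
split_protocol <- function(train_fraction = 0.6, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 stratified = TRUE),
            class = "split_protocol")
}

# Stratified split of binary-origin patients into train / calibration ids.
# Both classes always reach the training part; with >= 2 patients per class
# both parts are non-empty per class, with a single patient the calibration
# part of that class is empty (micro-cohorts stay runnable).
.split_binary <- function(pats, protocol) {
  out <- list(train = character(0), calibration = character(0))
  for (org in .binary_origins()) {
    ids <- sort(pats$patient_id[pats$origin == org])
    if (length(ids) < 1)
      stop("no patient of origin '", org, "' available for the split")
    perm <- .with_seed(protocol$seed + match(org, .binary_origins()),
                       sample(ids))
    n_tr <- round(protocol$train_fraction * length(ids))
    n_tr <- max(1L, min(max(length(ids) - 1L, 1L), n_tr))
    out$train <- c(out$train, perm[seq_len(n_tr)])
    out$calibration <- c(out$calibration, perm[-seq_len(n_tr)])
  }
  lapply(out, sort)
}

#' 3x3 confusion matrix (true origin x predicted origin)
#'
#' Rows are the true origins (pancreas, small_intestine, other); columns the
#' pipeline outputs (pancreas, small_intestine, uncertain).
#'
#' @param true_origin Character vector of true origins.
#' @param predicted Character vector of predictions (may include
#'   `"uncertain"`).
#' @return 3x3 integer matrix with dimnames.
#' @export
confusion_matrix3 <- function(true_origin, predicted) {
  stopifnot(length(true_origin) == length(predicted))
  m <- table(factor(true_origin, levels = net_origins()),
             factor(predicted, levels = c("pancreas", "small_intestine",
                                          "uncertain")))
  m <- matrix(as.integer(m), nrow = 3, dimnames = list(
    true = net_origins(),
    predicted = c("pancreas", "small_intestine", "uncertain")))
  m
}

#' Per-class sensitivity, specificity, PPV and NPV
#'
#' Computes the package's frozen metric conventions for one of the two
#' modelled classes on a 3x3 confusion matrix. Abstentions ("uncertain")
#' count against sensitivity (an abstained case of class k is not detected)
#' and as correct rejections for specificity (a non-k case labelled uncertain
#' is not misassigned to k):
#'
#' * sensitivity = m\[k, k\] / (row total of k)
#' * specificity = 1 - (sum of column k off the k row) / (total of non-k rows)
#' * PPV = m\[k, k\] / (column total of k)
#' * NPV = sum over non-k rows of (row total - m\[row, k\]) /
#'   (grand total - column total of k)
#'
#' A metric with a zero denominator is reported as `NA` and named in the
#' `undefined` field rather than propagating NaN.
#'
#' @param m 3x3 matrix from [confusion_matrix3()].
#' @param class `"pancreas"` or `"small_intestine"`.
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv`, and
#'   `undefined` (character vector of metric names with zero denominators).
#' @export
class_metrics <- function(m, class = c("pancreas", "small_intestine")) {
  class <- match.arg(class)
  stopifnot(all(dim(m) == c(3, 3)), all(m >= 0))
  k <- match(class, net_origins())
  row_tot <- rowSums(m); col_tot <- colSums(m); total <- sum(m)
  not_k <- setdiff(1:3, k)

  safe_div <- function(num, den) if (den == 0) NA_real_ else unname(num / den)
  out <- list(
    sensitivity = safe_div(m[k, k], row_tot[k]),
    specificity = if (sum(row_tot[not_k]) == 0) NA_real_ else
      unname(1 - sum(m[not_k, k]) / sum(row_tot[not_k])),
    ppv = safe_div(m[k, k], col_tot[k]),
    npv = safe_div(sum(row_tot[not_k] - m[not_k, k]), total - col_tot[k])
  )
  out$undefined <- names(out)[vapply(out[1:4], is.na, logical(1))]
  out
}

.fold_calibration <- function(scorer, emb, pats, cal_binary, cal_other) {
  sums_of <- function(ids) {
    if (!length(ids)) return(numeric(0))
    sub <- emb[emb$patient_id %in% ids, ]
    ps <- patient_sums(score_patches(scorer, sub))
    ps$sum_signed[match(ids, ps$patient_id)]
  }
  origin_of <- setNames(pats$origin, pats$patient_id)
  calibration_set(
    pancreas_sums = sums_of(cal_binary[origin_of[cal_binary] == "pancreas"]),
    si_sums = sums_of(cal_binary[origin_of[cal_binary] == "small_intestine"]),
    other_sums = sums_of(cal_other))
}

#' Leave-one-out evaluation of the full two-step pipeline
#'
#' For each held-out patient, the remaining pancreas/small-intestine patients
#' are re-split 60/40 with a fold-specific deterministic seed
#' (`seed + fold index`), the patch classifier is retrained on the 60% part,
#' the abstention thresholds are recalibrated on the 40% part plus the
#' remaining other-origin patients (`i = round(confidence * o_fold)`), and
#' the held-out patient is scored, summed, and classified with abstention.
#'
#' @param emb Cohort `net_embeddings`.
#' @param manifest Cohort `net_manifest`.
#' @param config A [classifier_config()].
#' @param confidence Confidence parameter in `[0, 1]`.
#' @param seed Base seed for the fold splits.
#' @param contain_zero Passed to [determine_thresholds()].
#' @return list with `predictions` (data.table: patient_id, true_origin,
#'   sum_signed, n_patches, predicted), `confusion` (3x3 matrix), and
#'   `thresholds` (per-fold `threshold_pair`s).
#' @export
loo_evaluate <- function(emb, manifest, config = classifier_config(),
                         confidence = 0.875, seed = 1L, contain_zero = TRUE) {
  sweep <- loo_confidence_sweep(emb, manifest, config, confidence, seed,
                                contain_zero)
  list(predictions = sweep$predictions[, !"confidence"],
       confusion = sweep$confusion[[1]],
       thresholds = sweep$thresholds[[1]])
}

# One leave-one-out pass: per fold, the 60/40 re-split, the retrained scorer,
# the calibration set on the remaining patients, and the held-out summed
# score. Fold-level work is independent of the confidence parameter, so a
# sweep over confidences reuses it.
.loo_folds <- function(emb, manifest, config, seed) {
  emb <- as.data.table(emb)
  pats <- manifest_patients(manifest)
  pats <- pats[pats$patient_id %in% unique(emb$patient_id), ]
  if (sum(pats$origin == "pancreas") < 2 ||
      sum(pats$origin == "small_intestine") < 2)
    stop("leave-one-out needs at least 2 patients per binary class")

  all_ids <- sort(pats$patient_id)
  origin_of <- setNames(pats$origin, pats$patient_id)
  lapply(seq_along(all_ids), function(f) {
    held <- all_ids[f]
    rest <- setdiff(all_ids, held)
    rest_binary <- rest[origin_of[rest] %in% .binary_origins()]
    rest_other <- rest[origin_of[rest] == "other"]

    protocol <- split_protocol(seed = seed + f)
    split <- .split_binary(pats[pats$patient_id %in% rest_binary, ], protocol)
    scorer <- train_patch_classifier(
      emb, manifest, config, train_patients = split$train)
    stopifnot(!held %in% scorer$train_patients)  # fold hygiene

    cal <- .fold_calibration(scorer, emb, pats, split$calibration, rest_other)
    held_sum <- patient_sums(
      score_patches(scorer, emb[emb$patient_id == held, ]))
    list(patient_id = held, true_origin = origin_of[[held]],
         sum_signed = held_sum$sum_signed, n_patches = held_sum$n_patches,
         o_fold = length(rest_other), cal = cal)
  })
}

#' Leave-one-out evaluation across a sweep of confidence levels
#'
#' Identical protocol to [loo_evaluate()], but the per-fold training and
#' scoring (which do not depend on the confidence parameter) are performed
#' once and the abstention thresholds recomputed per confidence level, making
#' a full confidence sweep cost one leave-one-out pass.
#'
#' @inheritParams loo_evaluate
#' @param confidences Numeric vector of confidence parameters in `[0, 1]`.
#' @return list with `predictions` (long data.table with a `confidence`
#'   column), `confusion` (named list of 3x3 matrices, one per confidence),
#'   and `thresholds` (list per confidence of per-fold `threshold_pair`s).
#' @export
loo_confidence_sweep <- function(emb, manifest, config = classifier_config(),
                                 confidences = 0.875, seed = 1L,
                                 contain_zero = TRUE) {
  stopifnot(all(confidences >= 0), all(confidences <= 1))
  folds <- .loo_folds(emb, manifest, config, seed)
  preds <- list(); confusion <- list(); thresholds <- list()
  for (conf in confidences) {
    key <- format(conf)
    fold_preds <- lapply(folds, function(fd) {
      thr <- determine_thresholds(fd$cal,
                                  as.integer(round(conf * fd$o_fold)),
                                  contain_zero)
      list(thr = thr,
           row = data.table(patient_id = fd$patient_id,
                            true_origin = fd$true_origin,
                            sum_signed = fd$sum_signed,
                            n_patches = fd$n_patches,
                            predicted = classify_with_abstention(
                              fd$sum_signed, thr),
                            confidence = conf))
    })
    p <- data.table::rbindlist(lapply(fold_preds, `[[`, "row"))
    preds[[key]] <- p
    confusion[[key]] <- confusion_matrix3(p$true_origin, p$predicted)
    thresholds[[key]] <- lapply(fold_preds, `[[`, "thr")
  }
  list(predictions = data.table::rbindlist(preds),
       confusion = confusion, thresholds = thresholds)
}

#' Evaluate a fixed pipeline on an external cohort
#'
#' The full training cohort is split 60/40 once, the classifier trained and
#' the thresholds calibrated on it (all training other-origin patients enter
#' the calibration set), and the fixed model and thresholds are applied to
#' every patient of the disjoint test cohort.
#'
#' @param train_emb,train_manifest Training cohort.
#' @param test_emb,test_manifest Test cohort (disjoint patients; may be
#'   empty).
#' @param config A [classifier_config()].
#' @param confidence Confidence parameter in `[0, 1]`.
#' @param seed Seed for the single training split.
#' @param contain_zero Passed to [determine_thresholds()].
#' @return list with `predictions`, `confusion`, `threshold`.
#' @export
external_evaluate <- function(train_emb, train_manifest, test_emb,
                              test_manifest, config = classifier_config(),
                              confidence = 0.875, seed = 1L,
                              contain_zero = TRUE) {
  stopifnot(confidence >= 0, confidence <= 1)
  train_emb <- as.data.table(train_emb)
  test_emb <- as.data.table(test_emb)
  pats <- manifest_patients(train_manifest)
  pats <- pats[pats$patient_id %in% unique(train_emb$patient_id), ]
  overlap <- intersect(pats$patient_id, unique(test_emb$patient_id))
  if (length(overlap))
    stop("train and test cohorts share patient(s): ",
         paste(overlap, collapse = ", "))

  binary_ids <- pats$patient_id[pats$origin %in% .binary_origins()]
  other_ids <- pats$patient_id[pats$origin == "other"]
  split <- .split_binary(pats[pats$patient_id %in% binary_ids, ],
                         split_protocol(seed = seed))
  scorer <- train_patch_classifier(train_emb, train_manifest, config,
                                   train_patients = split$train)
  o <- length(other_ids)
  i <- as.integer(round(confidence * o))
  cal <- .fold_calibration(scorer, train_emb, pats, split$calibration,
                           sort(other_ids))
  thr <- determine_thresholds(cal, i, contain_zero)

  test_pats <- manifest_patients(test_manifest)
  test_pats <- test_pats[test_pats$patient_id %in% unique(test_emb$patient_id), ]
  if (nrow(test_pats) == 0) {
    predictions <- data.table(patient_id = character(0),
                              true_origin = character(0),
                              sum_signed = numeric(0),
                              n_patches = integer(0),
                              predicted = character(0))
  } else {
    sums <- patient_sums(score_patches(scorer, test_emb))
    sums <- sums[match(sort(test_pats$patient_id), sums$patient_id), ]
    predictions <- data.table(
      patient_id = sums$patient_id,
      true_origin = test_pats$origin[match(sums$patient_id,
                                           test_pats$patient_id)],
      sum_signed = sums$sum_signed, n_patches = sums$n_patches,
      predicted = classify_with_abstention(sums$sum_signed, thr))
  }
  list(predictions = predictions,
       confusion = confusion_matrix3(predictions$true_origin,
                                     predictions$predicted),
       threshold = thr)
}

#' Leave-one-out evaluation of the plain binary classifier
#'
#' The first-step benchmark: for each held-out pancreas/small-intestine
#' patient, the classifier is trained on all remaining binary-origin
#' patients' patches and the held-out patient's 100 patches are scored; the
#' patient label is the majority vote.
#'
#' @param emb Cohort `net_embeddings` (other-origin patients are ignored).
#' @param manifest Cohort `net_manifest`.
#' @param config A [classifier_config()].
#' @return list with `patch_scores` (per-patch predictions with
#'   `true_origin`) and `patient_predictions` (majority votes).
#' @export
loo_binary_evaluate <- function(emb, manifest, config = classifier_config()) {
  emb <- as.data.table(emb)
  pats <- manifest_patients(manifest)
  pats <- pats[pats$patient_id %in% unique(emb$patient_id) &
                 pats$origin %in% .binary_origins(), ]
  if (sum(pats$origin == "pancreas") < 2 ||
      sum(pats$origin == "small_intestine") < 2)
    stop("leave-one-out needs at least 2 patients per binary class")
  ids <- sort(pats$patient_id)
  origin_of <- setNames(pats$origin, pats$patient_id)

  patch_rows <- vector("list", length(ids))
  pat_rows <- vector("list", length(ids))
  for (f in seq_along(ids)) {
    held <- ids[f]
    scorer <- train_patch_classifier(emb, manifest, config,
                                     train_patients = setdiff(ids, held))
    sc <- score_patches(scorer, emb[emb$patient_id == held, ])
    sc$true_origin <- origin_of[[held]]
    patch_rows[[f]] <- sc
    pat_rows[[f]] <- data.table(patient_id = held,
                                true_origin = origin_of[[held]],
                                predicted = majority_vote(sc))
  }
  list(patch_scores = data.table::rbindlist(patch_rows),
       patient_predictions = data.table::rbindlist(pat_rows))
}

#' Pooled binary accuracy at patch or patient level
#'
#' @param result Output of [loo_binary_evaluate()].
#' @param level `"patch"` or `"patient"`.
#' @return Fraction of correct predictions.
#' @export
binary_accuracy <- function(result, level = c("patient", "patch")) {
  level <- match.arg(level)
  if (level == "patch") {
    mean(result$patch_scores$predicted_label ==
           result$patch_scores$true_origin)
  } else {
    mean(result$patient_predictions$predicted ==
           result$patient_predictions$true_origin)
  }
}
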