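#' Patch-classifier configuration
#'
#' Mirrors the default settings of the reference implementation: no
#' hyperparameter optimisation, inverse regularisation strength `c = 1.0`,
#' SVM `gamma = "auto"` (1/d), polynomial degree 3 (unused by the linear and
#' RBF kernels but recorded), logistic regression with an L2 penalty and at
#' most 100 solver iterations. The positive class is fixed globally to
#' `small_intestine` so that signed scores, thresholds, and plots share one
#' sign convention: score > 0 means small intestine, score < 0 pancreas.
#'
#' @param model_kind `"svm_rbf"`, `"svm_linear"`, or `"logreg"`.
#' @param c Inverse regularisation strength (> 0).
#' @param svm_degree Polynomial degree (recorded only).
#' @param svm_gamma `"auto"` (= 1/d) or a positive number.
#' @param logreg_max_iter Iteration cap for the logistic-regression solver.
#' @param svm_tol Stopping tolerance of the SMO solver (KKT violation),
#'   matching the usual library default of `1e-3`.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(model_kind = c("svm_rbf", "svm_linear", "logreg"),
                              c = 1.0, svm_degree = 3L, svm_gamma = "auto",
                              logreg_max_iter = 100L, svm_tol = 1e-3) {
  model_kind <- match.arg(model_kind)
  stopifnot(c > 0, svm_tol > 0)
  if (!identical(svm_gamma, "auto")) stopifnot(is.numeric(svm_gamma), svm_gamma > 0)
  structure(list(model_kind = model_kind, c = c,
                 svm_degree = as.integer(svm_degree), svm_gamma = svm_gamma,
                 logreg_max_iter = as.integer(logreg_max_iter),
                 svm_tol = svm_tol,
                 positive_class = "small_intestine"),
            class = "classifier_config")
}

.resolve_gamma <- function(config, d)
  if (identical(config$svm_gamma, "auto")) 1 / d else config$svm_gamma

.fit_logreg <- function(X, y, C, max_iter) {
  # minimise 0.5 ||w||^2 + C * sum log(1 + exp(-y (Xw + b))); bias unpenalised
  d <- ncol(X)
  obj <- function(theta) {
    w <- theta[seq_len(d)]; b <- theta[d + 1]
    f <- drop(X %*% w) + b
    m <- -y * f
    0.5 * sum(w^2) + C * sum(ifelse(m > 30, m, log1p(exp(m))))
  }
  grad <- function(theta) {
    w <- theta[seq_len(d)]; b <- theta[d + 1]
    f <- drop(X %*% w) + b
    s <- 1 / (1 + exp(y * f))  # sigma(-y f)
    gw <- w - C * drop(t(X) %*% (y * s))
    gb <- -C * sum(y * s)
    c(gw, gb)
  }
  fit <- stats::optim(rep(0, d + 1), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = max_iter))
  list(w = fit$par[seq_len(d)], b = fit$par[d + 1])
}

#' Train the binary patch-level classifier
#'
#' Fits the configured model on the patch embeddings of the given training
#' patients (pancreas and small-intestine origins only). Training is
#' patient-honest: only patches whose `patient_id` is in `train_patients` are
#' seen, and the trained scorer records that set so downstream evaluation can
#' assert fold hygiene.
#'
#' @param emb A `net_embeddings` table.
#' @param manifest A `net_manifest` supplying origin labels.
#' @param config A [classifier_config()].
#' @param train_patients Character vector of training patient ids; defaults
#'   to all pancreas/small-intestine patients in `emb`.
#' @param seed Integer seed (accepted for interface symmetry; all three
#'   solvers are deterministic).
#' @return A `net_scorer` with a `signed_score` method exposed through
#'   [score_patches()].
#' @export
train_patch_classifier <- function(emb, manifest, config = classifier_config(),
                                   train_patients = NULL, seed = 1L) {
  emb <- as.data.table(emb)
  pats <- manifest_patients(manifest)
  origin_of <- setNames(pats$origin, pats$patient_id)
  if (is.null(train_patients)) {
    ids <- unique(emb$patient_id)
    train_patients <- ids[origin_of[ids] %in% .binary_origins()]
  }
  unknown <- setdiff(train_patients, pats$patient_id)
  if (length(unknown))
    stop("training patient(s) not in manifest: ", paste(unknown, collapse = ", "))
  bad <- train_patients[!origin_of[train_patients] %in% .binary_origins()]
  if (length(bad))
    stop("training restricted to pancreas/small_intestine patients; found ",
         "other-origin patient(s): ", paste(bad, collapse = ", "))

  sub <- emb[emb$patient_id %in% train_patients, ]
  if (nrow(sub) == 0) stop("no training patches")
  X <- embedding_matrix(sub)
  lab <- origin_of[sub$patient_id]
  if (length(unique(lab)) < 2)
    stop("training set contains a single class (", unique(lab),
         "); both pancreas and small_intestine are required")
  y <- ifelse(lab == config$positive_class, 1, -1)
  d <- ncol(X)

  fit <- switch(
    config$model_kind,
    svm_rbf = {
      g <- .resolve_gamma(config, d)
      f <- .svm_smo_fit(X, y, config$c, g, TRUE, tol = config$svm_tol)
      keep <- f$coef != 0
      list(sv = X[keep, , drop = FALSE], coef = f$coef[keep],
           rho = f$rho, gamma = g, rbf = TRUE)
    },
    svm_linear = {
      f <- .svm_smo_fit(X, y, config$c, 0, FALSE, tol = config$svm_tol)
      keep <- f$coef != 0
      list(sv = X[keep, , drop = FALSE], coef = f$coef[keep],
           rho = f$rho, gamma = 0, rbf = FALSE)
    },
    logreg = .fit_logreg(X, y, config$c, config$logreg_max_iter)
  )

  structure(list(kind = config$model_kind, config = config, dim = d,
                 fit = fit, train_patients = sort(unique(train_patients))),
            class = "net_scorer")
}

#' Signed decision values for a matrix of embedding vectors
#'
#' The "signed distance" of the pipeline is the raw decision value of the
#' model (SVM decision function, or the logit for logistic regression), not
#' the geometric distance `f/||w||`: the two are monotone-equivalent per
#' model, and the raw value is well-defined for the RBF kernel.
#'
#' @param scorer A `net_scorer`.
#' @param X Numeric matrix, one row per patch.
#' @return Numeric vector of signed scores (> 0: small intestine).
#' @export
signed_scores <- function(scorer, X) {
  stopifnot(inherits(scorer, "net_scorer"))
  X <- as.matrix(X)
  if (ncol(X) != scorer$dim)
    stop("embedding dimension ", ncol(X), " does not match the trained model (",
         scorer$dim, ")")
  if (scorer$kind %in% c("svm_rbf", "svm_linear")) {
    .svm_decision_values(scorer$fit$sv, scorer$fit$coef, scorer$fit$rho, X,
                         scorer$fit$gamma, scorer$fit$rbf)
  } else {
    drop(X %*% scorer$fit$w) + scorer$fit$b
  }
}

#' Score a patch-embedding table
#'
#' @param scorer A `net_scorer`.
#' @param emb A `net_embeddings`.
#' @return data.table with the provenance columns plus `signed_score` and
#'   `predicted_label` (sign > 0: small_intestine; sign < 0: pancreas; an
#'   exact 0 is kept as the boundary case and labelled pancreas).
#' @export
score_patches <- function(scorer, emb) {
  emb <- as.data.table(emb)
  s <- signed_scores(scorer, embedding_matrix(emb))
  out <- emb[, .prov_cols, with = FALSE]
  out$signed_score <- s
  out$predicted_label <- ifelse(s > 0, "small_intestine", "pancreas")
  out[]
}

#' Majority vote over one patient's patch predictions
#'
#' The label with strictly more patch votes wins; an exact vote tie is broken
#' by the sign of the summed signed scores, and a summed score of exactly 0
#' falls back to pancreas (with a message).
#'
#' @param scores data.table as returned by [score_patches()], restricted to
#'   one patient.
#' @return `"pancreas"` or `"small_intestine"`.
#' @export
majority_vote <- function(scores) {
  if (nrow(scores) == 0) stop("majority_vote on an empty patch set")
  n_si <- sum(scores$predicted_label == "small_intestine")
  n_pa <- nrow(scores) - n_si
  if (n_si != n_pa) return(if (n_si > n_pa) "small_intestine" else "pancreas")
  s <- sum(scores$signed_score)
  if (s > 0) return("small_intestine")
  if (s == 0) message("vote tie with summed score 0; defaulting to pancreas")
  "pancreas"
}

#' @export
print.net_scorer <- function(x, ...) {
  cat(sprintf("<net_scorer> %s, d=%d, trained on %d patient(s)\n",
              x$kind, x$dim, length(x$train_patients)))
  invisible(x)
}
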