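.prov_cols <- c("patient_id", "specimen_id", "slide_id", "x", "y", "size_px")

#' Assemble a patch-embedding table
#'
#' The cohort-wide embedding table stores one row per patch: provenance keys
#' (`patient_id`, `specimen_id`, `slide_id`, `x`, `y`, `size_px`) followed by
#' the feature vector in columns `f0 ... f{d-1}`. All vectors in one table
#' share the dimension `d`.
#'
#' @param provenance data.frame with the six provenance columns (one row per
#'   patch).
#' @param features numeric matrix, one row per patch; column count defines `d`.
#' @return A `net_embeddings` (a `data.table`).
#' @export
as_embeddings <- function(provenance, features) {
  provenance <- as.data.table(provenance)
  missing <- setdiff(.prov_cols, names(provenance))
  if (length(missing))
    stop("embedding provenance is missing column(s): ",
         paste(missing, collapse = ", "))
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(provenance) != nrow(features))
    stop("provenance and feature rows differ (",
         nrow(provenance), " vs ", nrow(features), ")")
  if (nrow(features) > 0 && !all(is.finite(features)))
    stop("feature vectors must be finite")
  d <- ncol(features)
  colnames(features) <- sprintf("f%d", seq_len(d) - 1L)
  out <- cbind(provenance[, .prov_cols, with = FALSE], as.data.table(features))
  for (col in c("patient_id", "specimen_id", "slide_id"))
    out[[col]] <- as.character(out[[col]])
  for (col in c("x", "y", "size_px"))
    out[[col]] <- as.integer(out[[col]])
  class(out) <- c("net_embeddings", class(out))
  out[]
}

.check_embeddings <- function(x) {
  fcols <- grep("^f[0-9]+$", names(x), value = TRUE)
  if (!length(fcols)) stop("no feature columns f0..f{d-1} found")
  d <- length(fcols)
  expect <- sprintf("f%d", seq_len(d) - 1L)
  if (!identical(sort(fcols), sort(expect)))
    stop("feature columns are not contiguous f0..f", d - 1L,
         " (mixed dimensions?)")
  if (nrow(x) > 0 && anyNA(x[, expect, with = FALSE]))
    stop("feature table contains missing values (mixed dimensions?)")
  expect
}

#' Feature matrix of an embedding table
#'
#' @param emb A `net_embeddings`.
#' @return numeric matrix, one row per patch.
#' @export
embedding_matrix <- function(emb) {
  emb <- as.data.table(emb)
  fcols <- .check_embeddings(emb)
  as.matrix(emb[, fcols, with = FALSE])
}

#' Embedding dimension
#' @param emb A `net_embeddings`.
#' @return Integer `d`.
#' @export
embedding_dim <- function(emb) length(.check_embeddings(as.data.table(emb)))

#' Write a patch-embedding table to CSV
#'
#' @param emb A `net_embeddings`.
#' @param path Output CSV path.
#' @return `path`, invisibly. The round-trip through [read_embeddings()] is
#'   lossless: full double precision is written.
#' @export
write_embeddings <- function(emb, path) {
  emb <- as.data.table(emb)
  if (nrow(emb) > 0) .check_embeddings(emb)
  # 17 significant digits round-trips IEEE doubles exactly
  old <- options(digits = 17); on.exit(options(old))
  fwrite(emb, path)
  invisible(path)
}

#' Read a patch-embedding table from CSV
#'
#' @param path CSV path as written by [write_embeddings()].
#' @return A `net_embeddings`.
#' @export
read_embeddings <- function(path) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  x <- fread(path)
  missing <- setdiff(.prov_cols, names(x))
  if (length(missing))
    stop("embedding file is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(x) > 0) {
    fcols <- .check_embeddings(x)
    as_embeddings(x[, .prov_cols, with = FALSE],
                  as.matrix(x[, fcols, with = FALSE]))
  } else {
    d <- length(grep("^f[0-9]+$", names(x)))
    as_embeddings(x[, .prov_cols, with = FALSE],
                  matrix(numeric(0), nrow = 0, ncol = d))
  }
}

#' @export
print.net_embeddings <- function(x, ...) {
  cat(sprintf("<net_embeddings> %d patches, d=%d, %d patient(s)\n",
              nrow(x), if (nrow(x) || ncol(x) > 6) embedding_dim(x) else 0L,
              length(unique(x$patient_id))))
  invisible(x)
}
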