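#' @importFrom data.table data.table as.data.table fread fwrite setkeyv copy :=
NULL

#' Origin labels recognised by the pipeline
#'
#' The binary classifier distinguishes `pancreas` from `small_intestine`;
#' every further primary site (lung, rectum, kidney, ...) is collapsed into
#' `other`, which the abstention layer is calibrated on.
#'
#' @return Character vector of the three allowed origin labels.
#' @export
net_origins <- function() c("pancreas", "small_intestine", "other")

.binary_origins <- function() c("pancreas", "small_intestine")

#' Assemble a cohort manifest
#'
#' A manifest is a flat table with one row per slide, describing the
#' patient -> specimen -> slide hierarchy and each patient's origin label.
#'
#' @param x data.frame with columns `patient_id`, `specimen_id`, `slide_id`,
#'   `origin`, `specimen_kind`.
#' @return A `net_manifest` (a `data.table` with the five columns above).
#' @export
as_manifest <- function(x) {
  x <- as.data.table(x)
  required <- c("patient_id", "specimen_id", "slide_id", "origin", "specimen_kind")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  x <- x[, required, with = FALSE]
  for (col in required) x[[col]] <- as.character(x[[col]])

  bad <- which(!(x$origin %in% net_origins()))
  if (length(bad))
    stop(sprintf(
      "row %d: unknown origin '%s' (allowed: %s)",
      bad[1], x$origin[bad[1]], paste(net_origins(), collapse = ", ")))
  bad_kind <- which(!(x$specimen_kind %in% c("resection", "biopsy")))
  if (length(bad_kind))
    stop(sprintf("row %d: unknown specimen_kind '%s' (allowed: resection, biopsy)",
                 bad_kind[1], x$specimen_kind[bad_kind[1]]))
  if (anyDuplicated(x$slide_id))
    stop("duplicate slide id: ",
         x$slide_id[which(duplicated(x$slide_id))[1]])

  # one origin per patient, one kind per specimen
  per_pat <- x[, list(n = length(unique(origin))), by = "patient_id"]
  if (any(per_pat$n > 1))
    stop("patient ", per_pat$patient_id[which(per_pat$n > 1)[1]],
         " carries more than one origin label")
  per_spec <- x[, list(n = length(unique(specimen_kind))),
                by = c("patient_id", "specimen_id")]
  if (any(per_spec$n > 1))
    stop("specimen ", per_spec$specimen_id[which(per_spec$n > 1)[1]],
         " carries more than one specimen_kind")

  setkeyv(x, c("patient_id", "specimen_id", "slide_id"))
  class(x) <- c("net_manifest", class(x))
  x[]
}

#' Read a cohort manifest from CSV
#'
#' Expects one row per slide with columns
#' `patient_id, specimen_id, slide_id, origin, specimen_kind`.
#'
#' @param path Path to a CSV file.
#' @return A `net_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  as_manifest(fread(path, colClasses = "character"))
}

#' Write a cohort manifest to CSV
#'
#' @param manifest A `net_manifest`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  fwrite(as.data.table(manifest), path)
  invisible(path)
}

#' Patient-level view of a manifest
#'
#' @param manifest A `net_manifest`.
#' @return data.table with one row per patient: `patient_id`, `origin`,
#'   `n_specimens`, `n_slides`.
#' @export
manifest_patients <- function(manifest) {
  m <- as.data.table(manifest)
  out <- m[, list(origin = origin[1],
                  n_specimens = length(unique(specimen_id)),
                  n_slides = length(unique(slide_id))),
           by = "patient_id"]
  setkeyv(out, "patient_id")
  out[]
}

#' @export
print.net_manifest <- function(x, ...) {
  pats <- manifest_patients(x)
  cat(sprintf("<net_manifest> %d patients, %d slides\n",
              nrow(pats), nrow(x)))
  comp <- table(factor(pats$origin, levels = net_origins()))
  cat("  origins:", paste(sprintf("%s=%d", names(comp), comp), collapse = ", "),
      "\n")
  invisible(x)
}
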