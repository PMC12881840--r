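#' Synthetic-cohort configuration
#'
#' Describes the latent structure the pipeline assumes: two class clusters of
#' patch embeddings separated by `delta` along the first feature axis, a
#' Gaussian patient-level random effect, isotropic within-patient patch
#' noise, and a heterogeneous "other origin" population drawn from a mixture
#' concentrated near the decision boundary.
#'
#' Defaults state the conditions of the reference cohort-scale experiments:
#' 100 patches per patient, separation 5x the patch noise, 20/20/8 patients,
#' and `dim = 36` so that the simulated-embedding path and the image +
#' toy-stats extractor path are interchangeable in tests.
#'
#' @param n_pancreas,n_si,n_other Patient counts per origin.
#' @param patches_per_patient Patches simulated per patient (100).
#' @param dim Embedding dimension.
#' @param delta Class-centroid separation along axis 1; pancreas at
#'   `-delta/2`, small intestine at `+delta/2`.
#' @param sigma_patch Within-patient patch spread (per coordinate).
#' @param sigma_patient Patient-level random-effect spread on axis 1.
#' @param other_mix list of mixture components for other-origin patients,
#'   each `c(offset, spread, weight)`: the patient effect on axis 1 is drawn
#'   from `Normal(offset, spread)` of a component chosen by weight. Default:
#'   one component centred on the boundary.
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_pancreas = 20L, n_si = 20L, n_other = 8L,
                              patches_per_patient = 100L, dim = 36L,
                              delta = 5, sigma_patch = 1, sigma_patient = 0.5,
                              other_mix = list(c(0, 0.5, 1)), seed = 1L) {
  stopifnot(sigma_patch > 0, sigma_patient > 0, dim >= 2, delta >= 0,
            patches_per_patient >= 1)
  w <- vapply(other_mix, function(cmp) cmp[3], numeric(1))
  stopifnot(abs(sum(w) - 1) < 1e-8, all(w > 0),
            all(vapply(other_mix, function(cmp) cmp[2] > 0, logical(1))))
  structure(list(n_pancreas = as.integer(n_pancreas), n_si = as.integer(n_si),
                 n_other = as.integer(n_other),
                 patches_per_patient = as.integer(patches_per_patient),
                 dim = as.integer(dim), delta = delta,
                 sigma_patch = sigma_patch, sigma_patient = sigma_patient,
                 other_mix = other_mix, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a cohort of patch embeddings
#'
#' Draws, per patient, a patient effect on the separation axis (class centre
#' plus `Normal(0, sigma_patient)`, or a mixture component for other-origin
#' patients) and then `patches_per_patient` embedding vectors with
#' independent `Normal(0, sigma_patch)` noise per coordinate, the first
#' coordinate centred on the patient effect. Reproducible per seed.
#'
#' @param cfg A [simulation_config()].
#' @return list with `manifest` (a `net_manifest`) and `embeddings` (a
#'   `net_embeddings`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  origins <- c(rep("pancreas", cfg$n_pancreas),
               rep("small_intestine", cfg$n_si),
               rep("other", cfg$n_other))
  prefix <- c(pancreas = "pan", small_intestine = "sin", other = "oth")
  idx <- unlist(lapply(c(cfg$n_pancreas, cfg$n_si, cfg$n_other), seq_len))
  ids <- sprintf("%s%03d", prefix[origins], idx)

  manifest <- as_manifest(data.frame(
    patient_id = ids,
    specimen_id = paste0(ids, "_s1"),
    slide_id = paste0(ids, "_sl1"),
    origin = origins,
    specimen_kind = "resection"))

  n <- cfg$patches_per_patient
  weights <- vapply(cfg$other_mix, function(cmp) cmp[3], numeric(1))
  rows <- .with_seed(cfg$seed, lapply(seq_along(ids), function(p) {
    effect <- switch(
      origins[p],
      pancreas = -cfg$delta / 2 + rnorm(1, 0, cfg$sigma_patient),
      small_intestine = cfg$delta / 2 + rnorm(1, 0, cfg$sigma_patient),
      other = {
        cmp <- cfg$other_mix[[sample.int(length(weights), 1, prob = weights)]]
        rnorm(1, cmp[1], cmp[2])
      })
    X <- matrix(rnorm(n * cfg$dim, 0, cfg$sigma_patch), nrow = n)
    X[, 1] <- X[, 1] + effect
    X
  }))

  prov <- data.frame(
    patient_id = rep(ids, each = n),
    specimen_id = rep(paste0(ids, "_s1"), each = n),
    slide_id = rep(paste0(ids, "_sl1"), each = n),
    x = rep((seq_len(n) - 1L) * 4096L, times = length(ids)),
    y = 0L, size_px = 4096L)
  list(manifest = manifest,
       embeddings = as_embeddings(prov, do.call(rbind, rows)))
}

#' Simulate textured slide images with annotations
#'
#' Generates, per patient, one small synthetic "slide" image whose pixel
#' intensities are the class palette value plus uniform noise, together with
#' a tumor polygon (the slide interior minus a margin) and optional artifact
#' polygons, written as plain-text PPM and GeoJSON. This exercises the
#' annotation -> sampling -> preprocessing -> toy-stats path end to end;
#' it makes no attempt at realistic histology texture.
#'
#' @param cfg A [simulation_config()] (patient counts and seed are used).
#' @param dir Output directory (created if needed).
#' @param palette Named list of RGB base intensities (0-255 3-vectors) for
#'   `pancreas`, `small_intestine`, `other`.
#' @param slide_px Side length of the synthetic slides.
#' @param noise Half-width of the uniform pixel noise.
#' @param artifact_fraction Fraction `[0, 1)` of the slide width covered by a
#'   left-anchored artifact rectangle on every slide.
#' @return list with `manifest` and a data.table `slides` (slide_id, image
#'   path, annotation path).
#' @export
simulate_tiles <- function(cfg, dir,
                           palette = list(pancreas = c(180, 120, 160),
                                          small_intestine = c(120, 160, 180),
                                          other = c(150, 140, 170)),
                           slide_px = 192L, noise = 20,
                           artifact_fraction = 0) {
  stopifnot(inherits(cfg, "simulation_config"),
            artifact_fraction >= 0, artifact_fraction < 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  origins <- c(rep("pancreas", cfg$n_pancreas),
               rep("small_intestine", cfg$n_si),
               rep("other", cfg$n_other))
  prefix <- c(pancreas = "pan", small_intestine = "sin", other = "oth")
  idx <- unlist(lapply(c(cfg$n_pancreas, cfg$n_si, cfg$n_other), seq_len))
  ids <- sprintf("%s%03d", prefix[origins], idx)

  if (length(ids) == 0) {
    return(list(manifest = NULL,
                slides = data.table(slide_id = character(0),
                                    image = character(0),
                                    annotation = character(0))))
  }

  manifest <- as_manifest(data.frame(
    patient_id = ids, specimen_id = paste0(ids, "_s1"),
    slide_id = paste0(ids, "_sl1"), origin = origins,
    specimen_kind = "resection"))
  write_manifest(manifest, file.path(dir, "manifest.csv"))

  margin <- 2
  tumor_poly <- rbind(c(margin, margin), c(slide_px - margin, margin),
                      c(slide_px - margin, slide_px - margin),
                      c(margin, slide_px - margin))
  rows <- .with_seed(cfg$seed, lapply(seq_along(ids), function(p) {
    base <- palette[[origins[p]]]
    img <- array(0L, dim = c(slide_px, slide_px, 3))
    for (c in 1:3) {
      v <- base[c] + runif(slide_px * slide_px, -noise, noise)
      img[, , c] <- as.integer(round(pmin(pmax(v, 0), 255)))
    }
    slide_id <- paste0(ids[p], "_sl1")
    img_path <- file.path(dir, paste0(slide_id, ".ppm"))
    write_ppm(img, img_path)
    artifact <- list()
    if (artifact_fraction > 0) {
      ax <- artifact_fraction * slide_px
      artifact <- list(rbind(c(0, 0), c(ax, 0), c(ax, slide_px),
                             c(0, slide_px)))
    }
    ann <- region_annotation(slide_id, tumor = list(tumor_poly),
                             artifact = artifact)
    ann_path <- file.path(dir, paste0(slide_id, ".geojson"))
    write_annotations(ann, ann_path)
    data.table(slide_id = slide_id, image = img_path, annotation = ann_path)
  }))
  list(manifest = manifest, slides = data.table::rbindlist(rows))
}
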