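#' Tile geometry specification
#'
#' @param patch_size_px Side length of the sampled square patch in pixels;
#'   4096 for 80x-scanned internal-style slides, 2048 for 20x-scanned
#'   external-style slides.
#' @param output_size_px Side length after downscaling (network input), 224.
#' @param patches_per_patient Patch quota per patient, 100.
#' @return A `tile_spec` list.
#' @export
tile_spec <- function(patch_size_px = 4096L, output_size_px = 224L,
                      patches_per_patient = 100L) {
  patch_size_px <- as.integer(patch_size_px)
  output_size_px <- as.integer(output_size_px)
  patches_per_patient <- as.integer(patches_per_patient)
  stopifnot(patch_size_px >= output_size_px, patches_per_patient >= 1L)
  structure(list(patch_size_px = patch_size_px,
                 output_size_px = output_size_px,
                 patches_per_patient = patches_per_patient),
            class = "tile_spec")
}

#' Channel-normalisation specification
#'
#' The ImageNet channel statistics applied after rescaling pixel values to
#' `[0, 1]`: `value = (pixel/255 - mean_c) / std_c`.
#'
#' @param channel_mean,channel_std RGB mean and standard deviation 3-vectors.
#' @return A `preprocess_spec` list.
#' @export
preprocess_spec <- function(channel_mean = c(0.485, 0.456, 0.406),
                            channel_std = c(0.229, 0.224, 0.225)) {
  stopifnot(length(channel_mean) == 3, length(channel_std) == 3,
            all(channel_std > 0))
  structure(list(channel_mean = as.numeric(channel_mean),
                 channel_std = as.numeric(channel_std)),
            class = "preprocess_spec")
}

#' Allocate a patient's patch quota across specimens and slides
#'
#' The quota is first distributed evenly across the patient's specimens
#' (biopsies/resections) and then, within each specimen, evenly across its
#' slides, so that every slide contributes equally. Rounding is by largest
#' remainder with ties broken in lexicographic `specimen_id` then `slide_id`
#' order, making the allocation deterministic.
#'
#' @param manifest A `net_manifest` restricted (or restrictable) to one
#'   patient.
#' @param patient_id Patient whose quota to allocate.
#' @param total Total patch count for the patient (default 100).
#' @return Named integer vector: slide_id -> patch count, summing to `total`.
#' @export
allocate_quota <- function(manifest, patient_id, total = 100L) {
  total <- as.integer(total)
  stopifnot(total >= 1L)
  m <- as.data.table(manifest)
  keep <- m$patient_id == patient_id  # evaluate outside the data.table frame
  m <- m[keep, ]
  if (nrow(m) == 0) stop("patient not in manifest: ", patient_id)

  largest_remainder <- function(total, ids) {
    # even split of `total` over `ids`, remainder to lexicographically first
    ids <- sort(ids)
    k <- length(ids)
    base <- total %/% k
    rem <- total %% k
    counts <- rep.int(base, k)
    if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
    setNames(as.integer(counts), ids)
  }

  spec_alloc <- largest_remainder(total, unique(m$specimen_id))
  out <- integer(0)
  for (sid in names(spec_alloc)) {
    slides <- unique(m$slide_id[m$specimen_id == sid])
    out <- c(out, largest_remainder(spec_alloc[[sid]], slides))
  }
  out
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Sample patch coordinates from the tumor regions of a slide
#'
#' Rejection-samples square patch top-left corners uniformly over the
#' bounding box of the tumor polygons, accepting a placement when the square
#' lies fully inside a tumor polygon and does not touch any artifact polygon.
#' Overlapping patches are permitted. If fewer than `count` placements are
#' found within `max_attempts` (default `1000 * count`), the found set is
#' returned and the shortfall flagged in the `shortfall` attribute.
#'
#' @param annotation A `net_annotation`.
#' @param count Number of patches to sample.
#' @param spec A [tile_spec()].
#' @param seed Integer seed; identical seed and inputs give identical
#'   coordinates.
#' @param max_attempts Attempt budget for rejection sampling.
#' @return data.table with columns `slide_id`, `x`, `y`, `size_px`; attribute
#'   `shortfall` = `count - rows`.
#' @export
sample_patches <- function(annotation, count, spec = tile_spec(), seed = 1L,
                           max_attempts = 1000L * count) {
  stopifnot(inherits(annotation, "net_annotation"), count >= 0)
  if (length(annotation$tumor) == 0)
    stop("slide ", annotation$slide_id, " has no tumor polygon")
  s <- spec$patch_size_px
  found_x <- integer(0); found_y <- integer(0)

  if (count > 0) {
    bb <- .polys_bbox(annotation$tumor)
    # top-left corners that could possibly fit
    x_lo <- bb["xmin"]; x_hi <- bb["xmax"] - s
    y_lo <- bb["ymin"]; y_hi <- bb["ymax"] - s
    if (x_hi >= x_lo && y_hi >= y_lo) {
      .with_seed(seed, {
        attempts <- 0L
        while (length(found_x) < count && attempts < max_attempts) {
          attempts <- attempts + 1L
          x <- floor(runif(1, x_lo, x_hi + 1))
          y <- floor(runif(1, y_lo, y_hi + 1))
          ok <- any(vapply(annotation$tumor,
                           function(p) .square_in_poly(x, y, s, p), logical(1)))
          if (ok && length(annotation$artifact) > 0)
            ok <- !any(vapply(annotation$artifact,
                              function(p) .square_intersects_poly(x, y, s, p),
                              logical(1)))
          if (ok) {
            found_x <- c(found_x, as.integer(x))
            found_y <- c(found_y, as.integer(y))
          }
        }
      })
    }
  }

  out <- data.table(slide_id = rep(annotation$slide_id, length(found_x)),
                    x = found_x, y = found_y,
                    size_px = rep(as.integer(s), length(found_x)))
  shortfall <- count - nrow(out)
  if (shortfall > 0)
    warning(sprintf("slide %s: placed %d of %d patches (shortfall %d)",
                    annotation$slide_id, nrow(out), count, shortfall))
  attr(out, "shortfall") <- as.integer(shortfall)
  out
}

# Exact area-average (box) downscaling matrix from `n` source pixels to
# `m` target pixels; A %*% v averages v over [i*n/m, (i+1)*n/m).
.area_average_matrix <- function(n, m) {
  A <- matrix(0, m, n)
  scale <- n / m
  for (i in seq_len(m)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    k_lo <- floor(lo) + 1
    k_hi <- ceiling(hi)
    for (k in k_lo:k_hi) {
      overlap <- min(hi, k) - max(lo, k - 1)
      if (overlap > 0) A[i, k] <- overlap / scale
    }
  }
  A
}

#' Preprocess an image tile to network-input format
#'
#' Downscales a square `patch_size_px` tile to `output_size_px` by exact area
#' averaging, rescales pixel values from `[0, 255]` to `[0, 1]`, and applies
#' per-channel standardisation `(value - mean_c) / std_c`.
#'
#' @param tile H x W x 3 array of integer pixel values in `[0, 255]`, with
#'   `H == W == spec_tile$patch_size_px`.
#' @param spec_pre A [preprocess_spec()].
#' @param spec_tile A [tile_spec()]; supplies input and output sizes.
#' @return `output_size_px` x `output_size_px` x 3 numeric array.
#' @export
preprocess_patch <- function(tile, spec_pre = preprocess_spec(),
                             spec_tile = tile_spec()) {
  d <- dim(tile)
  if (length(d) != 3 || d[3] != 3 || d[1] != d[2])
    stop("tile must be a square H x H x 3 array")
  if (d[1] != spec_tile$patch_size_px)
    stop("tile side ", d[1], " does not match patch_size_px ",
         spec_tile$patch_size_px)
  if (min(tile) < 0 || max(tile) > 255)
    stop("pixel values must lie in [0, 255]")
  m <- spec_tile$output_size_px
  A <- .area_average_matrix(d[1], m)
  out <- array(0, dim = c(m, m, 3))
  for (c in 1:3) {
    small <- A %*% tile[, , c] %*% t(A)
    out[, , c] <- (small / 255 - spec_pre$channel_mean[c]) /
      spec_pre$channel_std[c]
  }
  out
}
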