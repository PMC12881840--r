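# Plain-text PPM (P3) image IO. Used for synthetic slide/tile fixtures so the
# whole test surface stays text-only; real deployments would read scanner
# exports through dedicated tooling instead.

#' Write an RGB image as plain-text PPM (P3)
#'
#' @param img H x W x 3 integer array with values in `[0, 255]`.
#' @param path Output path (conventionally `.ppm`).
#' @return `path`, invisibly.
#' @export
write_ppm <- function(img, path) {
  d <- dim(img)
  stopifnot(length(d) == 3, d[3] == 3, min(img) >= 0, max(img) <= 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(d[2], d[1]), "255"), con)
  # pixel rows in raster order, one image row per line
  px <- matrix(0L, nrow = d[1], ncol = 3 * d[2])
  for (c in 1:3) px[, seq(c, by = 3, length.out = d[2])] <- as.integer(img[, , c])
  writeLines(apply(px, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a plain-text PPM (P3) image
#'
#' @param path Path to a P3 `.ppm` file.
#' @return H x W x 3 integer array.
#' @export
read_ppm <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P3") stop("only plain-text P3 PPM is supported: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxv <- as.integer(toks[4])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != 3 * w * h) stop("truncated PPM: ", path)
  img <- array(0L, dim = c(h, w, 3))
  m <- matrix(vals, nrow = h, ncol = 3 * w, byrow = TRUE)
  for (c in 1:3) img[, , c] <- m[, seq(c, by = 3, length.out = w)]
  if (maxv != 255) img <- as.integer(round(img * 255 / maxv))
  img
}

#' Crop a square tile out of a slide image
#'
#' Uses the package's raster convention: 0-based top-left coordinates and a
#' half-open `[x, x + size) x [y, y + size)` pixel window.
#'
#' @param slide H x W x 3 array.
#' @param x,y 0-based top-left pixel of the tile.
#' @param size Tile side length in pixels.
#' @return size x size x 3 array.
#' @export
crop_tile <- function(slide, x, y, size) {
  d <- dim(slide)
  if (x < 0 || y < 0 || x + size > d[2] || y + size > d[1])
    stop("tile window [", x, ", ", x + size, ") x [", y, ", ", y + size,
         ") exceeds the slide (", d[2], " x ", d[1], ")")
  slide[(y + 1):(y + size), (x + 1):(x + size), , drop = FALSE]
}
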