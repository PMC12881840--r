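#' Feature-extractor specification
#'
#' The pipeline consumes patch embeddings through a pluggable extractor
#' contract. The reference extractors of the original workflow
#' (`imagenet-resnet50`, `mtdp`, `retccl`, each d = 2048) are frozen
#' pretrained networks consumed as adapters and are not bundled: requesting
#' one raises an explicit error directing the user to supply pre-computed
#' embeddings or to use the deterministic offline `toy-stats` extractor.
#'
#' @param name Extractor name; `"toy-stats"` is the built-in offline
#'   extractor.
#' @param dim Output dimension; inferred for known names.
#' @return An `extractor_spec` list with fields `name`, `dim`,
#'   `deterministic`.
#' @export
extractor_spec <- function(name = "toy-stats", dim = NULL) {
  known <- c("toy-stats" = 36L, "imagenet-resnet50" = 2048L,
             "mtdp" = 2048L, "retccl" = 2048L)
  if (is.null(dim)) {
    if (!name %in% names(known))
      stop("unknown extractor '", name, "': supply dim explicitly")
    dim <- known[[name]]
  }
  dim <- as.integer(dim)
  stopifnot(dim >= 1L)
  structure(list(name = name, dim = dim,
                 deterministic = identical(name, "toy-stats")),
            class = "extractor_spec")
}

# toy-stats: per channel {mean, sd, min, max, 8-bin histogram proportion},
# 3 * 12 = 36 coordinates. Histogram bins are fixed at 8 equal-width bins on
# [-3, 3] (values clamped into the end bins) so the feature is independent of
# the tile content range.
.toy_stats_vector <- function(tile) {
  out <- numeric(0)
  breaks <- seq(-3, 3, length.out = 9L)
  for (c in 1:3) {
    v <- as.numeric(tile[, , c])
    clamped <- pmin(pmax(v, breaks[1]), breaks[9])
    idx <- findInterval(clamped, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    h <- tabulate(idx, nbins = 8L) / length(v)
    out <- c(out, mean(v), sd(v), min(v), max(v), h)
  }
  out
}

#' Extract feature vectors from preprocessed tiles
#'
#' Applies the extractor independently to each tile (no cross-tile state):
#' permuting the input order permutes the output rows identically.
#'
#' @param tiles list of preprocessed 224 x 224 x 3 numeric arrays (see
#'   [preprocess_patch()]).
#' @param extractor An [extractor_spec()]; only `"toy-stats"` is runnable
#'   offline.
#' @return Numeric matrix with one row per tile and `extractor$dim` columns.
#' @export
extract_features <- function(tiles, extractor = extractor_spec("toy-stats")) {
  stopifnot(inherits(extractor, "extractor_spec"))
  if (extractor$name != "toy-stats")
    stop("extractor '", extractor$name, "' requires pretrained weights that ",
         "are not bundled; use extractor 'toy-stats' or provide ",
         "pre-computed embeddings via read_embeddings()")
  if (length(tiles) == 0)
    return(matrix(numeric(0), nrow = 0, ncol = extractor$dim))
  out <- t(vapply(tiles, function(tl) {
    d <- dim(tl)
    if (length(d) != 3 || d[3] != 3)
      stop("tiles must be H x W x 3 arrays")
    .toy_stats_vector(tl)
  }, numeric(extractor$dim)))
  out
}
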