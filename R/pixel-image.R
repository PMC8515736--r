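#' Single-channel raster image with physical pixel size
#'
#' The universal carrier for one channel of a field of view: a 2D grid of
#' non-negative intensities (arbitrary units) plus the physical pixel size in
#' nanometres. Rows index y, columns index x; pixel centres sit at integer
#' 0-based coordinates, so the physical position of pixel `(row, col)` is
#' `((col - 1) * pixel_size_nm, (row - 1) * pixel_size_nm)`.
#'
#' @param values Numeric matrix of intensities (a.u.). Negative values are
#'   rejected.
#' @param pixel_size_nm Positive scalar, physical edge length of one pixel.
#' @param channel Channel label (e.g. `"target"`, `"psd"`).
#' @param modality Imaging modality, one of `"sted"`, `"confocal"`,
#'   `"airyscan"`. Informational; it does not change any computation.
#' @return An object of class `pixel_image`.
#' @export
pixel_image <- function(values, pixel_size_nm, channel = "unnamed",
                        modality = c("sted", "confocal", "airyscan")) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (anyNA(values) || any(values < 0))
    stop("`values` must be non-negative and free of NA")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a positive scalar")
  structure(
    list(values = values, pixel_size_nm = as.numeric(pixel_size_nm),
         channel = as.character(channel), modality = modality),
    class = "pixel_image")
}

#' @export
print.pixel_image <- function(x, ...) {
  cat(sprintf("<pixel_image> %s [%s], %d x %d px @ %.3g nm/px, range [%.4g, %.4g]\n",
              x$channel, x$modality, nrow(x$values), ncol(x$values),
              x$pixel_size_nm, min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.pixel_image <- function(x) dim(x$values)

as_pixel_image <- function(x) {
  if (inherits(x, "pixel_image")) return(x)
  if (is.matrix(x)) stop("a bare matrix lacks pixel size; use pixel_image()")
  stop("cannot coerce to pixel_image")
}

stopifnot_same_grid <- function(a, b) {
  da <- if (inherits(a, "pixel_image")) dim(a$values) else dim(mask_values(a))
  db <- if (inherits(b, "pixel_image")) dim(b$values) else dim(mask_values(b))
  if (!identical(da, db))
    stop(sprintf("grid shape mismatch: %dx%d vs %dx%d",
                 da[1], da[2], db[1], db[2]))
  invisible(TRUE)
}

#' Read a single- or multi-page TIFF as pixel images
#'
#' Reads every page of a TIFF file. Pixel size and channel names are taken
#' from a JSON sidecar (`<path>.json`, written by [write_pixel_images()]) when
#' present, otherwise from the `pixel_size_nm`/`channels` arguments.
#'
#' @param path TIFF file path.
#' @param pixel_size_nm Pixel size override; required when no sidecar exists.
#' @param channels Optional character vector of channel names, one per page.
#' @param modality Modality label applied to every page.
#' @return A named list of `pixel_image` objects, one per page.
#' @export
read_pixel_images <- function(path, pixel_size_nm = NULL, channels = NULL,
                              modality = "sted") {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  scale <- if (!is.null(meta$intensity_scale)) meta$intensity_scale else 1
  px <- pixel_size_nm %||% meta$pixel_size_nm
  if (is.null(px)) stop("pixel_size_nm not given and no metadata sidecar found")
  ch <- channels %||% meta$channels %||% sprintf("page%d", seq_along(pages))
  out <- lapply(seq_along(pages), function(i) {
    v <- pages[[i]]
    if (length(dim(v)) == 3) v <- v[, , 1]  # drop extra samples
    pixel_image(v * scale, px, channel = ch[i], modality = modality)
  })
  names(out) <- ch
  out
}

#' Write pixel images as one multi-page 16-bit TIFF plus a metadata sidecar
#'
#' Intensities are stored as 16-bit pages scaled by the global maximum; the
#' scale factor, channel names and pixel size are recorded in `<path>.json` so
#' that [read_pixel_images()] restores the original values (up to 16-bit
#' quantization).
#'
#' @param images List of `pixel_image` objects sharing one grid and pixel size.
#' @param path Output TIFF path.
#' @return Invisibly, the path.
#' @export
write_pixel_images <- function(images, path) {
  if (inherits(images, "pixel_image")) images <- list(images)
  px <- unique(vapply(images, function(i) i$pixel_size_nm, numeric(1)))
  if (length(px) != 1) stop("all channels must share one pixel size")
  top <- max(1, vapply(images, function(i) max(i$values), numeric(1)))
  pages <- lapply(images, function(i) i$values / top)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size_nm = px,
               channels = vapply(images, function(i) i$channel, character(1)),
               intensity_scale = top)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a binary mask as an 8-bit TIFF (0/255)
#' @param mask A `binary_mask`.
#' @param path Output path.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(mask_values(mask) * 1.0, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All simulator randomness flows through
# this so that (config, seed) fully determine the outputs.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic per-channel sub-seed: base seed combined with a small string
# hash, kept inside 32-bit integer range.
channel_seed <- function(seed, channel_id) {
  h <- sum(utf8ToInt(as.character(channel_id)) * seq_along(utf8ToInt(as.character(channel_id))))
  (as.numeric(seed) * 10007 + h) %% 2147483647
}
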