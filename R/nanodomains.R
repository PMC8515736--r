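#' Maximum Feret diameter of a pixel region
#'
#' The "length" of a nanodomain: the maximum caliper distance over pixel
#' centres, in physical units. Computed over the convex hull of the pixel
#' centres (the Feret diameter of a point set is attained on its hull). A
#' single-pixel region has length one pixel by convention.
#'
#' @param region Two-column matrix of 0-based (row, col) pixel coordinates,
#'   or a vector of linear indices with `dim` supplied.
#' @param pixel_size_nm Physical pixel size.
#' @param dim Grid dimensions when `region` is a linear index vector.
#' @return Length in nm.
#' @export
measure_length <- function(region, pixel_size_nm, dim = NULL) {
  pts <- region_points(region, dim)
  if (nrow(pts) == 0) stop("empty region has no length")
  if (nrow(pts) == 1) return(pixel_size_nm)
  h <- tryCatch(grDevices::chull(pts[, 2], pts[, 1]), error = function(e) NULL)
  hp <- if (!is.null(h) && length(h) >= 2) pts[h, , drop = FALSE] else pts
  d2 <- 0
  for (i in seq_len(nrow(hp) - 1)) {
    dd <- (hp[(i + 1):nrow(hp), 1] - hp[i, 1])^2 +
          (hp[(i + 1):nrow(hp), 2] - hp[i, 2])^2
    d2 <- max(d2, dd)
  }
  sqrt(d2) * pixel_size_nm
}

region_points <- function(region, dim = NULL) {
  if (is.matrix(region) && ncol(region) == 2) {
    storage.mode(region) <- "double"
    return(region)
  }
  if (is.null(dim)) stop("linear pixel indices need `dim`")
  cbind(row = (region - 1) %% dim[1], col = (region - 1) %/% dim[1])
}

#' Background-corrected intensity of a pixel region
#'
#' `integrated`: sum over the region of `max(value - background, 0)`;
#' `mean`: the integrated value divided by the region area.
#'
#' @param region Linear pixel indices into `img$values`.
#' @param img A `pixel_image`.
#' @param mode `"integrated"` (default) or `"mean"`.
#' @param background Non-negative background level subtracted per pixel.
#' @return Intensity (a.u.).
#' @export
measure_intensity <- function(region, img, mode = c("integrated", "mean"),
                              background = 0) {
  mode <- match.arg(mode)
  if (background < 0) stop("background must be non-negative")
  if (length(region) == 0) stop("empty region has no intensity")
  if (any(region < 1 | region > length(img$values)))
    stop("region indices fall outside the image")
  s <- sum(pmax(img$values[region] - background, 0))
  if (mode == "mean") s / length(region) else s
}

#' Nanodomain extraction parameters
#'
#' @param threshold_method,threshold_param,min_area_px,max_area_px,connectivity
#'   Segmentation of the target channel, as in [seg_config()].
#' @param assignment Zone-assignment rule: `"centroid"` (region centroid
#'   inside the zone mask, default) or `"overlap"` (overlap fraction of the
#'   region with the mask at least `min_overlap_frac`).
#' @param min_overlap_frac Overlap fraction for `assignment = "overlap"`.
#' @param intensity_mode `"integrated"` (default) or `"mean"`.
#' @param background `"auto"` (median of sub-threshold pixels, default) or a
#'   fixed number.
#' @param length_halfmax Measure length on the connected sub-region above
#'   half of the domain's background-corrected peak (default `TRUE`). This
#'   makes the length a full-width-at-half-maximum-type measure that does
#'   not depend on where the global threshold happened to fall; set `FALSE`
#'   to take the Feret diameter of the thresholded region as is.
#' @return A `nanodomain_config` list.
#' @export
nanodomain_config <- function(threshold_method = "otsu", threshold_param = NULL,
                              min_area_px = 2, max_area_px = NULL,
                              connectivity = 8,
                              assignment = c("centroid", "overlap"),
                              min_overlap_frac = 0.5,
                              intensity_mode = "integrated",
                              background = "auto",
                              length_halfmax = TRUE) {
  assignment <- match.arg(assignment)
  structure(list(threshold_method = threshold_method,
                 threshold_param = threshold_param,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 connectivity = connectivity, assignment = assignment,
                 min_overlap_frac = min_overlap_frac,
                 intensity_mode = intensity_mode, background = background,
                 length_halfmax = length_halfmax),
            class = "nanodomain_config")
}

# Connected sub-region above half of the background-corrected local peak,
# restricted to the component containing the peak pixel.
halfmax_subregion <- function(region, values, background, dims, connectivity) {
  v <- values[region] - background
  peak <- max(v)
  if (peak <= 0) return(region)
  keep <- region[v > peak / 2]
  if (length(keep) <= 1) return(keep)
  sub <- matrix(FALSE, dims[1], dims[2])
  sub[keep] <- TRUE
  lab <- label_regions(sub, connectivity = connectivity)
  peak_px <- region[which.max(v)]
  comp <- lab$labels[peak_px]
  which(lab$labels == comp)
}

#' Extract nanodomain records from a target channel within one zone class
#'
#' Segments the target channel with the same primitives used for zone
#' segmentation (threshold, size filter, label), then assigns each target
#' region to `zone_class` when it satisfies the assignment rule against
#' `zone_mask` (centroid containment by default), and measures its length
#' (maximum Feret diameter, optionally on the half-maximum sub-region) and
#' background-corrected intensity.
#'
#' @param target `pixel_image` of the target protein.
#' @param zone_mask `binary_mask` of the functional zone (or process mask).
#' @param zone_class Label stored on each record (`"pre"`, `"post"`,
#'   `"peri"`, `"process"`, or `"partner:<name>"`).
#' @param cfg A [nanodomain_config()].
#' @param regions Optional pre-segmented `labeled_regions` of the target
#'   channel (with attribute `"background"`), to avoid re-segmenting when
#'   extracting several zones from one field.
#' @param source_field Field identifier stored on each record.
#' @return Data frame with one row per assigned nanodomain: id, zone_class,
#'   length_nm, intensity_au, area_px, centroid_row, centroid_col,
#'   source_field.
#' @export
extract_nanodomains <- function(target, zone_mask, zone_class,
                                cfg = nanodomain_config(), regions = NULL,
                                source_field = "field") {
  zm <- mask_values(zone_mask)
  stopifnot_same_grid(target, zone_mask)
  if (is.null(regions)) regions <- segment_target(target, cfg)
  bg <- attr(regions, "background") %||% 0
  empty <- data.frame(id = integer(), zone_class = character(),
                      length_nm = numeric(), intensity_au = numeric(),
                      area_px = integer(), centroid_row = numeric(),
                      centroid_col = numeric(), source_field = character())
  if (!any(zm) || nrow(regions$regions) == 0) return(empty)
  dims <- dim(target$values)
  assigned <- vapply(seq_len(nrow(regions$regions)), function(i) {
    if (cfg$assignment == "centroid") {
      r <- round(regions$regions$centroid_row[i]) + 1L
      c <- round(regions$regions$centroid_col[i]) + 1L
      zm[r, c]
    } else {
      mean(zm[regions$pixels[[i]]]) >= cfg$min_overlap_frac
    }
  }, logical(1))
  idx <- which(assigned)
  if (!length(idx)) return(empty)
  rows <- lapply(idx, function(i) {
    pix <- regions$pixels[[i]]
    lpix <- if (isTRUE(cfg$length_halfmax))
      halfmax_subregion(pix, target$values, bg, dims, cfg$connectivity) else pix
    data.frame(id = regions$regions$label[i], zone_class = zone_class,
               length_nm = measure_length(lpix, target$pixel_size_nm, dim = dims),
               intensity_au = measure_intensity(pix, target, cfg$intensity_mode,
                                                background = bg),
               area_px = regions$regions$area_px[i],
               centroid_row = regions$regions$centroid_row[i],
               centroid_col = regions$regions$centroid_col[i],
               source_field = source_field)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Segment the target channel once for reuse across zones
#'
#' Threshold + size filter + label of the target channel with a
#' [nanodomain_config()]. The global background estimate (median of
#' sub-threshold pixels when `background = "auto"`) and the threshold ride
#' along as attributes, so several [extract_nanodomains()] calls on
#' different zone masks can share one segmentation.
#'
#' @param target `pixel_image` of the target protein.
#' @param cfg A [nanodomain_config()].
#' @return A `labeled_regions` with attributes `background` and `threshold`.
#' @export
segment_target <- function(target, cfg = nanodomain_config()) {
  m <- threshold_image(target, cfg$threshold_method, cfg$threshold_param)
  thr <- m$provenance$threshold
  maxa <- cfg$max_area_px %||% (1e6 / target$pixel_size_nm^2)
  m <- size_filter(m, cfg$min_area_px, maxa, connectivity = cfg$connectivity)
  lab <- label_regions(m, connectivity = cfg$connectivity)
  bg <- if (identical(cfg$background, "auto")) {
    sub <- target$values[target$values <= thr]
    if (length(sub)) stats::median(sub) else 0
  } else as.numeric(cfg$background)
  attr(lab, "background") <- bg
  attr(lab, "threshold") <- thr
  lab
}

#' Centroid-to-centroid intensity line profile
#'
#' Samples every channel along the straight segment between a presynaptic
#' and a postsynaptic centroid (0-based `(x, y)` pixel coordinates), at one
#' sample per pixel of path length with bilinear interpolation, averaging
#' over `width_px` parallel lines placed symmetrically across the segment.
#' The abscissa is converted to micrometres and each channel is normalized
#' to its own maximum (identically-zero channels stay 0).
#'
#' @param images Named list of `pixel_image` objects on one grid.
#' @param pre_centroid_px,post_centroid_px Numeric `(x, y)` pairs, 0-based.
#' @param width_px Odd number of parallel sampling lines (default 1).
#' @return A `line_profile`: data frame with `position_um` and one column
#'   per channel.
#' @export
line_scan <- function(images, pre_centroid_px, post_centroid_px, width_px = 1) {
  if (inherits(images, "pixel_image")) images <- list(images)
  a <- as.numeric(pre_centroid_px); b <- as.numeric(post_centroid_px)
  L <- sqrt(sum((b - a)^2))
  if (L == 0) stop("pre and post centroids coincide")
  px <- images[[1]]$pixel_size_nm
  n <- max(2L, ceiling(L) + 1L)
  t <- seq(0, 1, length.out = n)
  u <- (b - a) / L; perp <- c(-u[2], u[1])
  offs <- seq_len(width_px) - (width_px + 1) / 2
  prof <- lapply(images, function(img) {
    acc <- numeric(n)
    for (o in offs) {
      xs <- a[1] + t * (b[1] - a[1]) + o * perp[1]
      ys <- a[2] + t * (b[2] - a[2]) + o * perp[2]
      acc <- acc + bilinear_sample(img$values, xs, ys)
    }
    v <- acc / width_px
    if (max(v) > 0) v / max(v) else v
  })
  out <- data.frame(position_um = t * L * px / 1000)
  nm <- names(images) %||% vapply(images, function(i) i$channel, character(1))
  if (is.null(names(images)) || any(names(images) == ""))
    nm <- vapply(images, function(i) i$channel, character(1))
  for (k in seq_along(prof)) out[[nm[k]]] <- prof[[k]]
  class(out) <- c("line_profile", "data.frame")
  out
}

# Bilinear interpolation at 0-based (x, y) = (col, row) positions; clamped at
# the border.
bilinear_sample <- function(m, xs, ys) {
  nr <- nrow(m); nc <- ncol(m)
  xs <- pmin(pmax(xs, 0), nc - 1); ys <- pmin(pmax(ys, 0), nr - 1)
  x0 <- floor(xs); y0 <- floor(ys)
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  fx <- xs - x0; fy <- ys - y0
  v00 <- m[cbind(y0 + 1, x0 + 1)]; v01 <- m[cbind(y0 + 1, x1 + 1)]
  v10 <- m[cbind(y1 + 1, x0 + 1)]; v11 <- m[cbind(y1 + 1, x1 + 1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}
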