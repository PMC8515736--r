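mask_values <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$values
  else if (is.logical(mask) && is.matrix(mask)) mask
  else stop("expected a binary_mask or logical matrix")
}

new_binary_mask <- function(values, pixel_size_nm, provenance = list()) {
  structure(list(values = values, pixel_size_nm = pixel_size_nm,
                 provenance = provenance), class = "binary_mask")
}

#' Construct a binary mask
#'
#' Masks normally come out of [threshold_image()] with their provenance
#' filled in; this constructor covers externally defined regions of
#' interest (e.g. a full-field scope or a hand-drawn mask).
#'
#' @param values Logical matrix.
#' @param pixel_size_nm Physical pixel size (nm).
#' @param provenance Optional named list describing the mask's origin.
#' @return A `binary_mask`.
#' @export
binary_mask <- function(values, pixel_size_nm, provenance = list(method = "manual")) {
  if (!is.logical(values) || !is.matrix(values))
    stop("`values` must be a logical matrix")
  new_binary_mask(values, pixel_size_nm, provenance)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px (%.2f%%)\n",
              nrow(x$values), ncol(x$values), sum(x$values),
              100 * mean(x$values)))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance),
                               vapply(x$provenance, function(v)
                                 paste(format(unlist(v)), collapse = "/"),
                                 character(1)),
                               sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Threshold an image into a binary mask
#'
#' The sequential segmentation paradigm starts by thresholding each channel to
#' keep regions of high molecular content. Two methods are provided: Otsu's
#' criterion (the candidate threshold over the image's unique values that
#' maximizes between-class variance) and a fixed intensity percentile. The
#' mask is `TRUE` strictly above the threshold, and the method + value are
#' recorded in the mask's provenance.
#'
#' @param img A `pixel_image`.
#' @param method `"otsu"` or `"percentile"`.
#' @param param For `"percentile"`: the percentile in (0, 100). Ignored for
#'   Otsu.
#' @return A `binary_mask`.
#' @export
threshold_image <- function(img, method = c("otsu", "percentile"),
                            param = NULL) {
  method <- match.arg(method)
  v <- img$values
  thr <- switch(method,
    otsu = {
      if (length(unique(as.vector(v))) < 2)
        stop("otsu thresholding needs at least 2 distinct intensity values")
      otsu_threshold(as.vector(v))
    },
    percentile = {
      if (is.null(param) || param <= 0 || param >= 100)
        stop("percentile thresholding needs `param` in (0, 100)")
      as.numeric(stats::quantile(v, param / 100, names = FALSE))
    })
  new_binary_mask(v > thr, img$pixel_size_nm,
                  provenance = list(channel = img$channel, method = method,
                                    threshold = thr,
                                    size_bounds = c(NA_real_, NA_real_)))
}

# Exact Otsu over the unique intensity values: maximizes between-class
# variance w0*w1*(mu0-mu1)^2 over splits {<= t} / {> t}. Vectorized via
# cumulative sums; ties broken toward the smallest qualifying threshold.
otsu_threshold <- function(v) {
  sv <- sort(v)
  n <- length(sv)
  u <- unique(sv)
  cnt <- tabulate(match(sv, u))
  cw <- cumsum(cnt)                       # pixels <= u[k]
  cs <- cumsum(cnt * u)                   # intensity sum <= u[k]
  k <- seq_len(length(u) - 1L)
  w0 <- cw[k] / n; w1 <- 1 - w0
  mu0 <- cs[k] / cw[k]
  mu1 <- (cs[length(u)] - cs[k]) / (n - cw[k])
  bcv <- w0 * w1 * (mu0 - mu1)^2
  u[which.max(bcv)]
}

#' Remove connected components outside an area range
#'
#' Keeps connected foreground components whose pixel area lies in
#' `[min_area_px, max_area_px]`; everything else is erased. Applying the same
#' bounds twice is a no-op.
#'
#' @param mask A `binary_mask`.
#' @param min_area_px,max_area_px Inclusive area bounds (pixels);
#'   `max_area_px` may be `Inf`.
#' @param connectivity 4 or 8 (default) neighbour connectivity.
#' @return A `binary_mask` with updated provenance.
#' @export
size_filter <- function(mask, min_area_px, max_area_px = Inf,
                        connectivity = 8) {
  if (min_area_px <= 0 || min_area_px > max_area_px)
    stop("need 0 < min_area_px <= max_area_px")
  lab <- label_regions(mask, connectivity = connectivity)
  keep <- lab$regions$label[lab$regions$area_px >= min_area_px &
                            lab$regions$area_px <= max_area_px]
  out <- lab$labels %in% keep & lab$labels > 0
  prov <- if (inherits(mask, "binary_mask")) mask$provenance else list()
  prov$size_bounds <- c(min_area_px, max_area_px)
  new_binary_mask(matrix(out, nrow(lab$labels), ncol(lab$labels)),
                  px_of(mask), provenance = prov)
}

px_of <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$pixel_size_nm
  else if (inherits(mask, "labeled_regions")) mask$pixel_size_nm
  else 1
}

#' Label connected components and compute region properties
#'
#' Connected-component labeling with selectable 4- or 8-neighbour
#' connectivity: foreground pixels become graph vertices, neighbour pairs
#' become edges, and regions are the graph's connected components,
#' relabelled to consecutive integers in raster order of first occurrence.
#' Per region: area, centroid (0-based pixel coordinates), bounding box and
#' pixel list.
#'
#' @param mask A `binary_mask` or logical matrix.
#' @param connectivity 4 or 8 (default).
#' @return A `labeled_regions` object: `$labels` integer matrix (0 =
#'   background), `$regions` data frame and `$pixels` (list of linear pixel
#'   index vectors per region).
#' @export
label_regions <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  m <- mask_values(mask)
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  fg <- which(m)
  if (length(fg)) {
    P <- matrix(0L, nr, nc)
    P[fg] <- seq_along(fg)
    # forward neighbour offsets only; the graph is undirected
    offs <- list(c(1, 0), c(0, 1))
    if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(-1, 1)))
    edges <- list()
    for (o in offs) {
      rs <- max(1, 1 + o[1]):min(nr, nr + o[1])
      cs <- max(1, 1 + o[2]):min(nc, nc + o[2])
      a <- P[rs - o[1], cs - o[2], drop = FALSE]
      b <- P[rs, cs, drop = FALSE]
      keep <- a > 0 & b > 0
      if (any(keep)) edges[[length(edges) + 1L]] <- rbind(a[keep], b[keep])
    }
    if (length(edges)) {
      g <- igraph::make_graph(as.vector(do.call(cbind, edges)),
                              n = length(fg), directed = FALSE)
      memb <- igraph::components(g)$membership
    } else memb <- seq_along(fg)
    first <- !duplicated(memb)
    relab <- integer(max(memb))
    relab[memb[first]] <- seq_len(sum(first))
    lab[fg] <- relab[memb]
  }
  build_labeled_regions(lab, px_of(mask))
}

build_labeled_regions <- function(lab, pixel_size_nm) {
  fg <- which(lab > 0)
  n <- if (length(fg)) max(lab[fg]) else 0L
  if (n > 0) {
    rows <- (fg - 1L) %% nrow(lab)          # 0-based row/col of each pixel
    cols <- (fg - 1L) %/% nrow(lab)
    by <- lab[fg]
    pixels <- split(fg, by)
    regions <- data.frame(
      label = seq_len(n),
      area_px = as.integer(tabulate(by, n)),
      centroid_row = as.numeric(tapply(rows, by, mean)),
      centroid_col = as.numeric(tapply(cols, by, mean)),
      bbox_row_min = as.integer(tapply(rows, by, min)),
      bbox_row_max = as.integer(tapply(rows, by, max)),
      bbox_col_min = as.integer(tapply(cols, by, min)),
      bbox_col_max = as.integer(tapply(cols, by, max)))
  } else {
    pixels <- list()
    regions <- data.frame(label = integer(), area_px = integer(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          bbox_row_min = integer(), bbox_row_max = integer(),
                          bbox_col_min = integer(), bbox_col_max = integer())
  }
  structure(list(labels = lab, regions = regions, pixels = pixels,
                 pixel_size_nm = pixel_size_nm), class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("<labeled_regions> %d regions, %d foreground px on %d x %d grid\n",
              nrow(x$regions), sum(x$labels > 0), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Classify target regions by overlap with reference regions
#'
#' Mask-transfer classification: a target region that shares at least
#' `min_overlap_px` pixels with some single reference region is `positive`;
#' a target region without such overlap is `false_positive`; a reference
#' region with no qualifying target overlap contributes one `negative`.
#' With the default `min_overlap_px = 1` this is a pure presence/absence
#' call.
#'
#' @param reference,target `labeled_regions` on the same grid.
#' @param min_overlap_px Minimum shared pixels with one reference region.
#' @return An `overlap_classification`: `$target_classes` data frame (label,
#'   class, overlap_px = largest single-reference overlap, overlap_fraction
#'   of the target's area), `$counts` named vector
#'   (positive/false_positive/negative).
#' @export
classify_overlap <- function(reference, target, min_overlap_px = 1) {
  if (!identical(dim(reference$labels), dim(target$labels)))
    stop("reference and target grids differ in shape")
  both <- reference$labels > 0 & target$labels > 0
  nt <- nrow(target$regions); nref <- nrow(reference$regions)
  best <- integer(nt)            # max overlap with any one reference region
  matched_ref <- logical(nref)
  if (any(both)) {
    tab <- table(ref = reference$labels[both], tgt = target$labels[both])
    for (j in colnames(tab)) {
      tj <- as.integer(j)
      ov <- tab[, j]
      best[tj] <- max(ov)
      hit <- as.integer(rownames(tab)[ov >= min_overlap_px])
      matched_ref[hit] <- TRUE
    }
  }
  cls <- ifelse(best >= min_overlap_px, "positive", "false_positive")
  target_classes <- data.frame(
    label = target$regions$label,
    class = if (nt) cls else character(),
    overlap_px = best,
    overlap_fraction = if (nt) best / target$regions$area_px else numeric())
  counts <- c(positive = sum(cls == "positive"),
              false_positive = sum(cls == "false_positive"),
              negative = sum(!matched_ref))
  structure(list(target_classes = target_classes, counts = counts,
                 min_overlap_px = min_overlap_px),
            class = "overlap_classification")
}

#' @export
print.overlap_classification <- function(x, ...) {
  cat(sprintf("<overlap_classification> positive=%d false_positive=%d negative=%d (min_overlap_px=%d)\n",
              x$counts["positive"], x$counts["false_positive"],
              x$counts["negative"], x$min_overlap_px))
  invisible(x)
}

#' Segmentation parameters for zone and nanodomain detection
#'
#' @param threshold_method `"otsu"` (default) or `"percentile"`.
#' @param threshold_param Percentile when `threshold_method = "percentile"`.
#' @param min_area_px,max_area_px Size-filter bounds. The default maximum is
#'   the pixel area of 1 um^2 at the image's pixel size (resolved at call
#'   time when `NULL`).
#' @param connectivity 4 or 8 (default).
#' @param min_overlap_px Overlap-classification threshold (pixels).
#' @return A `seg_config` list.
#' @export
seg_config <- function(threshold_method = "otsu", threshold_param = NULL,
                       min_area_px = 4, max_area_px = NULL,
                       connectivity = 8, min_overlap_px = 1) {
  structure(list(threshold_method = threshold_method,
                 threshold_param = threshold_param,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 connectivity = connectivity, min_overlap_px = min_overlap_px),
            class = "seg_config")
}

resolve_max_area <- function(cfg, pixel_size_nm) {
  cfg$max_area_px %||% (1e6 / pixel_size_nm^2)   # 1 um^2 in pixels
}

#' Threshold, size-filter and label one channel
#'
#' Convenience composition of [threshold_image()], [size_filter()] and
#' [label_regions()] with a [seg_config()].
#'
#' @param img A `pixel_image`.
#' @param cfg A [seg_config()].
#' @return A `labeled_regions`.
#' @export
segment_channel <- function(img, cfg = seg_config()) {
  m <- threshold_image(img, cfg$threshold_method, cfg$threshold_param)
  m <- size_filter(m, cfg$min_area_px, resolve_max_area(cfg, img$pixel_size_nm),
                   connectivity = cfg$connectivity)
  label_regions(m, connectivity = cfg$connectivity)
}

#' Detect synapse-associated endocytic zones
#'
#' Sequential segmentation across imaging modalities: the (confocal) PSD
#' channel and the (STED) endocytic-marker channel are each thresholded,
#' size-filtered and labelled; endocytic regions are then classified against
#' the PSD regions by mask transfer, and the union of `positive` endocytic
#' regions is returned as the synapse-associated endocytic-zone mask.
#' Endocytic regions away from any PSD are discarded as false positives.
#'
#' @param psd_confocal `pixel_image` of the postsynaptic-density marker.
#' @param dynamin_sted `pixel_image` of the endocytic marker.
#' @param cfg A [seg_config()] applied to both channels.
#' @return A `binary_mask` of synaptic endocytic zones; the classification is
#'   attached as attribute `"classification"`.
#' @export
detect_synaptic_ez <- function(psd_confocal, dynamin_sted, cfg = seg_config()) {
  stopifnot_same_grid(psd_confocal, dynamin_sted)
  ref <- segment_channel(psd_confocal, cfg)
  tgt <- segment_channel(dynamin_sted, cfg)
  cl <- classify_overlap(ref, tgt, min_overlap_px = cfg$min_overlap_px)
  pos <- cl$target_classes$label[cl$target_classes$class == "positive"]
  out <- tgt$labels %in% pos & tgt$labels > 0
  mask <- new_binary_mask(matrix(out, nrow(tgt$labels), ncol(tgt$labels)),
                          dynamin_sted$pixel_size_nm,
                          provenance = list(channel = dynamin_sted$channel,
                                            method = "detect_synaptic_ez",
                                            threshold = cfg$threshold_method,
                                            size_bounds = c(cfg$min_area_px,
                                                            resolve_max_area(cfg, dynamin_sted$pixel_size_nm))))
  attr(mask, "classification") <- cl
  mask
}

#' Keep primary regions that touch a partner mask
#'
#' Mask-transfer validation: labelled primary regions are transferred onto
#' the partner channel's binary mask and only those whose pixel set
#' intersects it are retained (e.g. endocytic-marker regions validated by a
#' second endocytic marker). Regions without partner signal are dropped.
#'
#' @param primary A `labeled_regions`.
#' @param partner_mask A `binary_mask` on the same grid.
#' @return A `binary_mask` of retained primary regions; retained labels in
#'   attribute `"retained"`.
#' @export
filter_by_partner <- function(primary, partner_mask) {
  pm <- mask_values(partner_mask)
  if (!identical(dim(primary$labels), dim(pm)))
    stop("primary and partner grids differ in shape")
  hit <- sort(unique(primary$labels[primary$labels > 0 & pm]))
  out <- primary$labels %in% hit & primary$labels > 0
  mask <- new_binary_mask(matrix(out, nrow(pm), ncol(pm)), px_of(primary),
                          provenance = list(method = "filter_by_partner"))
  attr(mask, "retained") <- hit
  mask
}
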