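toy_image <- function(values, px = 25, channel = "t")
  pixel_image(values, px, channel = channel)

test_that("otsu separates a clean bimodal image and matches the brute-force scan", {
  set.seed(11)
  v <- matrix(10, 20, 20)
  hi <- sample(400, 40)
  v[hi] <- 100
  img <- toy_image(v)
  m <- threshold_image(img, "otsu")
  expect_identical(which(m$values), sort(hi))
  expect_equal(m$provenance$threshold, oracle_otsu(v))

  for (s in 1:5) {   # irregular intensity mixtures against the oracle
    set.seed(s)
    v <- matrix(rlnorm(16 * 16, 3, 1), 16, 16)
    img <- toy_image(v)
    m <- threshold_image(img, "otsu")
    t_star <- oracle_otsu(v)
    expect_equal(m$provenance$threshold, t_star)
    expect_identical(m$values, v > t_star)
  }
  expect_error(threshold_image(toy_image(matrix(5, 4, 4)), "otsu"),
               "distinct")
})

test_that("percentile thresholding keeps the expected foreground fraction", {
  v <- matrix(0:255, 16, 16)
  m <- threshold_image(toy_image(v), "percentile", 90)
  expect_lt(abs(mean(m$values) - 0.1), 1 / 16)
  expect_error(threshold_image(toy_image(v), "percentile"), "param")
})

test_that("size filter keeps exactly the in-range components and is idempotent", {
  m <- matrix(FALSE, 40, 40)
  m[2, 2:3] <- TRUE                       # area 2
  m[10:14, 10:11] <- TRUE                 # area 10
  m[20:39, 16:40] <- TRUE                 # area 500
  msk <- nanozone:::new_binary_mask(m, 25)
  out <- size_filter(msk, 4, 100)
  expect_equal(sum(out$values), 10)
  expect_true(all(out$values[10:14, 10:11]))
  ident <- size_filter(msk, 1, Inf)
  expect_identical(ident$values, m)
  twice <- size_filter(size_filter(msk, 4, 100), 4, 100)
  expect_identical(twice$values, out$values)
  expect_equal(out$provenance$size_bounds, c(4, 100))
  expect_error(size_filter(msk, 0, 10), "min_area_px")
})

test_that("labeling matches flood fill for both connectivities and EBImage for 4", {
  set.seed(42)
  for (k in 1:4) {
    msk <- random_mask(64, 64, p = 0.35)
    for (conn in c(4, 8)) {
      lab <- label_regions(msk, connectivity = conn)
      oracle <- oracle_flood_label(msk$values, conn)
      expect_equal(nrow(lab$regions), max(oracle))
      # identical partitions: one-to-one mapping between label sets
      pair <- paste(lab$labels[msk$values], oracle[msk$values])
      expect_equal(length(unique(pair)), max(oracle))
      expect_equal(sum(lab$regions$area_px), sum(msk$values))
    }
    lab4 <- label_regions(msk, connectivity = 4)
    eb <- EBImage::bwlabel(msk$values * 1)
    expect_equal(nrow(lab4$regions), max(eb))
  }
})

test_that("size-filtered component counts match flood-fill enumeration per connectivity", {
  set.seed(7)
  msk <- random_mask(64, 64, p = 0.3)
  for (conn in c(4, 8)) {
    out <- size_filter(msk, 5, 20, connectivity = conn)
    oracle <- oracle_flood_label(msk$values, conn)
    sizes <- tabulate(oracle[oracle > 0])
    keep <- which(sizes >= 5 & sizes <= 20)
    expect_equal(sum(out$values), sum(sizes[keep]))
    n_after <- max(oracle_flood_label(out$values, conn))
    expect_equal(n_after, length(keep))
  }
})

test_that("region properties: empty mask, two squares, centroids", {
  empty <- label_regions(matrix(FALSE, 8, 8))
  expect_equal(nrow(empty$regions), 0)
  m <- matrix(FALSE, 12, 12)
  m[2:4, 2:4] <- TRUE; m[8:10, 8:10] <- TRUE
  lab <- label_regions(m)
  expect_equal(lab$regions$area_px, c(9L, 9L))
  expect_equal(lab$regions$centroid_row, c(2, 8))   # 0-based centres
  expect_equal(lab$regions$centroid_col, c(2, 8))
})

test_that("overlap classification implements the positive/negative/false-positive rule", {
  ref <- matrix(FALSE, 20, 20); tgt <- matrix(FALSE, 20, 20)
  ref[2:6, 2:6] <- TRUE          # A, overlapped by B
  ref[14:18, 14:18] <- TRUE      # D, untouched
  tgt[5:8, 2:6] <- TRUE          # B, overlaps A on rows 5:6 x cols 2:6 = 10 px
  tgt[12:13, 2:3] <- TRUE        # C, disjoint
  cl <- classify_overlap(label_regions(ref), label_regions(tgt),
                         min_overlap_px = 1)
  expect_equal(unname(cl$counts), c(1L, 1L, 1L))
  tc <- cl$target_classes
  expect_equal(tc$class[tc$overlap_px == 10], "positive")
  expect_equal(tc$class[tc$overlap_px == 0], "false_positive")

  none <- classify_overlap(label_regions(matrix(FALSE, 20, 20)),
                           label_regions(tgt))
  expect_equal(unname(none$counts["positive"]), 0L)
  expect_equal(unname(none$counts["false_positive"]), 2L)
  expect_equal(unname(none$counts["negative"]), 0L)
  expect_error(classify_overlap(label_regions(ref),
                                label_regions(matrix(FALSE, 5, 5))),
               "shape")
})

test_that("overlap classes equal exhaustive per-region intersection enumeration", {
  set.seed(99)
  for (k in 1:10) {
    ref <- label_regions(EBImage::dilate(random_mask(48, 48, 0.08)$values,
                                         EBImage::makeBrush(3, "box")) > 0)
    tgt <- label_regions(EBImage::dilate(random_mask(48, 48, 0.08)$values,
                                         EBImage::makeBrush(3, "box")) > 0)
    min_ov <- sample(1:3, 1)
    cl <- classify_overlap(ref, tgt, min_overlap_px = min_ov)
    # oracle: per target region, intersect explicitly with every ref region
    pos <- fp <- 0; matched <- rep(FALSE, nrow(ref$regions))
    for (i in seq_len(nrow(tgt$regions))) {
      hit <- FALSE
      for (j in seq_len(nrow(ref$regions))) {
        ov <- length(intersect(tgt$pixels[[i]], ref$pixels[[j]]))
        if (ov >= min_ov) { hit <- TRUE; matched[j] <- TRUE }
      }
      if (hit) pos <- pos + 1 else fp <- fp + 1
    }
    expect_equal(unname(cl$counts),
                 c(pos, fp, sum(!matched)))
  }
})

test_that("classification is complete: every target classified, every reference accounted", {
  set.seed(3)
  ref <- label_regions(random_mask(32, 32, 0.2)$values)
  tgt <- label_regions(random_mask(32, 32, 0.2)$values)
  cl <- classify_overlap(ref, tgt)
  expect_equal(unname(cl$counts["positive"] + cl$counts["false_positive"]),
               nrow(tgt$regions))
  expect_true(cl$counts["negative"] <= nrow(ref$regions))
})

test_that("raising the threshold never enlarges the foreground", {
  set.seed(8)
  img <- toy_image(matrix(rlnorm(900, 3, 0.8), 30, 30))
  fg <- sapply(c(50, 70, 90, 97), function(p)
    sum(threshold_image(img, "percentile", p)$values))
  expect_true(all(diff(fg) <= 0))
})

test_that("synaptic EZ detection keeps only endocytic regions apposed to a PSD", {
  geom <- list(caz = list(semi_axes_nm = c(150, 100)),
               psd = list(semi_axes_nm = c(150, 100)),
               ez  = list(semi_axes_nm = c(100, 75)),
               apposition_nm = 150, ez_offset_nm = 40)  # EZ abuts the PSD
  cfg <- sim_config(field_size_px = c(384, 384), n_synapses = 8,
                    zone_geometry = geom, marker_density = 14,
                    shot_noise = FALSE, read_noise_sd = 0, seed = 15)
  gt <- simulate_field(cfg)
  # confocal PSD view: same emitters as the psd channel, wider PSF
  gt_conf <- gt
  gt_conf$emitters$channel[gt_conf$emitters$channel == "psd"] <- "psd_confocal"
  psd <- render_channel(gt_conf, "psd_confocal", cfg)
  dyn <- render_channel(gt, "ez", cfg)
  ez_mask <- detect_synaptic_ez(psd, dyn, seg_config(min_area_px = 4))
  # every true EZ zone has nearby PSD here, so recall should be complete
  ez_zones <- gt$zones[gt$zones$class == "ez", ]
  px <- cfg$pixel_size_nm
  hits <- mapply(function(x, y) {
    r <- round(y / px) + 1; c <- round(x / px) + 1
    any(ez_mask$values[max(1, r - 3):min(384, r + 3),
                       max(1, c - 3):min(384, c + 3)])
  }, ez_zones$center_x_nm, ez_zones$center_y_nm)
  expect_true(all(hits))
  cl <- attr(ez_mask, "classification")
  expect_gt(cl$counts["positive"], 0)
  # empty endocytic channel gives an empty mask
  empty_dyn <- pixel_image(matrix(c(0, rep(1, 384 * 384 - 1)), 384, 384), px,
                           channel = "ez")
  expect_equal(sum(detect_synaptic_ez(psd, empty_dyn,
                                      seg_config(min_area_px = 4))$values), 0)
})

test_that("endocytic regions far from any PSD are rejected", {
  px <- 25
  psd <- matrix(1, 200, 200); dyn <- matrix(1, 200, 200)
  psd[20:30, 20:30] <- 300                    # one PSD
  dyn[24:34, 24:34] <- 300                    # apposed EZ (overlaps PSD mask)
  dyn[150:160, 150:160] <- 300                # orphan EZ, no PSD anywhere near
  ez <- detect_synaptic_ez(pixel_image(psd, px, channel = "psd"),
                           pixel_image(dyn, px, channel = "dyn"),
                           seg_config(min_area_px = 4))
  expect_true(any(ez$values[24:34, 24:34]))
  expect_false(any(ez$values[150:160, 150:160]))
})

test_that("partner filtering equals the brute-force per-region intersection test", {
  set.seed(101)
  for (k in 1:10) {
    prim <- label_regions(EBImage::dilate(random_mask(48, 48, 0.06)$values,
                                          EBImage::makeBrush(3, "box")) > 0)
    part <- random_mask(48, 48, 0.15)
    out <- filter_by_partner(prim, part)
    keep_oracle <- integer(0)
    for (i in seq_len(nrow(prim$regions)))
      if (any(part$values[prim$pixels[[i]]]))
        keep_oracle <- c(keep_oracle, prim$regions$label[i])
    expect_identical(attr(out, "retained"), keep_oracle)
    expect_identical(out$values, matrix(prim$labels %in% keep_oracle &
                                          prim$labels > 0, 48, 48))
  }
  prim <- label_regions(matrix(c(TRUE, rep(FALSE, 63)), 8, 8))
  expect_equal(sum(filter_by_partner(prim,
    nanozone:::new_binary_mask(matrix(FALSE, 8, 8), 25))$values), 0)
})
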