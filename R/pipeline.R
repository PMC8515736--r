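#' Configuration of a full zone-analysis run
#'
#' Bundles the simulation (or input images), segmentation, nanodomain,
#' colocalization and statistics parameters of one reproducible run. The
#' persisted config snapshot plus the seed fully determine every output.
#'
#' @param sim A [sim_config()] describing the synthetic field, or `NULL`
#'   when `images` are supplied.
#' @param images Optional named list of `pixel_image`s with channels
#'   `target`, `caz`, `psd`, `ez` (acquired data path).
#' @param seg A [seg_config()] for the zone-marker channels.
#' @param nano A [nanodomain_config()] for the target channel.
#' @param coloc A [coloc_config()].
#' @param outdir Output directory, or `NULL` to keep results in memory.
#' @param seed Overrides `sim$seed` when given.
#' @return A `zone_run_config`.
#' @export
zone_run_config <- function(sim = sim_config(), images = NULL,
                            seg = seg_config(), nano = nanodomain_config(),
                            coloc = coloc_config(), outdir = NULL,
                            seed = NULL) {
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, images = images, seg = seg, nano = nano,
                 coloc = coloc, outdir = outdir,
                 seed = if (!is.null(sim)) sim$seed else seed),
            class = "zone_run_config")
}

zone_marker <- c(pre = "caz", post = "psd", peri = "ez")

#' Run the functional-zone analysis pipeline
#'
#' Stages (each logged with region counts): simulate or load the field;
#' segment each zone-marker channel into its zone mask; extract target
#' nanodomains per zone class (pre/post/peri); compute per-region
#' resolution-scaled colocalization of the target against each marker within
#' its zones; compare zones statistically (Kruskal-Wallis + Dunn on
#' nanodomain length and intensity, one-way ANOVA + Tukey on per-region RSP
#' and RSE). With an output directory, persists tidy CSVs, a JSON stats
#' report and a manifest holding the config snapshot and seed; reruns with
#' the same config + seed are byte-identical.
#'
#' @param cfg A [zone_run_config()].
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list: `ground_truth` (when simulated), `images`,
#'   `zone_masks`, `nanodomains` (data frame), `coloc` (data frame),
#'   `stats` (list of `test_result`s), `summaries`, `outdir`.
#' @export
run_zone_analysis <- function(cfg, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[3]
  gt <- NULL
  if (!is.null(cfg$images)) {
    imgs <- cfg$images
  } else {
    gt <- simulate_field(cfg$sim)
    imgs <- list()
    for (ch in c("target", "caz", "psd", "ez"))
      imgs[[ch]] <- render_channel(gt, ch)
    say("simulated %d zones, %d emitters [%.1fs]", nrow(gt$zones),
        nrow(gt$emitters), proc.time()[3] - t0)
  }
  missing <- setdiff(c("target", zone_marker), names(imgs))
  if (length(missing))
    stop("missing channel role(s): ", paste(missing, collapse = ", "),
         "; required: target, caz, psd, ez")

  zone_masks <- list()
  for (zc in names(zone_marker)) {
    lab <- segment_channel(imgs[[zone_marker[[zc]]]], cfg$seg)
    zone_masks[[zc]] <- new_binary_mask(lab$labels > 0, px_of(lab),
      provenance = list(channel = zone_marker[[zc]],
                        method = cfg$seg$threshold_method))
    say("zone %s (%s): %d regions", zc, zone_marker[[zc]], nrow(lab$regions))
  }

  tgt_lab <- segment_target(imgs$target, cfg$nano)
  say("target channel: %d candidate nanodomains", nrow(tgt_lab$regions))
  nd <- do.call(rbind, lapply(names(zone_marker), function(zc)
    extract_nanodomains(imgs$target, zone_masks[[zc]], zc, cfg$nano,
                        regions = tgt_lab)))
  if (is.null(nd)) nd <- extract_nanodomains(imgs$target,
    new_binary_mask(matrix(TRUE, 1, 1), 1), "none", cfg$nano)[0, ]
  # a region whose centroid sits in two overlapping zone masks is kept only
  # in the zone holding the larger share of its pixels
  if (anyDuplicated(nd$id)) {
    frac <- vapply(seq_len(nrow(nd)), function(i)
      mean(mask_values(zone_masks[[nd$zone_class[i]]])[
        tgt_lab$pixels[[nd$id[i]]]]), numeric(1))
    keep <- unlist(lapply(split(seq_len(nrow(nd)), nd$id), function(ii)
      ii[which.max(frac[ii])]), use.names = FALSE)
    nd <- nd[sort(keep), , drop = FALSE]
    rownames(nd) <- NULL
  }
  say("assigned nanodomains: %s",
      paste(names(table(nd$zone_class)), table(nd$zone_class),
            sep = "=", collapse = ", "))

  coloc_rows <- list()
  for (zc in names(zone_marker)) {
    res <- tryCatch(
      compute_rsp_rse(imgs$target, imgs[[zone_marker[[zc]]]],
                      zone_masks[[zc]], cfg$coloc),
      error = function(e) NULL)
    if (!is.null(res)) {
      pr <- res$per_region
      pr$zone_class <- zc
      coloc_rows[[zc]] <- pr
    }
  }
  coloc <- if (length(coloc_rows)) do.call(rbind, coloc_rows) else NULL
  if (!is.null(coloc)) rownames(coloc) <- NULL

  stats_out <- list()
  if (length(unique(nd$zone_class)) >= 2 &&
      all(table(nd$zone_class) >= 2)) {
    stats_out$length_kw_dunn <-
      kruskal_dunn(group_table(nd$length_nm, nd$zone_class))
    stats_out$intensity_kw_dunn <-
      kruskal_dunn(group_table(nd$intensity_au, nd$zone_class))
  }
  if (!is.null(coloc) && length(unique(coloc$zone_class)) >= 2 &&
      all(table(coloc$zone_class) >= 2)) {
    stats_out$rsp_anova_tukey <-
      anova_tukey(group_table(coloc$rsp, coloc$zone_class))
    stats_out$rse_anova_tukey <-
      anova_tukey(group_table(coloc$rse, coloc$zone_class))
  }
  summaries <- lapply(split(nd$length_nm, nd$zone_class), summarize_values)

  out <- list(ground_truth = gt, images = imgs, zone_masks = zone_masks,
              nanodomains = nd, coloc = coloc, stats = stats_out,
              summaries = summaries, outdir = cfg$outdir)
  if (!is.null(cfg$outdir)) persist_run(out, cfg, kind = "zone")
  say("done [%.1fs]", proc.time()[3] - t0)
  invisible(out)
}

#' Configuration of a partner-association run
#'
#' Two-channel neuronal-process acquisitions of the target protein with one
#' interaction partner each (e.g. the catalytic subunit and the substrate
#' precursor), simulated with planted partner-association fractions.
#'
#' @param sim Base [sim_config()] (field, noise, distributions).
#' @param partners Named list; per partner a list with optional entries
#'   `independent_fraction` (planted fraction of target spots with no nearby
#'   partner), `length_dist`, `intensity_dist` overrides for the target spots
#'   of that acquisition.
#' @param n_target Target spots per acquisition.
#' @param jitter_nm Partner placement jitter around associated target spots.
#' @param proximity_nm Association radius: a target nanodomain whose centroid
#'   lies within this distance of partner-positive pixels counts as
#'   partner-associated.
#' @param nano A [nanodomain_config()].
#' @param coloc A [coloc_config()].
#' @param outdir,seed As in [zone_run_config()].
#' @return A `partner_run_config`.
#' @export
partner_run_config <- function(sim = sim_config(),
                               partners = list(ps1 = list(independent_fraction = 0.3),
                                               app = list(independent_fraction = 0.3)),
                               n_target = 150, jitter_nm = 40,
                               proximity_nm = 150,
                               nano = nanodomain_config(),
                               coloc = coloc_config(), outdir = NULL,
                               seed = NULL) {
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, partners = partners, n_target = n_target,
                 jitter_nm = jitter_nm, proximity_nm = proximity_nm,
                 nano = nano, coloc = coloc, outdir = outdir,
                 seed = sim$seed),
            class = "partner_run_config")
}

#' Run the partner-association analysis pipeline
#'
#' For each partner channel: simulate the process field with its planted
#' independent fraction, segment the target channel, associate each target
#' nanodomain with the partner by proximity of its centroid to
#' partner-positive pixels, and compute per-region RSP/RSE of target vs
#' partner over the target-positive regions. Across the two partners:
#' Mann-Whitney on nanodomain length and intensity of the associated
#' domains, Welch's t on per-region RSP and RSE, and the fraction of target
#' nanodomains not associated with the partner (the "independent" subset).
#'
#' @param cfg A [partner_run_config()].
#' @param quiet Suppress log messages.
#' @return Invisibly: `nanodomains` (with `partner`, `associated` columns),
#'   `independent_fraction` (named, per partner), `coloc`, `stats`,
#'   `ground_truth` per partner.
#' @export
run_partner_analysis <- function(cfg, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  nd_all <- list(); coloc_all <- list(); gts <- list()
  indep_frac <- c()
  for (p in names(cfg$partners)) {
    ps <- cfg$partners[[p]]
    sim <- cfg$sim
    sim$seed <- as.integer(channel_seed(cfg$seed, p) %% 2147483647)
    if (!is.null(ps$length_dist)) sim$length_dist <- ps$length_dist
    if (!is.null(ps$intensity_dist)) sim$intensity_dist <- ps$intensity_dist
    gt <- simulate_partner_field(sim, n_target = cfg$n_target,
                                 partner_channel = p,
                                 independent_fraction = ps$independent_fraction %||% 0.3,
                                 jitter_nm = cfg$jitter_nm)
    gts[[p]] <- gt
    tgt <- render_channel(gt, "target", sim)
    par <- render_channel(gt, p, sim)
    full <- new_binary_mask(matrix(TRUE, nrow(tgt$values), ncol(tgt$values)),
                            tgt$pixel_size_nm,
                            provenance = list(method = "full-field"))
    tgt_lab <- segment_target(tgt, cfg$nano)
    nd <- extract_nanodomains(tgt, full, paste0("partner:", p), cfg$nano,
                              regions = tgt_lab, source_field = p)
    par_mask <- threshold_image(par, cfg$nano$threshold_method,
                                cfg$nano$threshold_param)
    par_mask <- size_filter(par_mask, cfg$nano$min_area_px,
                            cfg$nano$max_area_px %||% (1e6 / par$pixel_size_nm^2),
                            connectivity = cfg$nano$connectivity)
    d_nm <- partner_distance_nm(nd, par_mask)
    nd$partner <- p
    nd$associated <- d_nm <= cfg$proximity_nm
    indep_frac[p] <- if (nrow(nd)) mean(!nd$associated) else NA_real_
    say("partner %s: %d target domains, independent fraction %.3f",
        p, nrow(nd), indep_frac[p])
    nd_all[[p]] <- nd
    scope <- new_binary_mask(tgt_lab$labels > 0, tgt$pixel_size_nm,
                             provenance = list(method = "target-positive"))
    res <- tryCatch(compute_rsp_rse(tgt, par, scope, cfg$coloc),
                    error = function(e) NULL)
    if (!is.null(res)) { pr <- res$per_region; pr$partner <- p
                         coloc_all[[p]] <- pr }
  }
  nd <- do.call(rbind, nd_all); rownames(nd) <- NULL
  coloc <- if (length(coloc_all)) do.call(rbind, coloc_all) else NULL
  if (!is.null(coloc)) rownames(coloc) <- NULL

  stats_out <- list()
  ps <- names(cfg$partners)
  if (length(ps) == 2) {
    a <- nd[nd$partner == ps[1] & nd$associated, ]
    b <- nd[nd$partner == ps[2] & nd$associated, ]
    if (nrow(a) >= 2 && nrow(b) >= 2) {
      stats_out$length_mann_whitney <- mann_whitney(a$length_nm, b$length_nm)
      stats_out$intensity_mann_whitney <-
        mann_whitney(a$intensity_au, b$intensity_au)
    }
    if (!is.null(coloc)) {
      ca <- coloc[coloc$partner == ps[1], ]; cb <- coloc[coloc$partner == ps[2], ]
      if (nrow(ca) >= 2 && nrow(cb) >= 2) {
        stats_out$rsp_welch <- welch_t(ca$rsp, cb$rsp)
        stats_out$rse_welch <- welch_t(ca$rse, cb$rse)
      }
    }
  }
  out <- list(nanodomains = nd, independent_fraction = indep_frac,
              coloc = coloc, stats = stats_out, ground_truth = gts,
              outdir = cfg$outdir)
  if (!is.null(cfg$outdir)) persist_run(out, cfg, kind = "partner")
  invisible(out)
}

# Distance (nm) from each nanodomain centroid to the nearest partner-positive
# pixel, via a Euclidean distance transform of the partner-negative set.
partner_distance_nm <- function(nd, partner_mask) {
  pm <- mask_values(partner_mask)
  if (!nrow(nd)) return(numeric(0))
  if (!any(pm)) return(rep(Inf, nrow(nd)))
  dt <- EBImage::distmap(1 - pm)   # 0 on partner pixels
  idx <- cbind(round(nd$centroid_row) + 1L, round(nd$centroid_col) + 1L)
  dt[idx] * px_of(partner_mask)
}

test_result_to_list <- function(tr) {
  out <- list(test = tr$test_name, statistic = tr$statistic,
              p_value = tr$p_value, band = signif_band(tr$p_value))
  if (!is.null(tr$pairwise)) out$pairwise <- tr$pairwise
  if (!is.null(tr$method)) out$method <- tr$method
  out
}

persist_run <- function(out, cfg, kind) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(out$nanodomains, file.path(cfg$outdir, "nanodomains.csv"),
                   row.names = FALSE)
  if (!is.null(out$coloc))
    utils::write.csv(out$coloc, file.path(cfg$outdir, "coloc.csv"),
                     row.names = FALSE)
  jsonlite::write_json(lapply(out$stats, test_result_to_list),
                       file.path(cfg$outdir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(out$ground_truth)) {
    gts <- if (inherits(out$ground_truth, "ground_truth"))
      list(field = out$ground_truth) else out$ground_truth
    for (nm in names(gts))
      write_ground_truth(gts[[nm]], file.path(cfg$outdir, paste0("ground_truth_", nm)))
  }
  if (!is.null(out$images))
    write_pixel_images(out$images, file.path(cfg$outdir, "field.tif"))
  cfg_snapshot <- cfg
  cfg_snapshot$images <- NULL          # raster data lives in field.tif
  cfg_snapshot$outdir <- NULL          # location-independent snapshot
  manifest <- list(kind = kind, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("nanozone")),
                   config = unclass_config(cfg_snapshot))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg$outdir)
}

unclass_config <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_config)
    attributes(x) <- list(names = names(x))
    x
  } else x
}

#' Load a persisted run configuration from YAML
#'
#' The YAML mirrors the nested structure of [zone_run_config()] /
#' [partner_run_config()]; unknown keys are rejected. CLI flags override
#' file values.
#'
#' @param path YAML file.
#' @param kind `"zone"` or `"partner"`.
#' @return A run config object.
#' @export
read_run_config <- function(path, kind = c("zone", "partner")) {
  kind <- match.arg(kind)
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  if (!is.null(sim_args$psf_fwhm_nm)) sim_args$psf_fwhm_nm <- unlist(sim_args$psf_fwhm_nm)
  sim <- do.call(sim_config, sim_args)
  seg <- do.call(seg_config, y$segmentation %||% list())
  nano <- do.call(nanodomain_config, y$nanodomains %||% list())
  col <- do.call(coloc_config, y$colocalization %||% list())
  if (kind == "zone")
    zone_run_config(sim = sim, seg = seg, nano = nano, coloc = col,
                    outdir = y$outdir, seed = y$seed)
  else
    do.call(partner_run_config,
            c(list(sim = sim, nano = nano, coloc = col, outdir = y$outdir,
                   seed = y$seed),
              y[intersect(names(y), c("partners", "n_target", "jitter_nm",
                                      "proximity_nm"))]))
}
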