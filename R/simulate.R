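#' Configuration for a synthetic synapse-field simulation
#'
#' Describes a field of view containing `n_synapses` synapses, each built from
#' three elliptical functional zones: the cytomatrix at the active zone (CAZ,
#' presynaptic), the postsynaptic density (PSD) and the endocytic zone (EZ,
#' perisynaptic). Zones are populated with sub-diffraction Gaussian emitters
#' ("nanodomains") of the target protein; each zone's own marker channel is
#' populated with denser marker emitters so that the zone can be segmented
#' from its marker image. Sizes are physical (nm) and converted to pixels at
#' render time.
#'
#' Ground-truth nanodomain size is parameterized by the full width at half
#' maximum (FWHM) of the emitter's Gaussian profile before point-spread-
#' function (PSF) blurring; the rendered spot has
#' `sigma_eff^2 = sigma_emitter^2 + sigma_PSF^2` with `FWHM = 2.355 sigma`.
#'
#' @param field_size_px Integer pair, image height and width in pixels.
#' @param pixel_size_nm Physical pixel size (nm), default 25.
#' @param n_synapses Number of synapses to place.
#' @param zone_geometry List with per-zone ellipse semi-axes (nm) for
#'   `caz`, `psd`, `ez`, the CAZ-PSD apposition distance `apposition_nm`
#'   (centre-to-centre along the synaptic axis) and the lateral PSD-to-EZ
#'   offset `ez_offset_nm`.
#' @param nanodomain_density Poisson mean of target nanodomains per zone.
#' @param marker_density Poisson mean of marker emitters per zone (their own
#'   channel); denser than the target so the marker image fills the zone.
#' @param process_density Poisson mean of target nanodomains placed outside
#'   any synaptic zone ("process" spots) over the whole field.
#' @param length_dist Distribution of ground-truth emitter FWHM (nm):
#'   `list(name = "lognormal", meanlog=, sdlog=)` or
#'   `list(name = "constant", value=)`.
#' @param intensity_dist Distribution of emitter peak amplitude (a.u.), same
#'   forms as `length_dist`.
#' @param zone_length_dist,zone_intensity_dist Optional named lists of
#'   per-zone-class (`pre`/`post`/`peri`) distribution overrides for the
#'   target emitters, e.g. `list(post = list(name = "lognormal", meanlog =
#'   log(60), sdlog = 0.35))` to plant smaller postsynaptic domains.
#' @param psf_fwhm_nm Named numeric vector of per-channel PSF FWHM (nm).
#'   Defaults: STED-like 60 nm for `target`/`caz`/`psd`/`ez` and partner
#'   channels, confocal 250 nm for `psd_confocal`.
#' @param shot_noise Apply Poisson shot noise to the noiseless expectation?
#' @param read_noise_sd Standard deviation of additive Gaussian read noise.
#' @param background_level Uniform background level (a.u.).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   ground truth and images.
#' @return A `sim_config` list.
#' @export
sim_config <- function(field_size_px = c(256L, 256L),
                       pixel_size_nm = 25,
                       n_synapses = 10L,
                       zone_geometry = list(
                         caz = list(semi_axes_nm = c(150, 60)),
                         psd = list(semi_axes_nm = c(150, 60)),
                         ez  = list(semi_axes_nm = c(100, 75)),
                         apposition_nm = 180,
                         ez_offset_nm = 150),
                       nanodomain_density = 1.5,
                       marker_density = 12,
                       process_density = 0,
                       length_dist = list(name = "lognormal",
                                          meanlog = log(80), sdlog = 0.35),
                       intensity_dist = list(name = "lognormal",
                                             meanlog = log(150), sdlog = 0.5),
                       zone_length_dist = list(),
                       zone_intensity_dist = list(),
                       psf_fwhm_nm = c(target = 60, caz = 60, psd = 60, ez = 60,
                                       ps1 = 60, app = 60, psd_confocal = 250),
                       shot_noise = TRUE,
                       read_noise_sd = 2,
                       background_level = 10,
                       seed = 1L) {
  cfg <- list(field_size_px = as.integer(field_size_px),
              pixel_size_nm = pixel_size_nm, n_synapses = as.integer(n_synapses),
              zone_geometry = zone_geometry,
              nanodomain_density = nanodomain_density,
              marker_density = marker_density,
              process_density = process_density,
              length_dist = length_dist, intensity_dist = intensity_dist,
              zone_length_dist = zone_length_dist,
              zone_intensity_dist = zone_intensity_dist,
              psf_fwhm_nm = psf_fwhm_nm, shot_noise = isTRUE(shot_noise),
              read_noise_sd = read_noise_sd,
              background_level = background_level, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (any(cfg$field_size_px <= 0)) stop("field_size_px must be positive")
  if (cfg$pixel_size_nm <= 0) stop("pixel_size_nm must be positive")
  if (cfg$n_synapses < 0) stop("n_synapses must be non-negative")
  for (z in c("caz", "psd", "ez"))
    if (any(cfg$zone_geometry[[z]]$semi_axes_nm <= 0))
      stop("zone semi-axes must be strictly positive")
  if (cfg$nanodomain_density < 0 || cfg$marker_density < 0 ||
      cfg$process_density < 0) stop("densities must be non-negative")
  if (cfg$read_noise_sd < 0 || cfg$background_level < 0)
    stop("noise and background must be non-negative")
  if (any(cfg$psf_fwhm_nm / 2.355 < cfg$pixel_size_nm))
    warning("PSF sigma below one pixel for some channel: the PSF is undersampled")
  invisible(cfg)
}

draw_dist <- function(dist, n) {
  switch(dist$name,
         lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
         constant = rep(dist$value, n),
         gamma = stats::rgamma(n, shape = dist$shape, rate = dist$rate),
         stop("unknown distribution: ", dist$name))
}

zone_channel <- c(caz = "caz", psd = "psd", ez = "ez")
zone_class_of <- c(caz = "pre", psd = "post", ez = "peri")

# Uniform points inside an ellipse (semi-axes a,b, rotated by phi, centred at c)
runif_ellipse <- function(n, center, a, b, phi) {
  r <- sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
  x0 <- a * r * cos(th); y0 <- b * r * sin(th)
  cbind(x = center[1] + x0 * cos(phi) - y0 * sin(phi),
        y = center[2] + x0 * sin(phi) + y0 * cos(phi))
}

#' Simulate the ground truth of one synapse field
#'
#' Places synapses (CAZ + PSD ellipse pair separated by the apposition
#' distance, EZ offset laterally from the PSD) by rejection sampling so that
#' no two same-class zones overlap, then draws Poisson numbers of marker and
#' target emitters per zone and optional "process" emitters outside all
#' zones. Draw order (one RNG stream seeded from `config$seed`): synapse
#' geometry, then per-zone marker emitters, then per-zone target emitters
#' (zones in placement order), then process emitters.
#'
#' @param config A [sim_config()].
#' @return A `ground_truth` object: `$zones` (zone_id, class, centre,
#'   semi-axes, orientation) and `$emitters` (x_nm, y_nm, sigma_nm,
#'   amplitude_au, channel, zone_id, zone_class) data frames, plus the config.
#' @export
simulate_field <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_field_impl(config))
}

simulate_field_impl <- function(config) {
  g <- config$zone_geometry
  fw_nm <- rev(config$field_size_px) * config$pixel_size_nm  # (x, y) extent
  zones <- data.frame(zone_id = integer(), class = character(),
                      center_x_nm = numeric(), center_y_nm = numeric(),
                      semi_a_nm = numeric(), semi_b_nm = numeric(),
                      orientation_rad = numeric())
  margin <- max(g$caz$semi_axes_nm, g$psd$semi_axes_nm, g$ez$semi_axes_nm) +
    g$apposition_nm + g$ez_offset_nm
  placed <- 0L
  max_attempts <- max(200L, 60L * config$n_synapses)
  attempts <- 0L
  while (placed < config$n_synapses && attempts < max_attempts) {
    attempts <- attempts + 1L
    c0 <- c(stats::runif(1, margin, fw_nm[1] - margin),
            stats::runif(1, margin, fw_nm[2] - margin))
    phi <- stats::runif(1, 0, pi)
    axis <- c(cos(phi), sin(phi))          # synaptic (trans-cleft) axis
    perp <- c(-sin(phi), cos(phi))
    side <- sample(c(-1, 1), 1)
    caz_c <- c0 + axis * g$apposition_nm / 2
    psd_c <- c0 - axis * g$apposition_nm / 2
    ez_c  <- psd_c + perp * side * (g$psd$semi_axes_nm[2] + g$ez_offset_nm)
    cand <- data.frame(
      zone_id = placed * 3L + 1:3,
      class = c("caz", "psd", "ez"),
      center_x_nm = c(caz_c[1], psd_c[1], ez_c[1]),
      center_y_nm = c(caz_c[2], psd_c[2], ez_c[2]),
      semi_a_nm = c(g$caz$semi_axes_nm[1], g$psd$semi_axes_nm[1],
                    g$ez$semi_axes_nm[1]),
      semi_b_nm = c(g$caz$semi_axes_nm[2], g$psd$semi_axes_nm[2],
                    g$ez$semi_axes_nm[2]),
      orientation_rad = phi + pi / 2)      # ellipse long axis along the cleft
    ok <- TRUE
    if (nrow(zones)) {
      for (k in 1:3) {     # conservative same-class separation: sum of majors
        same <- zones[zones$class == cand$class[k], , drop = FALSE]
        if (nrow(same)) {
          d <- sqrt((same$center_x_nm - cand$center_x_nm[k])^2 +
                    (same$center_y_nm - cand$center_y_nm[k])^2)
          if (any(d < same$semi_a_nm + cand$semi_a_nm[k])) { ok <- FALSE; break }
        }
      }
    }
    if (ok) { zones <- rbind(zones, cand); placed <- placed + 1L }
  }
  if (placed < config$n_synapses)
    stop(sprintf("could not place %d synapses in the field (placed %d after %d attempts); enlarge the field or reduce n_synapses",
                 config$n_synapses, placed, attempts))

  emit <- function(n, center, a, b, phi, channel, zone_id, zone_class) {
    if (n == 0) return(NULL)
    ld <- config$length_dist; id <- config$intensity_dist
    if (channel == "target") {    # per-zone planted-effect overrides
      ld <- config$zone_length_dist[[zone_class]] %||% ld
      id <- config$zone_intensity_dist[[zone_class]] %||% id
    }
    xy <- runif_ellipse(n, center, a, b, phi)
    data.frame(x_nm = xy[, 1], y_nm = xy[, 2],
               sigma_nm = draw_dist(ld, n) / 2.355,
               amplitude_au = draw_dist(id, n),
               channel = channel, zone_id = zone_id, zone_class = zone_class)
  }
  parts <- list()
  if (nrow(zones)) {
    for (i in seq_len(nrow(zones))) {   # marker emitters first, documented order
      z <- zones[i, ]
      n <- stats::rpois(1, config$marker_density)
      parts[[length(parts) + 1L]] <-
        emit(n, c(z$center_x_nm, z$center_y_nm), z$semi_a_nm, z$semi_b_nm,
             z$orientation_rad, zone_channel[[z$class]], z$zone_id,
             zone_class_of[[z$class]])
    }
    for (i in seq_len(nrow(zones))) {   # then target emitters
      z <- zones[i, ]
      n <- stats::rpois(1, config$nanodomain_density)
      parts[[length(parts) + 1L]] <-
        emit(n, c(z$center_x_nm, z$center_y_nm), z$semi_a_nm, z$semi_b_nm,
             z$orientation_rad, "target", z$zone_id, zone_class_of[[z$class]])
    }
  }
  n_proc <- stats::rpois(1, config$process_density)
  if (n_proc > 0) {
    xy <- cbind(stats::runif(n_proc, 0, fw_nm[1]), stats::runif(n_proc, 0, fw_nm[2]))
    parts[[length(parts) + 1L]] <- data.frame(
      x_nm = xy[, 1], y_nm = xy[, 2],
      sigma_nm = draw_dist(config$length_dist, n_proc) / 2.355,
      amplitude_au = draw_dist(config$intensity_dist, n_proc),
      channel = "target", zone_id = 0L, zone_class = "process")
  }
  emitters <- if (length(parts)) do.call(rbind, parts) else
    data.frame(x_nm = numeric(), y_nm = numeric(), sigma_nm = numeric(),
               amplitude_au = numeric(), channel = character(),
               zone_id = integer(), zone_class = character())
  rownames(emitters) <- NULL
  structure(list(zones = zones, emitters = emitters, config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d zones (%d synapses), %d emitters [%s]\n",
              nrow(x$zones), nrow(x$zones) %/% 3,
              nrow(x$emitters),
              paste(names(table(x$emitters$channel)), collapse = ", ")))
  invisible(x)
}

#' Render one channel of a simulated field
#'
#' Each emitter of the channel becomes an isotropic 2D Gaussian spot with
#' `sigma_eff = sqrt(sigma_emitter^2 + sigma_PSF^2)` and peak amplitude
#' `amplitude_au` (the PSF enters by adding variance, so the amplitude is the
#' peak of the rendered spot). Spots are summed over the background level;
#' optional Poisson shot noise is drawn from the noiseless expectation and
#' Gaussian read noise is added afterwards, with the result clipped at 0.
#' Noise is drawn from a private stream seeded from `(config$seed, channel)`,
#' so renders are reproducible channel by channel in any order.
#'
#' @param gt A `ground_truth` from [simulate_field()].
#' @param channel_id Channel to render; must be a known channel (present in
#'   the emitter table or in `config$psf_fwhm_nm`).
#' @param config The [sim_config()]; defaults to the one stored in `gt`.
#' @param noise Override the config's noise switches: `TRUE`, `FALSE` or
#'   `NULL` (use config).
#' @return A `pixel_image`.
#' @export
render_channel <- function(gt, channel_id, config = gt$config, noise = NULL) {
  known <- union(names(config$psf_fwhm_nm), unique(gt$emitters$channel))
  if (!channel_id %in% known)
    stop(sprintf("unknown channel '%s'; known channels: %s", channel_id,
                 paste(known, collapse = ", ")))
  psf_fwhm <- if (channel_id %in% names(config$psf_fwhm_nm))
    config$psf_fwhm_nm[[channel_id]] else config$psf_fwhm_nm[["target"]]
  px <- config$pixel_size_nm
  nr <- config$field_size_px[1]; nc <- config$field_size_px[2]
  img <- matrix(config$background_level, nr, nc)
  em <- gt$emitters[gt$emitters$channel == channel_id, , drop = FALSE]
  sig_psf <- psf_fwhm / 2.355
  if (nrow(em)) {
    for (i in seq_len(nrow(em))) {
      s_eff <- sqrt(em$sigma_nm[i]^2 + sig_psf^2) / px   # sigma in pixels
      cx <- em$x_nm[i] / px; cy <- em$y_nm[i] / px       # 0-based centres
      r <- ceiling(4 * s_eff)
      c_lo <- max(1L, floor(cx) + 1L - r); c_hi <- min(nc, floor(cx) + 1L + r)
      r_lo <- max(1L, floor(cy) + 1L - r); r_hi <- min(nr, floor(cy) + 1L + r)
      if (c_lo > c_hi || r_lo > r_hi) next
      cols <- c_lo:c_hi; rows <- r_lo:r_hi
      dx <- (cols - 1) - cx; dy <- (rows - 1) - cy
      img[rows, cols] <- img[rows, cols] +
        em$amplitude_au[i] * (exp(-dy^2 / (2 * s_eff^2)) %o%
                              exp(-dx^2 / (2 * s_eff^2)))
    }
  }
  do_shot <- if (is.null(noise)) config$shot_noise else isTRUE(noise)
  do_read <- if (is.null(noise)) config$read_noise_sd > 0 else isTRUE(noise)
  if (do_shot || do_read) {
    img <- with_seed(channel_seed(config$seed, channel_id), {
      out <- img
      if (do_shot) out <- matrix(stats::rpois(length(out), out), nrow(out), ncol(out))
      if (do_read && config$read_noise_sd > 0)
        out <- out + stats::rnorm(length(out), 0, config$read_noise_sd)
      out
    })
  }
  img[img < 0] <- 0
  modality <- if (psf_fwhm >= 150) "confocal" else "sted"
  pixel_image(img, px, channel = channel_id, modality = modality)
}

#' Effective (measurable) FWHM of ground-truth emitters
#'
#' The best length a segmentation of the rendered image can recover for an
#' emitter is the FWHM of its rendered spot, `2.355 * sqrt(sigma^2 +
#' sigma_PSF^2)`; recovery scoring compares measured lengths against this.
#'
#' @param gt A `ground_truth`.
#' @param channel_id Channel whose PSF applies.
#' @return Numeric vector of effective FWHM (nm) for that channel's emitters.
#' @export
effective_fwhm_nm <- function(gt, channel_id = "target") {
  psf <- gt$config$psf_fwhm_nm[[channel_id]]
  em <- gt$emitters[gt$emitters$channel == channel_id, , drop = FALSE]
  2.355 * sqrt(em$sigma_nm^2 + (psf / 2.355)^2)
}

#' Write ground truth as CSV tables
#'
#' @param gt A `ground_truth`.
#' @param dir Output directory; writes `emitters.csv` and `zones.csv`.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(gt$emitters, file.path(dir, "emitters.csv"), row.names = FALSE)
  utils::write.csv(gt$zones, file.path(dir, "zones.csv"), row.names = FALSE)
  invisible(dir)
}

#' Simulate a neuronal-process field of target spots with a partner channel
#'
#' Emulates two-channel STED acquisitions of the target protein together with
#' an interaction partner on neuronal processes. A fraction
#' `independent_fraction` of target spots is planted with no partner emitter
#' within `guard_nm`; every other target spot receives a partner emitter
#' jittered by at most `jitter_nm`. Extra partner-only spots can be added.
#'
#' @param config A [sim_config()]; `n_synapses` is ignored (process field).
#' @param n_target Number of target spots.
#' @param partner_channel Partner channel name (e.g. `"ps1"`, `"app"`).
#' @param independent_fraction Fraction of target spots with no nearby partner.
#' @param jitter_nm Maximum partner displacement from its target spot.
#' @param guard_nm Minimum distance from an independent target to any partner.
#' @param n_partner_extra Partner-only spots, placed away from independent
#'   targets.
#' @return A `ground_truth`; target emitters carry `zone_class = "process"`
#'   and an extra logical column `independent` on the target rows.
#' @export
simulate_partner_field <- function(config, n_target = 150,
                                   partner_channel = "ps1",
                                   independent_fraction = 0.3,
                                   jitter_nm = 40, guard_nm = 400,
                                   n_partner_extra = 20) {
  validate_sim_config(config)
  with_seed(config$seed, {
    fw_nm <- rev(config$field_size_px) * config$pixel_size_nm
    m <- guard_nm
    tx <- stats::runif(n_target, m, fw_nm[1] - m)
    ty <- stats::runif(n_target, m, fw_nm[2] - m)
    indep <- stats::runif(n_target) < independent_fraction
    tgt <- data.frame(x_nm = tx, y_nm = ty,
                      sigma_nm = draw_dist(config$length_dist, n_target) / 2.355,
                      amplitude_au = draw_dist(config$intensity_dist, n_target),
                      channel = "target", zone_id = 0L, zone_class = "process",
                      independent = indep)
    th <- stats::runif(n_target, 0, 2 * pi)
    rr <- stats::runif(n_target, 0, jitter_nm)
    par <- data.frame(x_nm = tx + rr * cos(th), y_nm = ty + rr * sin(th),
                      sigma_nm = draw_dist(config$length_dist, n_target) / 2.355,
                      amplitude_au = draw_dist(config$intensity_dist, n_target),
                      channel = partner_channel, zone_id = 0L,
                      zone_class = "process", independent = FALSE)
    par <- par[!indep, , drop = FALSE]
    if (n_partner_extra > 0) {
      keep <- matrix(numeric(0), 0, 2)
      tries <- 0L
      while (nrow(keep) < n_partner_extra && tries < 50L * n_partner_extra) {
        tries <- tries + 1L
        p <- c(stats::runif(1, 0, fw_nm[1]), stats::runif(1, 0, fw_nm[2]))
        d <- sqrt((tx[indep] - p[1])^2 + (ty[indep] - p[2])^2)
        if (!length(d) || min(d) > guard_nm) keep <- rbind(keep, p)
      }
      if (nrow(keep)) {
        ne <- nrow(keep)
        par <- rbind(par, data.frame(
          x_nm = keep[, 1], y_nm = keep[, 2],
          sigma_nm = draw_dist(config$length_dist, ne) / 2.355,
          amplitude_au = draw_dist(config$intensity_dist, ne),
          channel = partner_channel, zone_id = 0L, zone_class = "process",
          independent = FALSE))
      }
    }
    emitters <- rbind(tgt, par)
    rownames(emitters) <- NULL
    structure(list(zones = data.frame(zone_id = integer(), class = character(),
                                      center_x_nm = numeric(), center_y_nm = numeric(),
                                      semi_a_nm = numeric(), semi_b_nm = numeric(),
                                      orientation_rad = numeric()),
                   emitters = emitters, config = config),
              class = "ground_truth")
  })
}
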