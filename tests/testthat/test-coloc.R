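px_img <- function(m, px = 25, ch = "t") pixel_image(m, px, channel = ch)

test_that("linear rescaling inverts exact affine relations and matches a grid search", {
  set.seed(6)
  ref <- px_img(matrix(rlnorm(64, 3, 0.5), 8, 8))
  fit <- linear_rescale(ref, ref)
  expect_equal(fit$alpha, 1)
  expect_equal(fit$beta, 0)
  expect_equal(fit$residual_rms, 0)

  test2 <- px_img(2 * ref$values + 5)
  fit2 <- linear_rescale(test2, ref)
  expect_equal(fit2$alpha, 0.5)
  expect_equal(fit2$beta, -2.5)
  expect_lt(fit2$residual_rms, 1e-12)

  # dense grid search over (alpha, beta) on a random 16x16 pair
  t3 <- px_img(matrix(runif(256, 0, 10), 16, 16))
  r3 <- px_img(matrix(runif(256, 0, 10), 16, 16))
  fit3 <- linear_rescale(t3, r3)
  sse <- function(a, b) sum((a * t3$values + b - r3$values)^2)
  grid_a <- seq(fit3$alpha - 0.05, fit3$alpha + 0.05, length.out = 101)
  grid_b <- seq(fit3$beta - 0.5, fit3$beta + 0.5, length.out = 101)
  best <- Inf; best_ab <- c(NA, NA)
  for (a in grid_a) for (b in grid_b)
    if (sse(a, b) < best) { best <- sse(a, b); best_ab <- c(a, b) }
  expect_equal(fit3$alpha, best_ab[1], tolerance = 1e-3)
  expect_equal(fit3$beta, best_ab[2], tolerance = 5e-3)
  expect_lte(sse(fit3$alpha, fit3$beta), best + 1e-9)

  expect_error(linear_rescale(px_img(matrix(1, 8, 8)), ref), "constant")
})

test_that("RSF width is recovered when the reference is a known blur of the test", {
  cfg <- sim_config(field_size_px = c(160, 160), n_synapses = 5,
                    shot_noise = FALSE, read_noise_sd = 0, seed = 13)
  gt <- simulate_field(cfg)
  test <- render_channel(gt, "target", cfg)
  sigma0 <- 100
  ref <- blur_image(test, sigma0)
  est <- estimate_rsf(test, ref, sigma_bounds_nm = c(0, 300))
  expect_lt(abs(est$sigma_nm - sigma0) / sigma0, 0.10)
  expect_lt(est$rse / mean(ref$values), 1e-3)   # residual of the 0.5 nm-tol fit

  # identical images: no scaling needed, RSE ~ 0 at the lower bound
  est0 <- estimate_rsf(test, test)
  expect_lt(est0$sigma_nm, 5)
  expect_lt(est0$rse, 1e-9)
})

test_that("the optimized RSF sigma beats a dense grid scan of the objective", {
  cfg <- sim_config(field_size_px = c(96, 96), n_synapses = 3,
                    shot_noise = TRUE, read_noise_sd = 2, seed = 19)
  gt <- simulate_field(cfg)
  test <- render_channel(gt, "target", cfg)
  ref <- render_channel(gt, "psd", cfg)
  est <- estimate_rsf(test, ref, sigma_bounds_nm = c(0, 300))
  sel <- seq_along(test$values)
  obj <- function(s) nanozone:::rse_at_sigma(test, ref, sel, s)$rse
  grid <- vapply(seq(0, 300, length.out = 200), obj, numeric(1))
  expect_lte(obj(est$sigma_nm), min(grid) + 1e-9)
})

test_that("RSP/RSE limiting cases and the two-pass Pearson oracle", {
  set.seed(2)
  m <- matrix(rlnorm(64, 2, 0.6), 8, 8)
  img <- px_img(m)
  self <- compute_rsp_rse(img, img, cfg = coloc_config(sigma_mode = "fixed",
                                                       sigma_nm = 0))
  expect_equal(self$aggregate$mean_rsp, 1)
  expect_equal(self$aggregate$mean_rse, 0)

  neg <- px_img(max(m) + min(m) - m)
  anti <- compute_rsp_rse(neg, img, cfg = coloc_config(sigma_mode = "fixed",
                                                       sigma_nm = 0))
  expect_equal(anti$aggregate$mean_rsp, -1)

  # fixture pair: RSP equals the textbook Pearson formula to 1e-12.
  # (alpha > 0 here, so rescaling does not flip the correlation.)
  a <- matrix(c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3), 4, 4)
  b <- matrix(c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8, 4, 5, 9, 0, 4, 5), 4, 4)
  b <- b + 0.5 * a                       # induce positive gain
  res <- compute_rsp_rse(px_img(a), px_img(b),
                         cfg = coloc_config(sigma_mode = "fixed", sigma_nm = 0))
  expect_equal(res$aggregate$mean_rsp, oracle_pearson(a, b),
               tolerance = 1e-12)
  # RSE equals the RMS residual of the least-squares fit
  fit <- linear_rescale(px_img(a), px_img(b))
  expect_equal(res$aggregate$mean_rse, fit$residual_rms, tolerance = 1e-12)

  expect_error(compute_rsp_rse(px_img(a), px_img(matrix(1, 4, 4)),
                               cfg = coloc_config(sigma_mode = "fixed")),
               "zero variance|degenerate")
})

test_that("RSP is invariant to affine transforms of the test image", {
  set.seed(77)
  cfg <- sim_config(field_size_px = c(96, 96), n_synapses = 3, seed = 5)
  gt <- simulate_field(cfg)
  test <- render_channel(gt, "target", cfg)
  ref <- render_channel(gt, "caz", cfg)
  base <- compute_rsp_rse(test, ref, cfg = coloc_config(sigma_mode = "fixed",
                                                        sigma_nm = 50))
  for (ab in list(c(3, 0), c(0.2, 40))) {    # positive gain: RSP unchanged
    tr <- test; tr$values <- ab[1] * test$values + ab[2]
    got <- compute_rsp_rse(tr, ref, cfg = coloc_config(sigma_mode = "fixed",
                                                       sigma_nm = 50))
    expect_equal(got$aggregate$mean_rsp, base$aggregate$mean_rsp,
                 tolerance = 1e-9)
  }
  # negative gain flips the sign of the correlation, by design
  tr <- test
  tr$values <- -2 * test$values + 2 * max(test$values)
  got <- compute_rsp_rse(tr, ref, cfg = coloc_config(sigma_mode = "fixed",
                                                     sigma_nm = 50))
  expect_equal(got$aggregate$mean_rsp, -base$aggregate$mean_rsp,
               tolerance = 1e-9)
})

test_that("positional jitter of target emitters degrades RSP monotonically", {
  jitters <- c(0, 50, 150)
  rsps <- vapply(jitters, function(j) {
    cfg <- sim_config(field_size_px = c(256, 256), n_synapses = 10,
                      nanodomain_density = 4, shot_noise = FALSE,
                      read_noise_sd = 0, seed = 23)
    gt <- simulate_field(cfg)
    ref <- render_channel(gt, "psd", cfg)
    # target emitters cloned from the reference emitters, jittered by j nm
    gt2 <- gt
    mk <- gt2$emitters$channel == "psd"
    tgt <- gt2$emitters[mk, ]
    tgt$channel <- "target"
    set.seed(1000 + j)
    th <- runif(nrow(tgt), 0, 2 * pi)
    tgt$x_nm <- tgt$x_nm + j * cos(th)
    tgt$y_nm <- tgt$y_nm + j * sin(th)
    gt2$emitters <- rbind(gt2$emitters[!mk & gt2$emitters$channel != "target", ],
                          gt2$emitters[mk, ], tgt)
    test <- render_channel(gt2, "target", cfg)
    res <- compute_rsp_rse(test, ref, cfg = coloc_config(sigma_mode = "fixed",
                                                         sigma_nm = 0))
    res$aggregate$mean_rsp
  }, numeric(1))
  expect_true(all(diff(rsps) < 0))
  expect_gt(rsps[1], 0.95)
})

test_that("per-region mode reports one row per scope region plus mean and SEM", {
  cfg <- sim_config(field_size_px = c(192, 192), n_synapses = 6,
                    nanodomain_density = 4, seed = 41)
  gt <- simulate_field(cfg)
  test <- render_channel(gt, "target", cfg)
  ref <- render_channel(gt, "psd", cfg)
  lab <- segment_channel(ref, seg_config())
  scope <- nanozone:::new_binary_mask(lab$labels > 0, ref$pixel_size_nm)
  res <- compute_rsp_rse(test, ref, scope,
                         coloc_config(per_region = TRUE, sigma_mode = "fixed",
                                      sigma_nm = 40))
  expect_equal(nrow(res$per_region) + res$n_skipped, nrow(lab$regions))
  expect_true(all(res$per_region$rsp >= -1 & res$per_region$rsp <= 1))
  expect_true(all(res$per_region$rse >= 0))
  expect_equal(res$aggregate$mean_rsp, mean(res$per_region$rsp))
  expect_equal(res$aggregate$sem_rsp,
               sd(res$per_region$rsp) / sqrt(nrow(res$per_region)))
})
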