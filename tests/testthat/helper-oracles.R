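# Independent brute-force oracles used to check the package's fast paths.
# Each one is written as the plainest possible computation of the defining
# formula, with no code shared with the implementation.

# Otsu: scan every unique intensity as a candidate split {<= t} vs {> t} and
# keep the t with maximal between-class variance.
oracle_otsu <- function(v) {
  v <- as.vector(v)
  cands <- sort(unique(v))
  cands <- cands[-length(cands)]
  best_t <- cands[1]; best_bcv <- -Inf
  for (t in cands) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best_bcv) { best_bcv <- bcv; best_t <- t }
  }
  best_t
}

# Connected components by explicit stack-based flood fill.
oracle_flood_label <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!m[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (o in offs) {
        q <- p + o
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            m[q[1], q[2]] && lab[q[1], q[2]] == 0) {
          lab[q[1], q[2]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# Maximum pairwise distance over all pixel-centre pairs.
oracle_feret <- function(pts) {
  best <- 0
  for (i in seq_len(nrow(pts))) for (j in seq_len(nrow(pts)))
    best <- max(best, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  best
}

# Textbook two-pass Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled observations to the two groups; U counted pair by pair
# (a > b scores 1, ties score 1/2), two-sided by distance of U from na*nb/2.
oracle_mw_p <- function(a, b) {
  pool <- c(a, b); na <- length(a)
  count_u <- function(ai, bi) {
    u <- 0
    for (x in ai) for (y in bi) u <- u + (x > y) + 0.5 * (x == y)
    u
  }
  u_obs <- count_u(a, b)
  mu <- na * length(b) / 2
  sets <- utils::combn(length(pool), na)
  hits <- 0
  for (k in seq_len(ncol(sets))) {
    ai <- pool[sets[, k]]; bi <- pool[-sets[, k]]
    if (abs(count_u(ai, bi) - mu) >= abs(u_obs - mu) - 1e-9) hits <- hits + 1
  }
  hits / ncol(sets)
}

# Kruskal-Wallis H from the defining rank formula with tie correction.
oracle_kw_h <- function(values, groups) {
  r <- rank(values); N <- length(r)
  h <- 0
  for (g in unique(groups)) {
    rg <- r[groups == g]
    h <- h + length(rg) * (mean(rg) - (N + 1) / 2)^2
  }
  h <- 12 / (N * (N + 1)) * h
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Welch t and Satterthwaite df from the definitional formulas.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# One-way ANOVA F from explicit sums of squares.
oracle_anova_f <- function(values, groups) {
  gm <- mean(values); k <- length(unique(groups)); N <- length(values)
  ssb <- ssw <- 0
  for (g in unique(groups)) {
    vg <- values[groups == g]
    ssb <- ssb + length(vg) * (mean(vg) - gm)^2
    ssw <- ssw + sum((vg - mean(vg))^2)
  }
  (ssb / (k - 1)) / (ssw / (N - k))
}

# A field-free single-spot image: isotropic Gaussian, peak amplitude `amp`,
# sigma in nm, on a constant background.
render_spot <- function(sigma_nm, amp = 100, pixel_size_nm = 25, size = 33,
                        background = 0, center_px = NULL) {
  ctr <- center_px %||% rep((size - 1) / 2, 2)   # 0-based (x, y)
  s <- sigma_nm / pixel_size_nm
  x <- 0:(size - 1)
  img <- background + amp * exp(-outer((x - ctr[2])^2, (x - ctr[1])^2, "+") /
                                (2 * s^2))
  pixel_image(img, pixel_size_nm, channel = "spot")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_mask <- function(nr, nc, p = 0.3, pixel_size_nm = 25) {
  m <- matrix(runif(nr * nc) < p, nr, nc)
  nanozone:::new_binary_mask(m, pixel_size_nm, provenance = list(method = "random"))
}
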