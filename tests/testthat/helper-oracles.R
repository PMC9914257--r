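# Independent oracles, deliberately naive: BFS/enumeration/closed forms that
# never reuse the package's code paths.

# Hole filling oracle: BFS flood fill over the background from all border
# background pixels (4-connectivity); unreached background pixels are holes.
fill_holes_oracle <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  reached <- matrix(FALSE, n, m)
  queue <- which(!mask & (row(mask) %in% c(1L, n) | col(mask) %in% c(1L, m)))
  reached[queue] <- TRUE
  while (length(queue)) {
    idx <- queue[1L]; queue <- queue[-1L]
    i <- ((idx - 1L) %% n) + 1L
    j <- ((idx - 1L) %/% n) + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ii <- i + d[1L]; jj <- j + d[2L]
      if (ii >= 1L && ii <= n && jj >= 1L && jj <= m) {
        k <- (jj - 1L) * n + ii
        if (!mask[k] && !reached[k]) {
          reached[k] <- TRUE
          queue <- c(queue, k)
        }
      }
    }
  }
  mask | (!mask & !reached)
}

# All integer thresholds satisfying the intermeans fixed-point condition
# T == round((mean below-or-equal + mean above) / 2), both classes nonempty.
intermeans_fixed_points <- function(img) {
  h <- tabulate(as.integer(img) + 1L, nbins = 256L)
  lv <- 0:255
  fp <- integer(0)
  for (t in 0:255) {
    lo <- lv <= t
    n1 <- sum(h[lo]); n2 <- sum(h[!lo])
    if (n1 == 0 || n2 == 0) next
    m1 <- sum(lv[lo] * h[lo]) / n1
    m2 <- sum(lv[!lo] * h[!lo]) / n2
    if (t == as.integer(round((m1 + m2) / 2))) fp <- c(fp, t)
  }
  fp
}

# Exhaustive Otsu: smallest integer split maximizing between-class variance.
otsu_oracle <- function(img) {
  h <- tabulate(as.integer(img) + 1L, nbins = 256L)
  lv <- 0:255
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:255) {
    lo <- lv <= t
    w1 <- sum(h[lo]); w2 <- sum(h[!lo])
    if (w1 == 0 || w2 == 0) next
    m1 <- sum(lv[lo] * h[lo]) / w1
    m2 <- sum(lv[!lo] * h[!lo]) / w2
    v <- w1 * w2 * (m1 - m2)^2
    if (v > best_v) { best_v <- v; best_t <- t }
  }
  best_t
}

# Rasterized disk mask on an n x m grid (inclusive boundary), the same
# geometry the enumeration oracles count pixels over.
disk_mask <- function(n, m, cy, cx, r) {
  outer((seq_len(n) - cy)^2, (seq_len(m) - cx)^2, `+`) <= r^2
}

# Closed-form least squares for the polynomial model; the package's fit is a
# stochastic search, this is the normal-equations reference.
ols_poly <- function(S, MR, n) {
  fit <- stats::lm(MR ~ stats::poly(S, n, raw = TRUE))
  list(coefficients = unname(stats::coef(fit)),
       J = mean(stats::residuals(fit)^2))
}

# Small grayscale test scene: bright disks on a dark background.
disk_scene <- function(n = 80, m = 120, centers = rbind(c(30, 35), c(30, 85)),
                      radii = c(12, 8), fg = 200L, bg = 40L) {
  img <- matrix(bg, n, m)
  for (i in seq_len(nrow(centers))) {
    img[disk_mask(n, m, centers[i, 1], centers[i, 2], radii[i])] <- fg
  }
  storage.mode(img) <- "integer"
  img
}
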