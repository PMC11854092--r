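# Independent brute-force oracles used to pin the implementations.
# Everything here is deliberately naive (loops, direct formula
# evaluation) and shares no code with the package internals.

# recursive-free flood fill labelling, 8-connectivity, scan order
naive_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni < 1 || ni > h || nj < 1 || nj > w) next
        if (mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          stack[[length(stack) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# exhaustive between-class-variance maximizer over all 256 candidates;
# the variance is exactly flat across empty-bin runs between modes, so the
# maximizing set can be a plateau — its midpoint is returned, matching the
# documented tie convention
naive_otsu <- function(gray) {
  g <- pmin(pmax(round(gray), 0), 255)
  v <- rep(-Inf, 255)
  for (t in 0:254) {
    lo <- g[g <= t]; hi <- g[g > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(g)
    v[t + 1] <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }
  best <- max(v)
  round(mean(which(v >= best - abs(best) * 1e-9))) - 1
}

# direct formula evaluations on the luminance channel
lum <- function(img) {
  if (is.matrix(img)) return(img * 1.0)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

naive_nrmse <- function(I, P) {
  a <- lum(I); b <- lum(P)
  sqrt(sum((a - b)^2) / length(a)) / (max(a) + min(a))
}

naive_psnr <- function(I, P) {
  a <- lum(I); b <- lum(P)
  mse <- sum((a - b)^2) / length(a)
  if (mse == 0) Inf else 10 * log10(max(a)^2 / mse)
}

# windowed SSIM by explicit loops; weights w sum to 1
naive_ssim <- function(I, P, w) {
  a <- lum(I); b <- lum(P)
  k <- nrow(w)
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2; C3 <- C2 / 2
  vals <- c()
  for (i in seq_len(nrow(a) - k + 1)) {
    for (j in seq_len(ncol(a) - k + 1)) {
      wa <- a[i:(i + k - 1), j:(j + k - 1)]
      wb <- b[i:(i + k - 1), j:(j + k - 1)]
      muA <- sum(w * wa); muB <- sum(w * wb)
      vA <- max(sum(w * wa^2) - muA^2, 0)
      vB <- max(sum(w * wb^2) - muB^2, 0)
      cAB <- sum(w * wa * wb) - muA * muB
      L <- (2 * muA * muB + C1) / (muA^2 + muB^2 + C1)
      Cc <- (2 * sqrt(vA) * sqrt(vB) + C2) / (vA + vB + C2)
      S <- (cAB + C3) / (sqrt(vA) * sqrt(vB) + C3)
      vals <- c(vals, L * Cc * S)
    }
  }
  mean(vals)
}

naive_gauss_win <- function(size, sigma) {
  half <- (size - 1) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# a small family of fixed 8x8 RGB fixtures
fixture_images <- function(n = 6, size = 8, seed = 99) {
  withr::with_seed(seed, lapply(seq_len(n), function(i)
    array(sample(0:255, size * size * 3, TRUE), dim = c(size, size, 3))))
}

rand_img <- function(h, w, seed = 1) {
  withr::with_seed(seed,
    array(sample(0:255, h * w * 3, TRUE), dim = c(h, w, 3)))
}
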