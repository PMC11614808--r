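# Independent brute-force oracles, deliberately coded as plain loops,
# separate from the package's vectorized / compiled implementations.

# exhaustive Otsu: maximize between-class variance over every candidate bin
oracle_otsu <- function(plane, n_bins = 256) {
  mn <- min(plane); mx <- max(plane)
  width <- (mx - mn) / n_bins
  idx <- pmin(floor((as.vector(plane) - mn) / width) + 1, n_bins)
  counts <- rep(0, n_bins)
  for (i in idx) counts[i] <- counts[i] + 1
  centers <- mn + (1:n_bins - 0.5) * width
  best <- -Inf; best_t <- NA
  for (t in 1:(n_bins - 1)) {
    w0 <- 0; s0 <- 0
    for (b in 1:t) { w0 <- w0 + counts[b]; s0 <- s0 + counts[b] * centers[b] }
    w1 <- 0; s1 <- 0
    for (b in (t + 1):n_bins) {
      w1 <- w1 + counts[b]; s1 <- s1 + counts[b] * centers[b]
    }
    if (w0 == 0 || w1 == 0) next
    score <- w0 * w1 * (s0 / w0 - s1 / w1)^2
    if (score > best) { best <- score; best_t <- t }
  }
  centers[best_t]
}

# exhaustive 3-class multi-Otsu: O(B^2) search over threshold pairs
oracle_multi_otsu3 <- function(plane, n_bins = 256) {
  mn <- min(plane); mx <- max(plane)
  width <- (mx - mn) / n_bins
  idx <- pmin(floor((as.vector(plane) - mn) / width) + 1, n_bins)
  counts <- rep(0, n_bins)
  for (i in idx) counts[i] <- counts[i] + 1
  centers <- mn + (1:n_bins - 0.5) * width
  seg_score <- function(a, b) {
    w <- sum(counts[a:b])
    if (w == 0) return(-Inf)
    s <- sum(counts[a:b] * centers[a:b])
    s^2 / w
  }
  best <- -Inf; best_pair <- c(NA, NA)
  for (t1 in 1:(n_bins - 2)) for (t2 in (t1 + 1):(n_bins - 1)) {
    sc <- seg_score(1, t1) + seg_score(t1 + 1, t2) +
      seg_score(t2 + 1, n_bins)
    if (sc > best) { best <- sc; best_pair <- c(t1, t2) }
  }
  centers[best_pair]
}

# naive border-clipped sliding-window local mean
oracle_local_mean <- function(plane, block) {
  r <- (block - 1) / 2
  h <- nrow(plane); w <- ncol(plane)
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    ri <- max(1, i - r):min(h, i + r)
    rj <- max(1, j - r):min(w, j + r)
    out[i, j] <- mean(plane[ri, rj])
  }
  out
}

# per-pixel majority vote
oracle_majority <- function(masks) {
  h <- nrow(masks[[1]]); w <- ncol(masks[[1]])
  out <- matrix(FALSE, h, w)
  for (i in 1:h) for (j in 1:w) {
    votes <- 0
    for (m in masks) if (m[i, j]) votes <- votes + 1
    out[i, j] <- votes > length(masks) / 2
  }
  out
}

# coordinate-set intersection of foreground pixels
oracle_coloc <- function(a, b) {
  ca <- which(a); cb <- which(b)
  keep <- intersect(ca, cb)
  out <- matrix(FALSE, nrow(a), ncol(a))
  out[keep] <- TRUE
  out
}

# BFS flood-fill connected-component labeling (4- or 8-connectivity)
oracle_label <- function(mask, connectivity = 8) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nb <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
          c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  next_id <- 0L
  for (sj in 1:w) for (si in 1:h) {
    if (!mask[si, sj] || lab[si, sj] > 0) next
    next_id <- next_id + 1L
    queue <- list(c(si, sj))
    lab[si, sj] <- next_id
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        ni <- p[1] + nb[k, 1]; nj <- p[2] + nb[k, 2]
        if (ni < 1 || nj < 1 || ni > h || nj > w) next
        if (mask[ni, nj] && lab[ni, nj] == 0) {
          lab[ni, nj] <- next_id
          queue[[length(queue) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# area filter by explicit component enumeration
oracle_filter_small <- function(mask, min_area, connectivity = 8) {
  lab <- oracle_label(mask, connectivity)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  if (max(lab) == 0) return(out)
  for (id in 1:max(lab)) {
    pix <- lab == id
    if (sum(pix) >= min_area) out <- out | pix
  }
  out
}

# step-by-step Conover-Iman evaluation, independent of the package path:
# own tie-averaged ranks, own H, explicit pairwise loops, no adjustment
oracle_conover <- function(groups) {
  vals <- c()
  gid <- c()
  for (g in seq_along(groups)) {
    vals <- c(vals, groups[[g]])
    gid <- c(gid, rep(g, length(groups[[g]])))
  }
  N <- length(vals)
  # mid-ranks by sorting
  o <- order(vals)
  rk <- numeric(N)
  i <- 1
  while (i <= N) {
    j <- i
    while (j < N && vals[o[j + 1]] == vals[o[i]]) j <- j + 1
    rk[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  k <- length(groups)
  n_i <- as.numeric(table(gid))
  R_i <- sapply(1:k, function(g) sum(rk[gid == g]))
  H_raw <- 12 / (N * (N + 1)) * sum(R_i^2 / n_i) - 3 * (N + 1)
  tie_counts <- as.numeric(table(vals))
  C <- 1 - sum(tie_counts^3 - tie_counts) / (N^3 - N)
  H <- H_raw / C
  S2 <- (sum(rk^2) - N * (N + 1)^2 / 4) / (N - 1)
  pmat <- matrix(1, k, k)
  tmat <- matrix(0, k, k)
  for (a in 1:(k - 1)) for (b in (a + 1):k) {
    se <- sqrt(S2 * (N - 1 - H) / (N - k) * (1 / n_i[a] + 1 / n_i[b]))
    t_ab <- (R_i[a] / n_i[a] - R_i[b] / n_i[b]) / se
    p <- 2 * stats::pt(-abs(t_ab), N - k)
    tmat[a, b] <- t_ab; tmat[b, a] <- -t_ab
    pmat[a, b] <- p; pmat[b, a] <- p
  }
  list(H = H, t = tmat, p = pmat)
}

# direct dense 2-D Gaussian convolution with symmetric padding
oracle_gauss_conv <- function(plane, sigma) {
  r <- max(1, ceiling(3 * sigma))
  k1 <- exp(-(-r:r)^2 / (2 * sigma^2))
  k2 <- outer(k1, k1); k2 <- k2 / sum(k2)
  h <- nrow(plane); w <- ncol(plane)
  sym <- function(n) c(rev(1:r), 1:n, n:(n - r + 1))
  p <- plane[sym(h), sym(w)]
  out <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w)
    out[i, j] <- sum(k2 * p[i:(i + 2 * r), j:(j + 2 * r)])
  out
}

rand_mask <- function(h, w, p = 0.3) matrix(runif(h * w) < p, h, w)
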