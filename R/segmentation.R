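#' Segmentation parameters
#'
#' Bundles every knob of the automated counting procedure: preprocessing
#' (unsharp mask, Gaussian blur, optional edge step), the thresholding
#' ensemble (Otsu, multi-Otsu, local mean), how the ensemble's binary outputs
#' are combined, and the small-object exclusion. Defaults follow the
#' published procedure where it is explicit (the 15 px^2 artifact exclusion,
#' the three threshold methods) and conservative, documented choices where it
#' is silent (majority-vote combination, edge step off, 8-connectivity).
#'
#' @param unsharp_radius_px Gaussian sigma of the unsharp mask (px).
#' @param unsharp_amount unsharp gain; 0 disables the step.
#' @param gaussian_sigma_px smoothing sigma applied after unsharp (px);
#'   0 disables.
#' @param edge_mode `"off"` (default) or `"subtract"` (subtract the Sobel
#'   gradient magnitude before thresholding). An edge image alone cannot
#'   yield filled nuclei, so the step is explicit and optional.
#' @param threshold_methods ordered subset of
#'   `c("otsu", "multi_otsu", "local")`.
#' @param multi_otsu_classes number of intensity classes (>= 2); the top
#'   class is foreground.
#' @param local_block_px odd window size of the local-mean threshold.
#' @param local_offset additive offset: a pixel is foreground iff its
#'   intensity exceeds the local mean plus this offset.
#' @param combine_rule `"majority"` (default), `"intersection"` or `"union"`.
#' @param min_area_px connected components smaller than this are excluded as
#'   artifacts (default 15 px^2).
#' @param z_mode `"per_plane"` (counts per z-plane plus their sum) or
#'   `"max_projection"`.
#' @param roi_band_halfwidth_px membership band half-width around a polyline
#'   ROI (px).
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(unsharp_radius_px = 2, unsharp_amount = 0.8,
                                gaussian_sigma_px = 1,
                                edge_mode = c("off", "subtract"),
                                threshold_methods = c("otsu", "multi_otsu",
                                                      "local"),
                                multi_otsu_classes = 3L,
                                local_block_px = 31L, local_offset = 0,
                                combine_rule = c("majority", "intersection",
                                                 "union"),
                                min_area_px = 15L,
                                z_mode = c("per_plane", "max_projection"),
                                roi_band_halfwidth_px = 200) {
  edge_mode <- match.arg(edge_mode)
  combine_rule <- match.arg(combine_rule)
  z_mode <- match.arg(z_mode)
  threshold_methods <- match.arg(threshold_methods,
                                 c("otsu", "multi_otsu", "local"),
                                 several.ok = TRUE)
  if (length(threshold_methods) < 1)
    stop_retinaquant("threshold_methods must be non-empty", "parameter_error")
  if (unsharp_radius_px < 0 || gaussian_sigma_px < 0)
    stop_retinaquant("radius/sigma must be non-negative", "parameter_error")
  if (local_block_px %% 2 == 0)
    stop_retinaquant("local_block_px must be odd", "parameter_error")
  if (multi_otsu_classes < 2)
    stop_retinaquant("multi_otsu_classes must be >= 2", "parameter_error")
  if (min_area_px < 0)
    stop_retinaquant("min_area_px must be >= 0", "parameter_error")
  structure(list(unsharp_radius_px = unsharp_radius_px,
                 unsharp_amount = unsharp_amount,
                 gaussian_sigma_px = gaussian_sigma_px,
                 edge_mode = edge_mode,
                 threshold_methods = threshold_methods,
                 multi_otsu_classes = as.integer(multi_otsu_classes),
                 local_block_px = as.integer(local_block_px),
                 local_offset = local_offset,
                 combine_rule = combine_rule,
                 min_area_px = as.integer(min_area_px),
                 z_mode = z_mode,
                 roi_band_halfwidth_px = roi_band_halfwidth_px),
            class = "segmentation_params")
}

#' Gaussian blur of a 2-D plane
#'
#' Separable convolution with a kernel truncated at `ceiling(3 * sigma)`,
#' symmetric (edge-reflecting) boundary handling.
#'
#' @param plane numeric matrix.
#' @param sigma standard deviation in px; 0 returns the input.
#' @return blurred matrix.
#' @export
gaussian_blur <- function(plane, sigma) {
  if (sigma < 0) stop_retinaquant("sigma must be >= 0", "parameter_error")
  if (sigma == 0) return(plane)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  .sep_convolve(plane, k, r)
}

# symmetric padding indices: (r..1 | 1..n | n..n-r+1)
.sym_idx <- function(n, r) c(rev(seq_len(r)), seq_len(n), seq(n, n - r + 1))

.sep_convolve <- function(plane, k, r) {
  h <- nrow(plane); w <- ncol(plane)
  p <- plane[.sym_idx(h, r), , drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_along(k)) out <- out + k[j] * p[(j - 1) + seq_len(h), ,
                                               drop = FALSE]
  p <- out[, .sym_idx(w, r), drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_along(k)) out <- out + k[j] * p[, (j - 1) + seq_len(w),
                                                drop = FALSE]
  out
}

#' Sobel gradient magnitude
#' @param plane numeric matrix.
#' @return matrix of the same shape.
#' @export
sobel_magnitude <- function(plane) {
  h <- nrow(plane); w <- ncol(plane)
  p <- plane[.sym_idx(h, 1), .sym_idx(w, 1)]
  sh <- function(di, dj) p[1 + di + seq_len(h), 1 + dj + seq_len(w)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Preprocess a plane before thresholding
#'
#' In order: unsharp mask
#' (`plane + amount * (plane - gaussian(plane, radius))`), Gaussian blur,
#' optional edge step. The output is clipped to the input's intensity range,
#' and identity parameters (`amount = 0`, `sigma = 0`, edge off) return the
#' input unchanged.
#'
#' @param plane numeric matrix of finite non-negative intensities.
#' @param params a [segmentation_params()].
#' @return processed matrix.
#' @export
preprocess <- function(plane, params = segmentation_params()) {
  if (any(!is.finite(plane)) || any(plane < 0))
    stop_retinaquant("plane must be finite and non-negative",
                     "parameter_error")
  lo <- min(plane); hi <- max(plane)
  out <- plane
  if (params$unsharp_amount > 0 && params$unsharp_radius_px > 0)
    out <- out + params$unsharp_amount *
      (out - gaussian_blur(out, params$unsharp_radius_px))
  if (params$gaussian_sigma_px > 0)
    out <- gaussian_blur(out, params$gaussian_sigma_px)
  if (params$edge_mode == "subtract") out <- out - sobel_magnitude(out)
  pmin(pmax(out, lo), hi)
}

.histogram_256 <- function(plane, n_bins) {
  mn <- min(plane); mx <- max(plane)
  width <- (mx - mn) / n_bins
  idx <- pmin(floor((as.vector(plane) - mn) / width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  centers <- mn + (seq_len(n_bins) - 0.5) * width
  list(counts = counts, centers = centers)
}

#' Otsu threshold
#'
#' Threshold maximizing the between-class variance over a 256-bin histogram
#' spanning the plane's observed min-max (8-bit convention while accepting
#' 16-bit input). Pixels strictly above the threshold are foreground. Ties
#' resolve to the lowest candidate.
#'
#' @param plane numeric matrix with at least two distinct values.
#' @param n_bins histogram bins (default 256).
#' @return threshold (bin-center intensity).
#' @export
threshold_otsu <- function(plane, n_bins = 256L) {
  if (length(unique(as.vector(plane))) < 2)
    stop_retinaquant("constant plane: Otsu threshold undefined",
                     "degenerate_input_error")
  hg <- .histogram_256(plane, n_bins)
  n <- sum(hg$counts)
  w0 <- cumsum(as.numeric(hg$counts))
  s0 <- cumsum(hg$counts * hg$centers)
  tot <- s0[n_bins]
  t <- seq_len(n_bins - 1)
  w1 <- n - w0[t]
  mu0 <- ifelse(w0[t] > 0, s0[t] / w0[t], 0)
  mu1 <- ifelse(w1 > 0, (tot - s0[t]) / w1, 0)
  score <- w0[t] * w1 * (mu0 - mu1)^2
  hg$centers[t[which.max(score)]]
}

#' Multi-Otsu thresholds
#'
#' Generalization of Otsu to `classes` intensity classes: the `classes - 1`
#' thresholds maximize the between-class variance (equivalently minimize the
#' within-class variance) over the histogram, found exactly by dynamic
#' programming over bin boundaries. The top class is foreground. With
#' `classes = 2` the partition reproduces [threshold_otsu()].
#'
#' @inheritParams threshold_otsu
#' @param classes number of classes (>= 2).
#' @return sorted numeric vector of `classes - 1` thresholds.
#' @export
threshold_multi_otsu <- function(plane, classes = 3L, n_bins = 256L) {
  if (classes < 2) stop_retinaquant("classes must be >= 2", "parameter_error")
  if (length(unique(as.vector(plane))) < classes)
    stop_retinaquant(
      sprintf("plane has fewer than %d distinct values", classes),
      "degenerate_input_error")
  hg <- .histogram_256(plane, n_bins)
  c0 <- c(0, cumsum(hg$counts))
  c1 <- c(0, cumsum(hg$counts * hg$centers))
  seg <- function(a, b) {  # sum w * mu^2 contribution of bins a..b
    w <- c0[b + 1] - c0[a]
    if (w <= 0) return(-Inf)  # empty class: forbid
    (c1[b + 1] - c1[a])^2 / w
  }
  k <- as.integer(classes); B <- as.integer(n_bins)
  best <- matrix(-Inf, k, B)
  back <- matrix(0L, k, B)
  for (b in seq_len(B)) best[1, b] <- seg(1, b)
  for (cl in 2:k) {
    for (b in cl:B) {
      for (t in (cl - 1):(b - 1)) {
        v <- best[cl - 1, t] + seg(t + 1, b)
        if (v > best[cl, b]) { best[cl, b] <- v; back[cl, b] <- t }
      }
    }
  }
  bounds <- integer(k - 1)
  b <- B
  for (cl in k:2) {
    bounds[cl - 1] <- back[cl, b]
    b <- back[cl, b]
  }
  sort(hg$centers[bounds])
}

#' Local mean threshold
#'
#' A pixel is foreground iff its intensity exceeds the mean over an odd
#' square block centered on it (clipped at image borders) plus `offset`.
#' A constant plane therefore gives an empty mask for positive `offset` and
#' a full mask for negative `offset`.
#'
#' @param plane numeric matrix.
#' @param block_px odd block size, smaller than both image dimensions.
#' @param offset additive offset in intensity units.
#' @return logical matrix (the binary mask).
#' @export
threshold_local <- function(plane, block_px = 31L, offset = 0) {
  if (block_px %% 2 == 0)
    stop_retinaquant("block_px must be odd", "parameter_error")
  if (block_px >= min(dim(plane)))
    stop_retinaquant("block_px must be smaller than the image",
                     "parameter_error")
  m <- local_mean(plane, block_px)
  plane > m + offset
}

#' Local block mean via integral image (border-clipped window)
#' @inheritParams threshold_local
#' @return matrix of local means.
#' @export
local_mean <- function(plane, block_px) {
  h <- nrow(plane); w <- ncol(plane)
  r <- (block_px - 1) / 2
  S <- matrix(0, h + 1, w + 1)
  S[-1, -1] <- t(apply(apply(plane, 2, cumsum), 1, cumsum))
  # S[i+1, j+1] = sum of plane[1..i, 1..j]
  i1 <- pmax(seq_len(h) - r, 1); i2 <- pmin(seq_len(h) + r, h)
  j1 <- pmax(seq_len(w) - r, 1); j2 <- pmin(seq_len(w) + r, w)
  sums <- S[i2 + 1, j2 + 1] - S[i1, j2 + 1] - S[i2 + 1, j1] + S[i1, j1]
  area <- outer(i2 - i1 + 1, j2 - j1 + 1)
  sums / area
}

#' Combine an ensemble of binary masks
#'
#' `majority`: a pixel is foreground when set in more than half of the masks;
#' `intersection` / `union` as named. A single mask is returned unchanged
#' under any rule.
#'
#' @param masks non-empty list of logical matrices with identical shape.
#' @param rule combination rule.
#' @return logical matrix.
#' @export
combine_masks <- function(masks, rule = c("majority", "intersection",
                                          "union")) {
  rule <- match.arg(rule)
  if (length(masks) == 0)
    stop_retinaquant("mask list must be non-empty", "dimension_error")
  d <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), d))
    stop_retinaquant("masks must share dimensions", "dimension_error")
  switch(rule,
         majority = Reduce(`+`, masks) > length(masks) / 2,
         intersection = Reduce(`&`, masks),
         union = Reduce(`|`, masks))
}

#' Binary-AND colocalization of two masks
#'
#' The published overlay step: a pixel is colocalized iff it is foreground in
#' both channels' masks; the result is a subset of each input.
#'
#' @param mask_a,mask_b logical matrices with identical shape.
#' @return logical matrix.
#' @export
colocalize <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop_retinaquant("masks must share dimensions", "dimension_error")
  mask_a & mask_b
}

#' Label connected components and measure them
#'
#' 8-connected (default) two-pass labeling; centroids are reported in 0-based
#' (row, col) pixel coordinates to match the ROI convention.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return list with `labels` (integer matrix) and `objects` (data.frame:
#'   object_id, area_px, centroid_row, centroid_col, bbox columns).
#' @export
label_objects <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    stop_retinaquant("connectivity must be 4 or 8", "parameter_error")
  lab <- label_components_cpp(mask, as.integer(connectivity))
  n <- max(lab)
  if (n == 0) {
    objects <- data.frame(object_id = integer(0), area_px = integer(0),
                          centroid_row = numeric(0), centroid_col = numeric(0),
                          bbox_rmin = integer(0), bbox_rmax = integer(0),
                          bbox_cmin = integer(0), bbox_cmax = integer(0))
    return(list(labels = lab, objects = objects))
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  area <- tabulate(l, nbins = n)
  r0 <- idx[, 1] - 1; c0 <- idx[, 2] - 1   # 0-based
  objects <- data.frame(
    object_id = seq_len(n),
    area_px = area,
    centroid_row = as.numeric(tapply(r0, l, mean)),
    centroid_col = as.numeric(tapply(c0, l, mean)),
    bbox_rmin = as.integer(tapply(r0, l, min)),
    bbox_rmax = as.integer(tapply(r0, l, max)),
    bbox_cmin = as.integer(tapply(c0, l, min)),
    bbox_cmax = as.integer(tapply(c0, l, max)))
  list(labels = lab, objects = objects)
}

#' Remove small connected components
#'
#' Components below `min_area_px` (default 15 px^2) are excluded as imaging
#' artifacts; survivors are relabeled and measured.
#'
#' @param mask logical matrix.
#' @param min_area_px minimum component area in pixels.
#' @param connectivity 4 or 8.
#' @return list with `mask` (filtered), `labels`, `objects`.
#' @export
filter_small <- function(mask, min_area_px = 15L, connectivity = 8L) {
  lo <- label_objects(mask, connectivity)
  keep <- lo$objects$object_id[lo$objects$area_px >= min_area_px]
  fmask <- matrix(lo$labels %in% keep, nrow(mask), ncol(mask))
  lo2 <- label_objects(fmask, connectivity)
  list(mask = fmask, labels = lo2$labels, objects = lo2$objects)
}
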