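# Full automated counting procedure: preprocess -> threshold ensemble ->
# combine -> per-channel area filter -> binary AND -> area filter again ->
# connected components -> ROI membership -> density normalization.

# Threshold ensemble on one preprocessed plane. A degenerate (constant)
# plane yields an empty mask with a warning rather than an error: an empty
# channel is a legitimate biological outcome (e.g. no PCNA signal).
.ensemble_mask <- function(plane, params) {
  masks <- list()
  thresholds <- list()
  for (m in params$threshold_methods) {
    res <- tryCatch(switch(m,
      otsu = {
        th <- threshold_otsu(plane)
        list(mask = plane > th, threshold = th)
      },
      multi_otsu = {
        th <- threshold_multi_otsu(plane, params$multi_otsu_classes)
        list(mask = plane > th[length(th)], threshold = th)
      },
      local = list(mask = threshold_local(plane, params$local_block_px,
                                          params$local_offset),
                   threshold = NA_real_)),
      degenerate_input_error = function(e) NULL)
    if (!is.null(res)) {
      masks[[length(masks) + 1]] <- res$mask
      thresholds[[m]] <- res$threshold
    }
  }
  n_failed <- length(params$threshold_methods) - length(masks)
  if (n_failed > 0)
    warning(sprintf(
      "degenerate (constant) plane: %d threshold method(s) skipped",
      n_failed), call. = FALSE)
  if (length(masks) == 0)
    return(list(mask = matrix(FALSE, nrow(plane), ncol(plane)),
                thresholds = thresholds))
  list(mask = combine_masks(masks, params$combine_rule),
       thresholds = thresholds)
}

# segment one channel of one plane: preprocess, ensemble, small-object filter
.segment_plane <- function(plane, params) {
  pp <- preprocess(plane, params)
  em <- .ensemble_mask(pp, params)
  fs <- filter_small(em$mask, params$min_area_px)
  list(mask = fs$mask, objects = fs$objects, thresholds = em$thresholds)
}

.roi_member <- function(objects, roi, params) {
  if (nrow(objects) == 0) return(logical(0))
  pts <- cbind(objects$centroid_row, objects$centroid_col)
  if (roi$kind == "polygon") points_in_polygon(pts, roi)
  else points_polyline_distance(pts, roi) <= params$roi_band_halfwidth_px
}

.roi_normalizer <- function(roi, pixel_size_um) {
  # densities are per mm (polyline) or per mm^2 (polygon)
  if (roi$kind == "polygon")
    list(value = polygon_area(roi, pixel_size_um) / 1e6, unit = "mm2",
         colname = "roi_area_mm2")
  else
    list(value = polyline_length(roi, pixel_size_um) / 1e3, unit = "mm",
         colname = "roi_length_mm")
}

.count_record <- function(sample_id, group, marker_combo, raw_count, roi,
                          pixel_size_um, per_plane = NULL) {
  nrm <- .roi_normalizer(roi, pixel_size_um)
  rec <- data.frame(sample_id = sample_id,
                    line = group$line %||% NA_character_,
                    treatment = group$treatment %||% NA_character_,
                    dpi = group$dpi %||% NA_integer_,
                    marker_combo = marker_combo,
                    raw_count = as.integer(raw_count),
                    roi_normalizer = nrm$value,
                    roi_unit = nrm$unit,
                    density = raw_count / nrm$value)
  class(rec) <- c("count_record", "data.frame")
  attr(rec, "per_plane") <- per_plane
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count colocalized two-channel objects in a ROI
#'
#' The automated counting procedure applied to two channels (typically DAPI
#' and PCNA): each channel is preprocessed and thresholded by the ensemble,
#' small objects (< `min_area_px`, default 15 px^2) are excluded per channel,
#' the two masks are overlaid with a binary logical AND, the AND mask is
#' area-filtered again (the overlay can fragment objects), and surviving
#' 8-connected components whose centroid lies inside the polygon ROI (or
#' within the band around a polyline ROI) are counted. The density is the
#' count per mm^2 of ROI area or per mm of curvilinear distance.
#'
#' @param stack an [image_stack()].
#' @param ch_a,ch_b channel names (e.g. `"DAPI"`, `"PCNA"`).
#' @param roi a [roi_polygon()] or [roi_polyline()].
#' @param params a [segmentation_params()].
#' @param sample_id identifier recorded in the output.
#' @param group optional list with `line`, `treatment`, `dpi` labels.
#' @return a `count_record` (one-row data.frame; `density * roi_normalizer`
#'   equals `raw_count` exactly). Attribute `per_plane` holds per-z counts in
#'   `z_mode = "per_plane"`; attribute `thresholds` logs the thresholds
#'   chosen per plane and channel.
#' @export
count_coloc <- function(stack, ch_a, ch_b, roi,
                        params = segmentation_params(),
                        sample_id = "sample", group = list()) {
  for (ch in c(ch_a, ch_b)) if (!ch %in% stack$channel_names)
    stop_retinaquant(paste0("channel not in stack: ", ch),
                     "missing_channel_error")
  zs <- .z_planes(stack, params)
  per_plane <- integer(length(zs$planes))
  thr_log <- list()
  for (zi in seq_along(zs$planes)) {
    sa <- .segment_plane(zs$planes[[zi]][[ch_a]], params)
    sb <- .segment_plane(zs$planes[[zi]][[ch_b]], params)
    am <- colocalize(sa$mask, sb$mask)
    fs <- filter_small(am, params$min_area_px)
    inroi <- .roi_member(fs$objects, roi, params)
    per_plane[zi] <- sum(inroi)
    thr_log[[zi]] <- list(a = sa$thresholds, b = sb$thresholds)
  }
  rec <- .count_record(sample_id, group,
                       paste0(ch_a, "&", ch_b), sum(per_plane), roi,
                       stack$pixel_size_um,
                       per_plane = data.frame(z = zs$z_label,
                                              count = per_plane))
  attr(rec, "thresholds") <- thr_log
  rec
}

#' Count single-marker objects in a ROI
#'
#' As [count_coloc()] without the AND stage: used for totals of TUNEL+,
#' L-plastin+ or HuC/D+ cells normalized to ROI area or curvilinear
#' distance.
#'
#' @inheritParams count_coloc
#' @param channel channel name.
#' @return a `count_record`.
#' @export
count_single_marker <- function(stack, channel, roi,
                                params = segmentation_params(),
                                sample_id = "sample", group = list()) {
  if (!channel %in% stack$channel_names)
    stop_retinaquant(paste0("channel not in stack: ", channel),
                     "missing_channel_error")
  zs <- .z_planes(stack, params)
  per_plane <- integer(length(zs$planes))
  thr_log <- list()
  for (zi in seq_along(zs$planes)) {
    sg <- .segment_plane(zs$planes[[zi]][[channel]], params)
    inroi <- .roi_member(sg$objects, roi, params)
    per_plane[zi] <- sum(inroi)
    thr_log[[zi]] <- sg$thresholds
  }
  rec <- .count_record(sample_id, group, channel, sum(per_plane), roi,
                       stack$pixel_size_um,
                       per_plane = data.frame(z = zs$z_label,
                                              count = per_plane))
  attr(rec, "thresholds") <- thr_log
  rec
}

# z handling: per-plane list of named channel planes, or one max projection
.z_planes <- function(stack, params) {
  nz <- dim(stack$pixels)[3]
  if (params$z_mode == "max_projection") {
    planes <- list(lapply(stack$channel_names, function(ch)
      apply(stack$pixels[, , , ch, drop = FALSE], c(1, 2), max)))
    names(planes[[1]]) <- stack$channel_names
    list(planes = planes, z_label = "max_projection")
  } else {
    planes <- lapply(seq_len(nz), function(z) {
      p <- lapply(stack$channel_names, function(ch) stack$pixels[, , z, ch])
      names(p) <- stack$channel_names
      p
    })
    list(planes = planes, z_label = seq_len(nz))
  }
}

#' Score segmented cells for a partner marker
#'
#' Implements the two manual scoring rules as explicit set operations on
#' masks:
#' * `rule = "nuclear_overlap"` — a cell (e.g. an L-plastin+ leukocyte) is
#'   positive iff at least `fraction_threshold` of its contained nuclear
#'   pixels lie in the partner mask (e.g. PCNA): "scored for nuclear PCNA
#'   signal".
#' * `rule = "surround"` — a nucleus is positive iff at least
#'   `fraction_threshold` of an annulus around it (dilation by `annulus_px`
#'   minus the nucleus) lies in the partner mask: "signal surrounding the
#'   nucleus" (the HuC/D rule).
#'
#' A cell without any contained nuclear pixel is scored negative and flagged.
#'
#' @param cell_mask binary mask of segmented cells (or nuclei for
#'   `"surround"`).
#' @param nuclear_mask binary nuclear (DAPI) mask; ignored by `"surround"`.
#' @param partner_mask binary mask of the partner marker.
#' @param rule `"nuclear_overlap"` or `"surround"`.
#' @param fraction_threshold positivity cutoff (defaults: 0.5 for
#'   nuclear_overlap, 0.3 for surround; tunable, no published guidance).
#' @param annulus_px annulus width for `"surround"` (px).
#' @param connectivity component connectivity.
#' @return list with `scores` (data.frame: object_id, n_reference_px,
#'   n_positive_px, fraction, positive, no_nucleus flag) and `n_positive`.
#' @export
score_cells <- function(cell_mask, nuclear_mask = NULL, partner_mask,
                        rule = c("nuclear_overlap", "surround"),
                        fraction_threshold = NULL, annulus_px = 3L,
                        connectivity = 8L) {
  rule <- match.arg(rule)
  if (is.null(fraction_threshold))
    fraction_threshold <- if (rule == "nuclear_overlap") 0.5 else 0.3
  lo <- label_objects(cell_mask, connectivity)
  n <- nrow(lo$objects)
  scores <- data.frame(object_id = integer(0), n_reference_px = integer(0),
                       n_positive_px = integer(0), fraction = numeric(0),
                       positive = logical(0), no_nucleus = logical(0))
  if (n == 0) return(list(scores = scores, n_positive = 0L))
  if (rule == "nuclear_overlap" && is.null(nuclear_mask))
    stop_retinaquant("nuclear_overlap requires a nuclear_mask",
                     "parameter_error")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    obj <- lo$labels == i
    if (rule == "nuclear_overlap") {
      ref <- obj & nuclear_mask
    } else {
      # dilate this object alone: cheap via bounding box crop
      bb <- lo$objects[i, ]
      r1 <- max(1, bb$bbox_rmin + 1 - annulus_px)
      r2 <- min(nrow(cell_mask), bb$bbox_rmax + 1 + annulus_px)
      c1 <- max(1, bb$bbox_cmin + 1 - annulus_px)
      c2 <- min(ncol(cell_mask), bb$bbox_cmax + 1 + annulus_px)
      sub <- obj[r1:r2, c1:c2, drop = FALSE]
      ring <- .dilate_disk(sub, annulus_px) & !sub
      ref <- matrix(FALSE, nrow(cell_mask), ncol(cell_mask))
      ref[r1:r2, c1:c2] <- ring
    }
    n_ref <- sum(ref)
    if (n_ref == 0) {
      rows[[i]] <- data.frame(object_id = i, n_reference_px = 0L,
                              n_positive_px = 0L, fraction = 0,
                              positive = FALSE, no_nucleus = TRUE)
      next
    }
    n_pos <- sum(ref & partner_mask)
    frac <- n_pos / n_ref
    rows[[i]] <- data.frame(object_id = i, n_reference_px = n_ref,
                            n_positive_px = n_pos, fraction = frac,
                            positive = frac >= fraction_threshold,
                            no_nucleus = FALSE)
  }
  scores <- do.call(rbind, rows)
  if (any(scores$no_nucleus))
    message(sum(scores$no_nucleus),
            " cell(s) without contained nucleus scored negative")
  list(scores = scores, n_positive = sum(scores$positive))
}

# binary dilation with a disk of radius r (shift-OR over the disk offsets)
.dilate_disk <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (di in -r:r) for (dj in -r:r) {
    if (di^2 + dj^2 > r^2) next
    ri <- max(1, 1 - di):min(h, h - di)
    rj <- max(1, 1 - dj):min(w, w - dj)
    out[ri + di, rj + dj] <- out[ri + di, rj + dj] | mask[ri, rj]
  }
  out
}
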