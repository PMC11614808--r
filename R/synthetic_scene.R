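#' Configuration of a synthetic retinal-section scene
#'
#' Describes a confocal-like cryosection: three nuclear strata (ONL/INL/GCL
#' analogues) of DAPI-stained nuclei, a PCNA-positive nuclear subset,
#' leukocyte cell bodies (L-plastin channel) with their own nuclei, optional
#' TUNEL and HuC/D channels, point-spread blur and Poisson + Gaussian camera
#' noise. The published study reports neither pixel sizes nor densities or
#' SNR, so these defaults describe a plausible 40x-confocal field; they are
#' stated here, not claimed to match the study.
#'
#' @param image_height_px,image_width_px image dimensions.
#' @param n_z number of z-planes; each cell is placed on one plane.
#' @param pixel_size_um pixel size (um, > 0).
#' @param layer_bands named list of `c(row_start, row_end)` (0-based,
#'   inclusive) nuclear strata; must be disjoint and inside the image.
#' @param n_nuclei_per_layer nuclei per band.
#' @param nucleus_radius_um `c(mean, sd)` of nuclear radius (um).
#' @param pcna_positive_fraction fraction of nuclei that are PCNA+ (S-phase).
#' @param n_leukocytes number of leukocyte bodies scattered over the image.
#' @param leukocyte_radius_um `c(mean, sd)` of body radius (um).
#' @param leukocyte_nuclear_pcna_fraction fraction of leukocytes whose
#'   nucleus carries PCNA signal.
#' @param tunel_positive_fraction fraction of nuclei that are TUNEL+; the
#'   TUNEL channel is emitted only when > 0.
#' @param hucd_positive_fraction fraction of INL/GCL-band nuclei wrapped by a
#'   HuC/D+ ring (signal surrounding the DAPI nucleus); channel emitted only
#'   when > 0.
#' @param psf_sigma_um Gaussian point-spread sigma (um); 0 = no blur.
#' @param background_level background intensity on the unit ideal scale.
#' @param photon_scale expected photon count of a unit-intensity pixel;
#'   shot-noise SNR of the signal is about `sqrt(photon_scale)`.
#' @param read_noise_sd camera read noise (photons, Gaussian).
#' @param min_center_separation_um minimum distance between cell centers; the
#'   generator additionally enforces non-touching footprints (sum of radii)
#'   so noiseless ground-truth counts are exact.
#' @param seed scene seed; identical config + seed gives bit-identical output.
#' @return a `scene_config` list.
#' @export
scene_config <- function(image_height_px = 360L, image_width_px = 360L,
                         n_z = 1L, pixel_size_um = 0.5,
                         layer_bands = list(ONL = c(20, 115),
                                            INL = c(135, 230),
                                            GCL = c(250, 345)),
                         n_nuclei_per_layer = 50L,
                         nucleus_radius_um = c(3, 0.4),
                         pcna_positive_fraction = 0.3,
                         n_leukocytes = 8L,
                         leukocyte_radius_um = c(6, 1),
                         leukocyte_nuclear_pcna_fraction = 0.4,
                         tunel_positive_fraction = 0,
                         hucd_positive_fraction = 0,
                         psf_sigma_um = 0.25,
                         background_level = 0.02,
                         photon_scale = 200,
                         read_noise_sd = 3,
                         min_center_separation_um = 7.5,
                         seed = 1L) {
  cfg <- list(image_height_px = as.integer(image_height_px),
              image_width_px = as.integer(image_width_px),
              n_z = as.integer(n_z), pixel_size_um = pixel_size_um,
              layer_bands = layer_bands,
              n_nuclei_per_layer = as.integer(n_nuclei_per_layer),
              nucleus_radius_um = nucleus_radius_um,
              pcna_positive_fraction = pcna_positive_fraction,
              n_leukocytes = as.integer(n_leukocytes),
              leukocyte_radius_um = leukocyte_radius_um,
              leukocyte_nuclear_pcna_fraction = leukocyte_nuclear_pcna_fraction,
              tunel_positive_fraction = tunel_positive_fraction,
              hucd_positive_fraction = hucd_positive_fraction,
              psf_sigma_um = psf_sigma_um,
              background_level = background_level,
              photon_scale = photon_scale,
              read_noise_sd = read_noise_sd,
              min_center_separation_um = min_center_separation_um,
              seed = as.integer(seed))
  .validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

.validate_scene_config <- function(cfg) {
  fr <- c(cfg$pcna_positive_fraction, cfg$leukocyte_nuclear_pcna_fraction,
          cfg$tunel_positive_fraction, cfg$hucd_positive_fraction)
  if (any(fr < 0 | fr > 1))
    stop_retinaquant("fractions must lie in [0, 1]", "scene_config_error")
  if (cfg$pixel_size_um <= 0 || cfg$photon_scale <= 0)
    stop_retinaquant("pixel_size_um and photon_scale must be positive",
                     "scene_config_error")
  if (cfg$psf_sigma_um < 0 || cfg$read_noise_sd < 0 ||
      cfg$background_level < 0 || cfg$min_center_separation_um < 0 ||
      any(cfg$nucleus_radius_um < 0) || any(cfg$leukocyte_radius_um < 0))
    stop_retinaquant("radii, sigmas and noise levels must be >= 0",
                     "scene_config_error")
  bands <- cfg$layer_bands
  if (length(bands) > 0) {
    b <- do.call(rbind, bands)
    if (any(b[, 1] > b[, 2]) || any(b < 0) ||
        any(b[, 2] >= cfg$image_height_px))
      stop_retinaquant("layer bands must lie inside the image",
                       "scene_config_error")
    if (length(bands) > 1) {
      o <- order(b[, 1])
      if (any(b[o, 1][-1] <= b[o, 2][-length(bands)]))
        stop_retinaquant("layer bands must be disjoint", "scene_config_error")
    }
  }
  invisible(cfg)
}

# filled-ellipse pixel set: center (r0, c0) 0-based, semi-axes a >= b (px),
# orientation theta; returns 1-based (row, col) index matrix
.ellipse_pixels <- function(r0, c0, a, b, theta, h, w) {
  rad <- ceiling(max(a, b))
  rr <- max(0, floor(r0 - rad)):min(h - 1, ceiling(r0 + rad))
  cc <- max(0, floor(c0 - rad)):min(w - 1, ceiling(c0 + rad))
  g <- expand.grid(row = rr, col = cc)
  dr <- g$row - r0; dc <- g$col - c0
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  ok <- (u / a)^2 + (v / b)^2 <= 1
  cbind(g$row[ok] + 1L, g$col[ok] + 1L)
}

#' Generate a synthetic retinal section with exact ground truth
#'
#' Places nuclei (filled ellipses, axis ratio drawn in `[0.7, 1]`, random
#' orientation) in each layer band and leukocytes (ellipse body containing a
#' concentric DAPI nucleus) anywhere, by rejection sampling under the
#' non-touching constraint (1000 retries per cell, then a capacity error).
#' Channels: DAPI (all nuclei incl. leukocyte nuclei), PCNA (PCNA+ nuclear
#' subset; footprint identical to the DAPI footprint before blur), L-plastin
#' (leukocyte bodies), optional TUNEL and HuC/D. The ideal image is blurred
#' with a Gaussian PSF and corrupted with Poisson shot noise plus Gaussian
#' read noise, then rounded and clipped to 16-bit.
#'
#' @param config a [scene_config()].
#' @return list with `stack` (an [image_stack()]) and `truth` (class
#'   `ground_truth`: `cells` data.frame, per-channel `label_maps`, exact
#'   `counts` per marker combination).
#' @export
generate_section <- function(config) {
  .validate_scene_config(config)
  with_seed(config$seed, .generate_section_impl(config))
}

.generate_section_impl <- function(cfg) {
  h <- cfg$image_height_px; w <- cfg$image_width_px
  px <- cfg$pixel_size_um
  channels <- c("DAPI", "PCNA", "Lplastin")
  if (cfg$tunel_positive_fraction > 0) channels <- c(channels, "TUNEL")
  if (cfg$hucd_positive_fraction > 0) channels <- c(channels, "HuCD")

  cells <- list()
  placed <- matrix(numeric(0), ncol = 3)  # row, col, radius_px (max footprint)

  try_place <- function(radius_px, row_range, extra_margin = 0) {
    min_sep_px <- cfg$min_center_separation_um / px
    for (attempt in seq_len(1000)) {
      r0 <- runif(1, row_range[1] + radius_px, row_range[2] - radius_px)
      c0 <- runif(1, radius_px, w - 1 - radius_px)
      if (nrow(placed) > 0) {
        d <- sqrt((placed[, 1] - r0)^2 + (placed[, 2] - c0)^2)
        req <- pmax(min_sep_px, placed[, 3] + radius_px + 1 + extra_margin)
        if (any(d < req)) next
      }
      return(c(r0, c0))
    }
    stop_retinaquant(paste0(
      "could not place a cell after 1000 retries; reduce density or ",
      "min_center_separation_um"), "placement_capacity_error")
  }

  cell_id <- 0L
  add_cell <- function(class, r0, c0, radius_px, z, chans, axis_ratio,
                       theta) {
    cell_id <<- cell_id + 1L
    cells[[cell_id]] <<- list(cell_id = cell_id, class = class, z = z,
                              row = r0, col = c0, radius_px = radius_px,
                              axis_ratio = axis_ratio, theta = theta,
                              channels = chans)
    placed <<- rbind(placed, c(r0, c0, radius_px))
  }

  # nuclei per layer band
  for (band_i in seq_along(cfg$layer_bands)) {
    band <- cfg$layer_bands[[band_i]]
    band_name <- names(cfg$layer_bands)[band_i]
    is_inner <- !identical(band_name, "ONL")
    for (k in seq_len(cfg$n_nuclei_per_layer)) {
      r_um <- max(0.5 * cfg$nucleus_radius_um[1],
                  rnorm(1, cfg$nucleus_radius_um[1], cfg$nucleus_radius_um[2]))
      radius_px <- r_um / px
      # HuC/D rings extend 2 px beyond the nucleus; keep rings non-touching too
      ring_margin <- if (cfg$hucd_positive_fraction > 0) 5 else 0
      pos <- try_place(radius_px, band, extra_margin = ring_margin)
      chans <- "DAPI"
      if (runif(1) < cfg$pcna_positive_fraction) chans <- c(chans, "PCNA")
      if (cfg$tunel_positive_fraction > 0 &&
          runif(1) < cfg$tunel_positive_fraction) chans <- c(chans, "TUNEL")
      if (cfg$hucd_positive_fraction > 0 && is_inner &&
          runif(1) < cfg$hucd_positive_fraction) chans <- c(chans, "HuCD")
      add_cell("nucleus", pos[1], pos[2], radius_px,
               z = sample.int(cfg$n_z, 1),
               chans = chans, axis_ratio = runif(1, 0.7, 1),
               theta = runif(1, 0, pi))
    }
  }

  # leukocytes: body (Lplastin) containing a concentric nucleus (DAPI)
  for (k in seq_len(cfg$n_leukocytes)) {
    r_um <- max(0.5 * cfg$leukocyte_radius_um[1],
                rnorm(1, cfg$leukocyte_radius_um[1],
                      cfg$leukocyte_radius_um[2]))
    radius_px <- r_um / px
    pos <- try_place(radius_px, c(0, h - 1))
    chans <- c("Lplastin", "DAPI")
    if (runif(1) < cfg$leukocyte_nuclear_pcna_fraction)
      chans <- c(chans, "PCNA")
    add_cell("leukocyte", pos[1], pos[2], radius_px,
             z = sample.int(cfg$n_z, 1),
             chans = chans, axis_ratio = runif(1, 0.7, 1),
             theta = runif(1, 0, pi))
  }

  # rasterize: per-channel ideal masks and label maps
  label_maps <- lapply(channels, function(ch)
    array(0L, dim = c(h, w, cfg$n_z)))
  names(label_maps) <- channels
  draw <- function(ch, z, pix, id) {
    m <- label_maps[[ch]][, , z]
    m[pix] <- id
    label_maps[[ch]][, , z] <<- m
  }
  leuk_nucleus_scale <- 0.45
  hucd_ring_px <- 2

  cell_rows <- list()
  for (cl in cells) {
    a <- cl$radius_px; b <- cl$radius_px * cl$axis_ratio
    if (cl$class == "nucleus") {
      pix <- .ellipse_pixels(cl$row, cl$col, a, b, cl$theta, h, w)
      nuc_pix <- pix
    } else {
      body <- .ellipse_pixels(cl$row, cl$col, a, b, cl$theta, h, w)
      draw("Lplastin", cl$z, body, cl$cell_id)
      nuc_pix <- .ellipse_pixels(cl$row, cl$col, a * leuk_nucleus_scale,
                                 b * leuk_nucleus_scale, cl$theta, h, w)
      pix <- nuc_pix
    }
    draw("DAPI", cl$z, nuc_pix, cl$cell_id)
    if ("PCNA" %in% cl$channels) draw("PCNA", cl$z, nuc_pix, cl$cell_id)
    if ("TUNEL" %in% cl$channels) draw("TUNEL", cl$z, nuc_pix, cl$cell_id)
    if ("HuCD" %in% cl$channels) {
      ring <- .ellipse_pixels(cl$row, cl$col, a + hucd_ring_px,
                              b + hucd_ring_px, cl$theta, h, w)
      keep <- !(paste(ring[, 1], ring[, 2]) %in%
                  paste(nuc_pix[, 1], nuc_pix[, 2]))
      draw("HuCD", cl$z, ring[keep, , drop = FALSE], cl$cell_id)
    }
    cell_rows[[cl$cell_id]] <- data.frame(
      cell_id = cl$cell_id, class = cl$class, z = cl$z,
      centroid_row = cl$row, centroid_col = cl$col,
      area_px = nrow(nuc_pix),
      DAPI = "DAPI" %in% cl$channels,
      PCNA = "PCNA" %in% cl$channels,
      Lplastin = "Lplastin" %in% cl$channels,
      TUNEL = "TUNEL" %in% cl$channels,
      HuCD = "HuCD" %in% cl$channels)
  }
  cells_df <- if (length(cell_rows) > 0) do.call(rbind, cell_rows) else
    data.frame(cell_id = integer(0), class = character(0), z = integer(0),
               centroid_row = numeric(0), centroid_col = numeric(0),
               area_px = integer(0), DAPI = logical(0), PCNA = logical(0),
               Lplastin = logical(0), TUNEL = logical(0), HuCD = logical(0))

  counts <- .truth_counts(cells_df)

  # render: ideal (unit scale) -> PSF blur -> photons -> shot + read noise
  sigma_px <- cfg$psf_sigma_um / px
  pixels <- array(0, dim = c(h, w, cfg$n_z, length(channels)))
  for (ci in seq_along(channels)) {
    for (z in seq_len(cfg$n_z)) {
      ideal <- cfg$background_level + (label_maps[[ci]][, , z] > 0)
      if (sigma_px > 0) ideal <- gaussian_blur(ideal, sigma_px)
      photons <- cfg$photon_scale * ideal
      noisy <- rpois(h * w, photons)
      if (cfg$read_noise_sd > 0)
        noisy <- noisy + rnorm(h * w, 0, cfg$read_noise_sd)
      pixels[, , z, ci] <- matrix(pmin(pmax(round(noisy), 0), 65535), h, w)
    }
  }
  stack <- image_stack(pixels, channels, pixel_size_um = px)
  truth <- structure(list(cells = cells_df, label_maps = label_maps,
                          counts = counts),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

# exact counts per marker combination from the cell records
.truth_counts <- function(cells_df) {
  cnt <- function(expr) sum(expr)
  with(cells_df, list(
    "DAPI" = cnt(DAPI),
    "PCNA" = cnt(PCNA),
    "Lplastin" = cnt(Lplastin),
    "TUNEL" = cnt(TUNEL),
    "HuCD" = cnt(HuCD),
    "DAPI&PCNA" = cnt(DAPI & PCNA),
    "Lplastin&PCNA" = cnt(Lplastin & PCNA),
    "DAPI&TUNEL" = cnt(DAPI & TUNEL),
    "DAPI&HuCD" = cnt(DAPI & HuCD)))
}

#' Recount ground truth from the emitted label maps
#'
#' Independent of the `counts` field: counts the distinct cell ids present in
#' each channel's label maps (and their intersections), which must equal the
#' record-derived counts.
#'
#' @param truth a `ground_truth`.
#' @return named list of counts, same keys as `truth$counts`.
#' @export
recount_label_maps <- function(truth) {
  ids <- function(ch) {
    m <- truth$label_maps[[ch]]
    if (is.null(m)) integer(0) else sort(unique(m[m > 0]))
  }
  combos <- names(truth$counts)
  out <- lapply(combos, function(cmb) {
    chs <- strsplit(cmb, "&", fixed = TRUE)[[1]]
    length(Reduce(intersect, lapply(chs, ids)))
  })
  names(out) <- combos
  out
}

#' Write ground-truth cell records to CSV
#' @param truth a `ground_truth`.
#' @param path output CSV path.
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(truth$cells, path, row.names = FALSE)
  invisible(path)
}
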