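# end-to-end counting on synthetic scenes with exact ground truth

test_that("noiseless scene: colocalization count is exact, density consistent", {
  cfg <- noiseless_config(seed = 31)
  sec <- generate_section(cfg)
  roi <- full_field_roi(cfg)
  rec <- count_coloc(sec$stack, "DAPI", "PCNA", roi, default_params,
                     sample_id = "s1", group = list(line = "mpeg1:FP",
                                                    treatment = "ouabain",
                                                    dpi = 4L))
  expect_equal(rec$raw_count, sec$truth$counts[["DAPI&PCNA"]])
  expect_equal(rec$density * rec$roi_normalizer, rec$raw_count)
  expect_identical(rec$marker_combo, "DAPI&PCNA")
  pp <- attr(rec, "per_plane")
  expect_equal(sum(pp$count), rec$raw_count)
})

test_that("all PCNA-negative scene counts zero; blank channel counts zero", {
  cfg <- noiseless_config(seed = 32, pcna_positive_fraction = 0,
                          n_leukocytes = 0)
  sec <- generate_section(cfg)
  roi <- full_field_roi(cfg)
  expect_warning(
    rec <- count_coloc(sec$stack, "DAPI", "PCNA", roi, default_params),
    "degenerate")
  expect_equal(rec$raw_count, 0)
  expect_warning(
    rec2 <- count_single_marker(sec$stack, "PCNA", roi, default_params),
    "degenerate")
  expect_equal(rec2$raw_count, 0)
})

test_that("single-marker counts: TUNEL and L-plastin exact on noiseless scenes", {
  cfg <- noiseless_config(seed = 33, tunel_positive_fraction = 0.25)
  sec <- generate_section(cfg)
  roi <- full_field_roi(cfg)
  tun <- count_single_marker(sec$stack, "TUNEL", roi, default_params)
  expect_equal(tun$raw_count, sec$truth$counts[["TUNEL"]])
  lp <- count_single_marker(sec$stack, "Lplastin", roi, default_params)
  expect_equal(lp$raw_count, sec$truth$counts[["Lplastin"]])
})

test_that("polyline ROI: curvilinear density and band membership", {
  cfg <- noiseless_config(seed = 34)
  sec <- generate_section(cfg)
  # horizontal mid-line through the INL band; generous band covers the image
  line <- roi_polyline(rbind(c(180, 0), c(180, cfg$image_width_px - 1)))
  rec <- count_coloc(sec$stack, "DAPI", "PCNA", line, default_params)
  expect_equal(rec$raw_count, sec$truth$counts[["DAPI&PCNA"]])
  expect_identical(rec$roi_unit, "mm")
  expect_equal(rec$roi_normalizer,
               polyline_length(line, cfg$pixel_size_um) / 1e3)
  expect_equal(rec$density * rec$roi_normalizer, rec$raw_count)
  # a narrow band restricted to the INL counts fewer objects
  narrow <- segmentation_params(roi_band_halfwidth_px = 50)
  rec2 <- count_coloc(sec$stack, "DAPI", "PCNA", line, narrow)
  expect_lte(rec2$raw_count, rec$raw_count)
})

test_that("counts invariant under joint 90-degree rotation of image + ROI", {
  cfg <- noiseless_config(
    seed = 35, image_height_px = 120, image_width_px = 120,
    layer_bands = list(B1 = c(10, 55), B2 = c(65, 110)),
    n_nuclei_per_layer = 10, n_leukocytes = 2)
  sec <- generate_section(cfg)
  roi <- roi_polygon(rbind(c(5, 5), c(5, 110), c(110, 110), c(110, 5)))
  rec <- count_coloc(sec$stack, "DAPI", "PCNA", roi, default_params)

  h <- cfg$image_height_px
  rot_px <- sec$stack$pixels
  rot_px <- aperm(rot_px, c(2, 1, 3, 4))[, h:1, , , drop = FALSE]
  rot_stack <- image_stack(rot_px, sec$stack$channel_names,
                           cfg$pixel_size_um)
  # (r, c) -> (c, H - 1 - r)
  rot_v <- cbind(roi$vertices[, 2], h - 1 - roi$vertices[, 1])
  rot_roi <- roi_polygon(rot_v)
  rec_rot <- count_coloc(rot_stack, "DAPI", "PCNA", rot_roi, default_params)
  expect_equal(rec_rot$raw_count, rec$raw_count)
  expect_equal(rec_rot$density, rec$density)
})

test_that("colocalized count never exceeds single-channel counts", {
  cfg <- scene_config(seed = 36)  # default noise model
  sec <- generate_section(cfg)
  roi <- full_field_roi(cfg)
  ab <- count_coloc(sec$stack, "DAPI", "PCNA", roi, default_params)
  a <- count_single_marker(sec$stack, "DAPI", roi, default_params)
  b <- count_single_marker(sec$stack, "PCNA", roi, default_params)
  expect_lte(ab$raw_count, a$raw_count)
  expect_lte(ab$raw_count, b$raw_count)
})

test_that("missing channel raises a named error", {
  cfg <- noiseless_config(seed = 37, n_nuclei_per_layer = 2)
  sec <- generate_section(cfg)
  roi <- full_field_roi(cfg)
  expect_error(count_coloc(sec$stack, "DAPI", "GFAP", roi),
               class = "missing_channel_error")
  expect_error(count_single_marker(sec$stack, "GFAP", roi),
               class = "missing_channel_error")
})

# ---- marker scoring ------------------------------------------------------

test_that("score_cells trivial contracts: superset partner, empty partner", {
  cell <- matrix(FALSE, 30, 30); cell[5:20, 5:20] <- TRUE
  nuc <- matrix(FALSE, 30, 30); nuc[10:15, 10:15] <- TRUE
  full <- matrix(TRUE, 30, 30); empty <- matrix(FALSE, 30, 30)
  s_pos <- score_cells(cell, nuc, full, "nuclear_overlap", 1)
  expect_equal(s_pos$n_positive, 1)
  s_neg <- score_cells(cell, nuc, empty, "nuclear_overlap")
  expect_equal(s_neg$n_positive, 0)
  # cell without contained nucleus: negative + flagged
  nuc_out <- matrix(FALSE, 30, 30); nuc_out[25:28, 25:28] <- TRUE
  expect_message(s_no <- score_cells(cell, nuc_out, full, "nuclear_overlap"),
                 "without contained nucleus")
  expect_equal(s_no$n_positive, 0)
  expect_true(s_no$scores$no_nucleus[1])
})

test_that("surround rule scores a ring-wrapped nucleus positive", {
  nuc <- matrix(FALSE, 40, 40); nuc[15:25, 15:25] <- TRUE
  ring <- retinaquant:::.dilate_disk(nuc, 3) & !nuc
  s <- score_cells(nuc, NULL, ring, "surround", 0.9, annulus_px = 3)
  expect_equal(s$n_positive, 1)
  s2 <- score_cells(nuc, NULL, matrix(FALSE, 40, 40), "surround")
  expect_equal(s2$n_positive, 0)
})

test_that("programmed leukocyte nuclear-PCNA fraction is recovered", {
  cfg <- noiseless_config(seed = 38, n_nuclei_per_layer = 0,
                          n_leukocytes = 25,
                          leukocyte_nuclear_pcna_fraction = 0.4)
  sec <- generate_section(cfg)
  params <- default_params
  lp <- retinaquant:::.segment_plane(sec$stack$pixels[, , 1, "Lplastin"],
                                     params)
  da <- retinaquant:::.segment_plane(sec$stack$pixels[, , 1, "DAPI"], params)
  pc_plane <- sec$stack$pixels[, , 1, "PCNA"]
  pc <- if (length(unique(as.vector(pc_plane))) < 2)
    matrix(FALSE, nrow(pc_plane), ncol(pc_plane))
  else retinaquant:::.segment_plane(pc_plane, params)$mask
  sc <- score_cells(lp$mask, da$mask, pc, "nuclear_overlap", 0.5)
  truth_pos <- sec$truth$counts[["Lplastin&PCNA"]]
  expect_equal(sc$n_positive, truth_pos)
  expect_equal(nrow(sc$scores), sec$truth$counts[["Lplastin"]])
})
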