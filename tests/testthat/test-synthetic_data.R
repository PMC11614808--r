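test_that("blank config gives background-only image and empty truth", {
  cfg <- scene_config(n_nuclei_per_layer = 0, n_leukocytes = 0, seed = 1)
  sec <- generate_section(cfg)
  expect_equal(nrow(sec$truth$cells), 0)
  expect_true(all(unlist(sec$truth$counts) == 0))
  # no structure: mean close to background photon level
  expect_lt(mean(sec$stack$pixels),
            cfg$photon_scale * cfg$background_level * 1.5)
})

test_that("single PCNA+ nucleus: identical DAPI/PCNA footprints, exact counts", {
  cfg <- scene_config(image_height_px = 64, image_width_px = 64,
                      layer_bands = list(ONL = c(8, 55)),
                      n_nuclei_per_layer = 1, pcna_positive_fraction = 1,
                      n_leukocytes = 0, psf_sigma_um = 0, read_noise_sd = 0,
                      background_level = 0, photon_scale = 1000, seed = 7)
  sec <- generate_section(cfg)
  dapi <- sec$truth$label_maps$DAPI[, , 1]
  pcna <- sec$truth$label_maps$PCNA[, , 1]
  expect_identical(dapi, pcna)
  expect_gt(sum(dapi > 0), 0)
  expect_equal(sec$truth$counts[["DAPI&PCNA"]], 1)
  expect_equal(sec$truth$counts[["DAPI"]], 1)
})

test_that("determinism: identical config + seed gives bit-identical output", {
  cfg <- scene_config(image_height_px = 120, image_width_px = 120,
                      layer_bands = list(B1 = c(10, 50), B2 = c(60, 100)),
                      n_nuclei_per_layer = 8, n_leukocytes = 2, seed = 11)
  s1 <- generate_section(cfg)
  s2 <- generate_section(cfg)
  expect_identical(s1$stack$pixels, s2$stack$pixels)
  expect_identical(s1$truth$cells, s2$truth$cells)
  f1 <- tempfile(); f2 <- tempfile()
  write_stack(s1$stack, f1); write_stack(s2$stack, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  s3 <- generate_section(scene_config(image_height_px = 120,
                                      image_width_px = 120,
                                      layer_bands = list(B1 = c(10, 50),
                                                         B2 = c(60, 100)),
                                      n_nuclei_per_layer = 8,
                                      n_leukocytes = 2, seed = 12))
  expect_false(identical(s1$stack$pixels, s3$stack$pixels))
})

test_that("ground-truth counts equal a brute-force label-map recount", {
  cfg <- scene_config(seed = 1, tunel_positive_fraction = 0.2,
                      hucd_positive_fraction = 0.5)
  sec <- generate_section(cfg)
  recount <- recount_label_maps(sec$truth)
  for (combo in names(sec$truth$counts))
    expect_equal(recount[[combo]], sec$truth$counts[[combo]],
                 info = combo)
  # binomial sanity for the 150-nuclei default at 30% PCNA+
  n_nuc <- sum(sec$truth$cells$class == "nucleus")
  expect_equal(n_nuc, 150)
  pc <- sum(sec$truth$cells$PCNA[sec$truth$cells$class == "nucleus"])
  expect_gt(pc, qbinom(1e-6, 150, 0.3))
  expect_lt(pc, qbinom(1 - 1e-6, 150, 0.3))
})

test_that("counts field is conserved over disjoint channel combinations", {
  sec <- generate_section(scene_config(seed = 5))
  cells <- sec$truth$cells
  # PCNA+ and PCNA- nuclei partition DAPI+ cells
  expect_equal(sec$truth$counts[["DAPI&PCNA"]] +
                 sum(cells$DAPI & !cells$PCNA),
               sec$truth$counts[["DAPI"]])
  expect_equal(sum(cells$class == "nucleus") +
                 sum(cells$class == "leukocyte"), nrow(cells))
})

test_that("pre-noise containment: PCNA mask subset of DAPI mask (psf=0)", {
  sec <- generate_section(scene_config(seed = 2, psf_sigma_um = 0))
  dapi <- sec$truth$label_maps$DAPI > 0
  pcna <- sec$truth$label_maps$PCNA > 0
  expect_true(all(dapi[pcna]))
})

test_that("infeasible placement raises a capacity error", {
  cfg <- scene_config(image_height_px = 80, image_width_px = 80,
                      layer_bands = list(ONL = c(10, 30)),
                      n_nuclei_per_layer = 200, n_leukocytes = 0, seed = 1)
  expect_error(generate_section(cfg), class = "placement_capacity_error")
})

test_that("scene config validation", {
  expect_error(scene_config(pcna_positive_fraction = 1.2),
               class = "scene_config_error")
  expect_error(scene_config(layer_bands = list(A = c(10, 50), B = c(40, 90))),
               class = "scene_config_error")
  expect_error(scene_config(layer_bands = list(A = c(300, 400))),
               class = "scene_config_error")
  expect_error(scene_config(psf_sigma_um = -1), class = "scene_config_error")
})

test_that("ground truth writes a per-cell CSV", {
  sec <- generate_section(scene_config(
    image_height_px = 100, image_width_px = 100,
    layer_bands = list(B = c(10, 90)), n_nuclei_per_layer = 5,
    n_leukocytes = 1, seed = 3))
  f <- tempfile(fileext = ".csv")
  write_ground_truth(sec$truth, f)
  got <- read.csv(f)
  expect_equal(nrow(got), 6)
  expect_true(all(c("cell_id", "class", "area_px", "DAPI", "PCNA") %in%
                    names(got)))
})

# ---- qPCR generator ------------------------------------------------------

test_that("zero-noise, zero-fold design: ddCt pipeline returns fold 1", {
  d <- zero_noise_design()
  tab <- generate_qpcr(d)
  expect_true(all(!tab$nondetect))
  for (g in setdiff(d$genes, "18s")) {
    res <- delta_delta_ct(tab, g, "18s")
    expect_equal(res$fold_change, rep(1, nrow(res)))
  }
})

test_that("programmed +3 log2 fold is recovered as fold 8 downstream", {
  prog <- data.frame(gene = "ascl1a", line = "mpeg1:FP",
                     treatment = "ouabain", dpi = 4L, log2_fold = 3)
  d <- zero_noise_design(programmed_log2_fold = prog)
  tab <- generate_qpcr(d)
  res <- delta_delta_ct(tab, "ascl1a", "18s")
  ouab <- res[res$treatment == "ouabain" & res$line == "mpeg1:FP", ]
  expect_equal(ouab$fold_change, rep(8, nrow(ouab)))
  sal <- res[res$treatment == "saline" & res$line == "mpeg1:FP", ]
  expect_equal(sal$fold_change, rep(1, nrow(sal)))
})

test_that("noisy fold recovery: geometric mean within closed-form bounds", {
  # design: fold 4, tech sd 0.3, 6 biological replicates
  prog <- data.frame(gene = "ascl1a", line = "mpeg1:FP",
                     treatment = "ouabain", dpi = 4L, log2_fold = 2)
  d <- qpcr_design(programmed_log2_fold = prog, ct_noise_sd = 0.3,
                   reference_drift_sd = 0.3, seed = 21)
  tab <- generate_qpcr(d)
  res <- delta_delta_ct(tab, "ascl1a", "18s", match_on = c("dpi", "line"))
  ouab <- res[res$treatment == "ouabain" & res$line == "mpeg1:FP", ]
  gm_log2 <- mean(log2(ouab$fold_change))
  # closed form: per-sample dCt noise sd = sqrt(2) * 0.3 / sqrt(3); the
  # group geometric mean and the calibrator mean each contribute var/6
  sd_gm <- sqrt(2 * (0.3^2 / 3) * (1 / 6 + 1 / 6))
  expect_lt(abs(gm_log2 - 2), 4 * sd_gm)
})

test_that("non-detects: cycle-limit censoring and missing-reference error", {
  d <- zero_noise_design(genes = c("18s", "lin28a"),
                         baseline_ct = c("18s" = 12, "lin28a" = 41))
  tab <- generate_qpcr(d)
  lin <- tab[tab$gene == "lin28a", ]
  expect_true(all(lin$nondetect))
  expect_true(all(is.na(lin$ct)))
  expect_error(qpcr_design(genes = c("ascl1a"), reference_gene = "18s",
                           baseline_ct = c("ascl1a" = 26)),
               class = "qpcr_config_error")
  expect_error(
    qpcr_design(programmed_log2_fold = data.frame(
      gene = "18s", line = "mpeg1:FP", treatment = "ouabain", dpi = 4L,
      log2_fold = 1)),
    class = "qpcr_config_error")
})

test_that("qPCR generation is deterministic and tables round-trip CSV", {
  d <- qpcr_design(seed = 5)
  t1 <- generate_qpcr(d); t2 <- generate_qpcr(d)
  expect_identical(t1, t2)
  f <- tempfile(fileext = ".csv")
  write_ct_table(t1, f)
  t3 <- read_ct_table(f)
  expect_equal(t3$ct, t1$ct)
  expect_identical(t3$nondetect, t1$nondetect)
})
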