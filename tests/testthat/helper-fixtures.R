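# Shared scene/ROI builders used across test files.

# noiseless, blur-free scene: segmentation must recover counts exactly
noiseless_config <- function(seed = 1, ...) {
  scene_config(psf_sigma_um = 0, read_noise_sd = 0,
               photon_scale = 1e6,   # shot noise negligible
               background_level = 0, seed = seed, ...)
}

full_field_roi <- function(cfg) {
  roi_polygon(rbind(c(0, 0), c(0, cfg$image_width_px - 1),
                    c(cfg$image_height_px - 1, cfg$image_width_px - 1),
                    c(cfg$image_height_px - 1, 0)), label = "full_field")
}

# small noiseless design for qPCR round trips
zero_noise_design <- function(...) {
  qpcr_design(ct_noise_sd = 0, reference_drift_sd = 0, ...)
}

default_params <- segmentation_params()
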