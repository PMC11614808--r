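#' Multi-channel z-stack container
#'
#' The unit every imaging operation in the package consumes: a 4-D array of
#' non-negative intensities indexed `[row, col, z, channel]`, with named
#' channels and physical pixel size. Confocal anisotropy in z is carried as
#' metadata only; all measurements are in-plane.
#'
#' @param pixels numeric array, dim `c(rows, cols, n_z, n_channels)`. A 2-D
#'   matrix is promoted to a single-plane single-channel stack.
#' @param channel_names character vector, one unique name per channel.
#' @param pixel_size_um in-plane pixel size in micrometres (> 0). Never
#'   defaulted: acquisition metadata must be supplied explicitly.
#' @param z_step_um z spacing in micrometres (> 0); confocal sections are
#'   typically acquired at 2-3 um intervals.
#' @param dtype_max maximum representable intensity (65535 for 16-bit cameras).
#' @return an `image_stack` object.
#' @export
image_stack <- function(pixels, channel_names, pixel_size_um,
                        z_step_um = 2, dtype_max = 65535) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L, 1L)
  if (length(dim(pixels)) != 4)
    stop_retinaquant("pixels must be a [row, col, z, channel] array",
                     "stack_format_error")
  channel_names <- as.character(channel_names)
  if (length(channel_names) != dim(pixels)[4])
    stop_retinaquant(sprintf(
      "channel axis has length %d but %d channel names given",
      dim(pixels)[4], length(channel_names)), "stack_format_error")
  if (anyDuplicated(channel_names))
    stop_retinaquant("channel names must be unique", "stack_format_error")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      pixel_size_um <= 0)
    stop_retinaquant("pixel_size_um must be a positive scalar",
                     "stack_format_error")
  if (z_step_um <= 0)
    stop_retinaquant("z_step_um must be positive", "stack_format_error")
  if (any(pixels < 0) || any(pixels > dtype_max))
    stop_retinaquant("intensities must lie in [0, dtype_max]",
                     "stack_format_error")
  dimnames(pixels) <- list(NULL, NULL, NULL, channel_names)
  structure(list(pixels = pixels, channel_names = channel_names,
                 pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 dtype_max = dtype_max),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "image_stack: %d x %d px, %d z-plane(s), channels [%s], %.4g um/px\n",
    d[1], d[2], d[3], paste(x$channel_names, collapse = ", "),
    x$pixel_size_um))
  invisible(x)
}

#' Extract one channel plane from a stack
#' @param stack an `image_stack`.
#' @param channel channel name.
#' @param z z index (1-based).
#' @return numeric matrix.
#' @export
get_plane <- function(stack, channel, z = 1) {
  if (!channel %in% stack$channel_names)
    stop_retinaquant(paste0("channel not in stack: ", channel),
                     "missing_channel_error")
  stack$pixels[, , z, channel]
}

n_z <- function(stack) dim(stack$pixels)[3]

.serialize_stack_meta <- function(stack) {
  paste0("retinaquant_stack\n",
         "channels=", paste(stack$channel_names, collapse = ","), "\n",
         "n_z=", dim(stack$pixels)[3], "\n",
         "pixel_size_um=", format(stack$pixel_size_um, digits = 17), "\n",
         "z_step_um=", format(stack$z_step_um, digits = 17), "\n",
         "dtype_max=", format(stack$dtype_max, digits = 17))
}

.parse_stack_meta <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 1 || lines[1] != "retinaquant_stack") return(NULL)
  kv <- strsplit(lines[-1], "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  list(channels = strsplit(vals[["channels"]], ",", fixed = TRUE)[[1]],
       n_z = as.integer(vals[["n_z"]]),
       pixel_size_um = as.numeric(vals[["pixel_size_um"]]),
       z_step_um = as.numeric(vals[["z_step_um"]]),
       dtype_max = as.numeric(vals[["dtype_max"]]))
}

#' Write an image stack to multi-page TIFF
#'
#' Planes are interleaved channel-fastest (all channels of z=1, then z=2, ...),
#' i.e. dimension order XYCZ. Channel names, pixel size and z step are stored
#' in the first page's ImageDescription; with `sidecar = TRUE` the same
#' metadata is additionally written to `<path>.meta` as structured text so
#' plain-TIFF consumers can recover channel names.
#'
#' @param stack an `image_stack` with integer-valued intensities.
#' @param path output path.
#' @param sidecar also write a `<path>.meta` text sidecar.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = FALSE) {
  d <- dim(stack$pixels)
  bits <- if (stack$dtype_max <= 255) 8L else 16L
  planes <- vector("list", d[3] * d[4])
  k <- 1
  for (z in seq_len(d[3])) for (ch in seq_len(d[4])) {
    planes[[k]] <- stack$pixels[, , z, ch]
    k <- k + 1
  }
  meta <- .serialize_stack_meta(stack)
  write_tiff(path, planes, bits = bits, description = meta)
  if (sidecar) writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read an image stack from multi-page TIFF
#'
#' Metadata resolution order: embedded ImageDescription written by
#' [write_stack()], then a `<path>.meta` sidecar, then the explicit arguments.
#' The plane count must be divisible by the channel count.
#'
#' @param path TIFF path.
#' @param channel_names channel names, required when no metadata is found.
#' @param pixel_size_um,z_step_um physical calibration, required when no
#'   metadata is found.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, channel_names = NULL, pixel_size_um = NULL,
                       z_step_um = 2) {
  tf <- read_tiff(path)
  meta <- if (!is.null(tf$description)) .parse_stack_meta(tf$description)
  if (is.null(meta) && file.exists(paste0(path, ".meta")))
    meta <- .parse_stack_meta(paste(readLines(paste0(path, ".meta")),
                                    collapse = "\n"))
  dtype_max <- 2^tf$bits - 1
  if (!is.null(meta)) {
    channel_names <- meta$channels
    pixel_size_um <- meta$pixel_size_um
    z_step_um <- meta$z_step_um
    dtype_max <- meta$dtype_max
  }
  if (is.null(channel_names))
    stop_retinaquant("no channel metadata found; pass channel_names",
                     "stack_format_error")
  if (is.null(pixel_size_um))
    stop_retinaquant("no pixel size metadata found; pass pixel_size_um",
                     "stack_format_error")
  n_ch <- length(channel_names)
  n_pl <- length(tf$planes)
  if (n_pl %% n_ch != 0)
    stop_retinaquant(sprintf(
      "%d planes are not divisible by %d declared channels", n_pl, n_ch),
      "stack_format_error")
  nz <- n_pl / n_ch
  h <- nrow(tf$planes[[1]]); w <- ncol(tf$planes[[1]])
  px <- array(0, dim = c(h, w, nz, n_ch))
  k <- 1
  for (z in seq_len(nz)) for (ch in seq_len(n_ch)) {
    px[, , z, ch] <- tf$planes[[k]]
    k <- k + 1
  }
  image_stack(px, channel_names, pixel_size_um, z_step_um, dtype_max)
}
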