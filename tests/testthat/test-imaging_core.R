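test_that("stack write/read round-trips pixels and metadata exactly", {
  px <- array(as.numeric(sample(0:65535, 24 * 18 * 3 * 2, replace = TRUE)),
              dim = c(24, 18, 3, 2))
  st <- image_stack(px, c("DAPI", "PCNA"), pixel_size_um = 0.325,
                    z_step_um = 2.5)
  path <- tempfile(fileext = ".tif")
  write_stack(st, path)
  st2 <- read_stack(path)
  expect_equal(st2$pixels, st$pixels)
  expect_identical(st2$channel_names, c("DAPI", "PCNA"))
  expect_equal(st2$pixel_size_um, 0.325)
  expect_equal(st2$z_step_um, 2.5)

  # single-plane single-channel file -> [H][W][1][1]
  st1 <- image_stack(matrix(0:99, 10, 10), "DAPI", pixel_size_um = 1)
  p1 <- tempfile(fileext = ".tif")
  write_stack(st1, p1)
  expect_equal(dim(read_stack(p1)$pixels), c(10, 10, 1, 1))

  # sidecar metadata path for plain TIFF consumers
  p2 <- tempfile(fileext = ".tif")
  write_stack(st, p2, sidecar = TRUE)
  expect_true(file.exists(paste0(p2, ".meta")))
})

test_that("plane count must divide by declared channels", {
  planes <- lapply(1:7, function(i) matrix(i, 4, 4))
  path <- tempfile(fileext = ".tif")
  retinaquant:::write_tiff(path, planes, bits = 8)
  expect_error(read_stack(path, channel_names = c("A", "B"),
                          pixel_size_um = 1),
               class = "stack_format_error")
  expect_error(read_stack(path), class = "stack_format_error")
  expect_error(read_stack(tempfile(), channel_names = "A"),
               class = "tiff_format_error")
})

test_that("stack validation rejects bad inputs", {
  px <- array(0, dim = c(4, 4, 1, 2))
  expect_error(image_stack(px, "onlyone", 1), class = "stack_format_error")
  expect_error(image_stack(px, c("A", "A"), 1), class = "stack_format_error")
  expect_error(image_stack(px, c("A", "B"), -1), class = "stack_format_error")
  expect_error(image_stack(px - 1, c("A", "B"), 1),
               class = "stack_format_error")
  expect_error(get_plane(image_stack(px, c("A", "B"), 1), "C"),
               class = "missing_channel_error")
})

test_that("polygon_area: shoelace, orientation-independent, unit-scaled", {
  sq <- rbind(c(0, 0), c(0, 1), c(1, 1), c(1, 0))
  expect_equal(polygon_area(roi_polygon(sq), 1), 1)
  expect_equal(polygon_area(roi_polygon(sq[4:1, ]), 1), 1)
  # triangle (0,0),(0,4),(3,0): 6 px^2 -> 1.5 um^2 at 0.5 um/px
  tri <- roi_polygon(rbind(c(0, 0), c(0, 4), c(3, 0)))
  expect_equal(polygon_area(tri, 0.5), 1.5)
  expect_error(polygon_area(roi_polyline(rbind(c(0, 0), c(1, 1))), 1),
               class = "roi_kind_error")
})

test_that("polyline_length: Euclidean, unit-scaled, analytic arc check", {
  expect_equal(polyline_length(roi_polyline(rbind(c(0, 0), c(3, 4))), 1), 5)
  expect_equal(polyline_length(
    roi_polyline(rbind(c(0, 0), c(0, 1), c(0, 2))), 1), 2)
  # 100-vertex quarter circle, radius 100 px: length -> 50*pi within 0.1%
  th <- seq(0, pi / 2, length.out = 100)
  arc <- roi_polyline(cbind(100 * sin(th), 100 * cos(th)))
  expect_equal(polyline_length(arc, 1), 50 * pi, tolerance = 1e-3)
  expect_error(polyline_length(roi_polygon(rbind(c(0, 0), c(0, 4), c(3, 0))),
                               1), class = "roi_kind_error")
})

test_that("geometry is invariant under translation and 90-degree rotation,
           and scales as pixel_size^2 / pixel_size^1", {
  set.seed(42)
  for (rep in 1:5) {
    ang <- sort(runif(7, 0, 2 * pi))
    rad <- runif(7, 2, 10)
    v <- cbind(5 + rad * sin(ang), 5 + rad * cos(ang))
    pgon <- roi_polygon(v)  # star-shaped around (5,5): always simple
    line <- roi_polyline(v)
    shift <- cbind(v[, 1] + 13.7, v[, 2] - 4.2)
    rot90 <- cbind(v[, 2], -v[, 1])
    expect_equal(polygon_area(roi_polygon(shift), 1), polygon_area(pgon, 1))
    expect_equal(polygon_area(roi_polygon(rot90), 1), polygon_area(pgon, 1))
    expect_equal(polyline_length(roi_polyline(shift), 1),
                 polyline_length(line, 1))
    expect_equal(polyline_length(roi_polyline(rot90), 1),
                 polyline_length(line, 1))
    expect_equal(polygon_area(pgon, 2), 4 * polygon_area(pgon, 1))
    expect_equal(polyline_length(line, 2), 2 * polyline_length(line, 1))
  }
})

test_that("polygon validation: vertex count and self-intersection", {
  expect_error(roi_polygon(rbind(c(0, 0), c(1, 1))), class = "roi_kind_error")
  bowtie <- rbind(c(0, 0), c(2, 2), c(0, 2), c(2, 0))
  expect_error(roi_polygon(bowtie), class = "roi_kind_error")
  expect_error(roi_polyline(rbind(c(0, 0))), class = "roi_kind_error")
})

test_that("points_in_polygon follows the even-odd pixel-center rule", {
  sq <- roi_polygon(rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0)))
  pts <- rbind(c(5, 5), c(-1, 5), c(11, 5), c(5, 15))
  expect_identical(points_in_polygon(pts, sq), c(TRUE, FALSE, FALSE, FALSE))
  # concave polygon: notch excluded by parity
  cshape <- roi_polygon(rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 6),
                              c(2, 6), c(2, 4), c(10, 4), c(10, 0)))
  expect_false(all(points_in_polygon(rbind(c(9, 5)), cshape)))
  expect_true(all(points_in_polygon(rbind(c(1, 5)), cshape)))
})

test_that("ROI text files round-trip; ImageJ .roi files are read", {
  r1 <- roi_polygon(rbind(c(0.5, 1.5), c(0.5, 20), c(30, 20)), "layer GCL")
  path <- tempfile(fileext = ".txt")
  write_roi(r1, path)
  r2 <- read_roi(path)
  expect_equal(r2$vertices, r1$vertices)
  expect_identical(r2$kind, "polygon")
  expect_identical(r2$label, "layer GCL")

  # minimal ImageJ .roi: header "Iout", type polygon(0), bounds, n, coords
  ij <- tempfile(fileext = ".roi")
  be16 <- function(x) as.raw(c(x %/% 256, x %% 256))
  con <- file(ij, "wb")
  writeBin(charToRaw("Iout"), con)             # magic
  writeBin(as.raw(c(0, 227)), con)             # version
  writeBin(as.raw(c(0, 0)), con)               # type 0 = polygon
  writeBin(c(be16(10), be16(20), be16(40), be16(60)), con)  # top,left,bot,right
  writeBin(be16(3), con)                       # n coordinates
  writeBin(raw(64 - 18), con)                  # pad header to 64 bytes
  writeBin(c(be16(0), be16(5), be16(9)), con)  # x offsets
  writeBin(c(be16(0), be16(12), be16(2)), con) # y offsets
  close(con)
  rij <- read_roi(ij)
  expect_identical(rij$kind, "polygon")
  expect_equal(rij$vertices,
               cbind(row = c(10, 22, 12), col = c(20, 25, 29)))
})
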