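#' Regions of interest: polygons (area) and polylines (curvilinear distance)
#'
#' Vertices are 0-based `(row, col)` pixel coordinates referring to pixel
#' centers. Polygons normalize counts per area; polylines normalize per
#' curvilinear distance traced through the section (e.g. along a retinal
#' layer).
#'
#' @param vertices two-column numeric matrix (row, col) or data.frame.
#' @param label optional name.
#' @return a `region_of_interest` object.
#' @export
roi_polygon <- function(vertices, label = "roi") {
  v <- .as_vertex_matrix(vertices)
  if (nrow(v) < 3)
    stop_retinaquant("polygon needs >= 3 vertices", "roi_kind_error")
  if (.polygon_self_intersects(v))
    stop_retinaquant("polygon must be simple (non-self-intersecting)",
                     "roi_kind_error")
  structure(list(kind = "polygon", vertices = v, label = label),
            class = "region_of_interest")
}

#' @rdname roi_polygon
#' @export
roi_polyline <- function(vertices, label = "roi") {
  v <- .as_vertex_matrix(vertices)
  if (nrow(v) < 2)
    stop_retinaquant("polyline needs >= 2 vertices", "roi_kind_error")
  structure(list(kind = "polyline", vertices = v, label = label),
            class = "region_of_interest")
}

.as_vertex_matrix <- function(v) {
  v <- as.matrix(v)
  if (ncol(v) != 2 || !is.numeric(v) || any(!is.finite(v)))
    stop_retinaquant("vertices must be a finite 2-column (row, col) matrix",
                     "roi_kind_error")
  colnames(v) <- c("row", "col")
  v
}

# segment-intersection test on non-adjacent edges (proper crossings only)
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the closing edge
      p <- seg[i, 1:2]; p2 <- seg[i, 3:4]; q <- seg[j, 1:2]; q2 <- seg[j, 3:4]
      d1 <- cross(p2[1] - p[1], p2[2] - p[2], q[1] - p[1], q[2] - p[2])
      d2 <- cross(p2[1] - p[1], p2[2] - p[2], q2[1] - p[1], q2[2] - p[2])
      d3 <- cross(q2[1] - q[1], q2[2] - q[2], p[1] - q[1], p[2] - q[2])
      d4 <- cross(q2[1] - q[1], q2[2] - q[2], p2[1] - q[1], p2[2] - q[2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' @export
print.region_of_interest <- function(x, ...) {
  cat(sprintf("region_of_interest '%s': %s, %d vertices\n",
              x$label, x$kind, nrow(x$vertices)))
  invisible(x)
}

#' Polygon area in square micrometres (shoelace formula)
#'
#' Orientation-independent: the absolute value of the signed shoelace sum is
#' scaled by `pixel_size_um^2`.
#'
#' @param roi a polygon `region_of_interest`.
#' @param pixel_size_um pixel size in micrometres.
#' @return area in um^2.
#' @export
polygon_area <- function(roi, pixel_size_um) {
  if (!inherits(roi, "region_of_interest") || roi$kind != "polygon")
    stop_retinaquant("polygon_area requires a polygon ROI", "roi_kind_error")
  v <- roi$vertices
  n <- nrow(v)
  j <- c(2:n, 1)
  a <- abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
  a * pixel_size_um^2
}

#' Polyline curvilinear length in micrometres
#'
#' Sum of Euclidean segment lengths scaled by `pixel_size_um`.
#'
#' @inheritParams polygon_area
#' @param roi a polyline `region_of_interest`.
#' @return length in um.
#' @export
polyline_length <- function(roi, pixel_size_um) {
  if (!inherits(roi, "region_of_interest") || roi$kind != "polyline")
    stop_retinaquant("polyline_length requires a polyline ROI",
                     "roi_kind_error")
  d <- diff(roi$vertices)
  sum(sqrt(rowSums(d^2))) * pixel_size_um
}

#' Even-odd point-in-polygon test
#'
#' A pixel belongs to the polygon iff its center is inside by the even-odd
#' (crossing parity) rule. Counts depend on this convention, so it is fixed
#' and documented rather than configurable.
#'
#' @param points two-column (row, col) matrix of query points.
#' @param roi polygon ROI.
#' @return logical vector.
#' @export
points_in_polygon <- function(points, roi) {
  if (roi$kind != "polygon")
    stop_retinaquant("points_in_polygon requires a polygon ROI",
                     "roi_kind_error")
  pts <- .as_vertex_matrix(points)
  v <- roi$vertices
  n <- nrow(v)
  inside <- logical(nrow(pts))
  px <- pts[, 1]; py <- pts[, 2]
  j <- n
  for (i in seq_len(n)) {
    yi <- v[i, 2]; yj <- v[j, 2]; xi <- v[i, 1]; xj <- v[j, 1]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Distance from points to a polyline, in pixels
#'
#' Minimum Euclidean distance to any segment; used to decide membership in a
#' band around a curvilinear ROI.
#'
#' @param points two-column (row, col) matrix.
#' @param roi polyline ROI.
#' @return numeric vector of distances (px).
#' @export
points_polyline_distance <- function(points, roi) {
  if (roi$kind != "polyline")
    stop_retinaquant("requires a polyline ROI", "roi_kind_error")
  pts <- .as_vertex_matrix(points)
  v <- roi$vertices
  dmin <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(v) - 1)) {
    a <- v[i, ]; b <- v[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, nrow(pts)) else
      pmin(1, pmax(0, ((pts[, 1] - a[1]) * ab[1] +
                       (pts[, 2] - a[2]) * ab[2]) / len2))
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
  }
  dmin
}

#' Read/write ROI files
#'
#' The native interchange is a structured-text file: a header line
#' `retinaquant_roi <kind> <label>` followed by one `row col` pair per line.
#' ImageJ binary `.roi` files (polygon, polyline, freehand/freeline traces)
#' are also read, so ROIs drawn in Fiji can be used directly.
#'
#' @param roi a `region_of_interest`.
#' @param path file path; `read_roi` dispatches on the ImageJ magic bytes.
#' @return `read_roi` returns a `region_of_interest`.
#' @export
write_roi <- function(roi, path) {
  lines <- c(paste("retinaquant_roi", roi$kind, roi$label),
             apply(roi$vertices, 1, function(r)
               paste(format(r[1], digits = 17), format(r[2], digits = 17))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  if (!file.exists(path))
    stop_retinaquant(paste0("ROI file not found: ", path), "roi_kind_error")
  magic <- readBin(path, "raw", 4)
  if (length(magic) == 4 && rawToChar(magic) == "Iout")
    return(.read_imagej_roi(path))
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  if (length(hdr) < 2 || hdr[1] != "retinaquant_roi")
    stop_retinaquant("unrecognized ROI file format", "roi_kind_error")
  kind <- hdr[2]
  label <- if (length(hdr) >= 3) paste(hdr[-(1:2)], collapse = " ") else "roi"
  v <- do.call(rbind, lapply(lines[-1], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  switch(kind,
         polygon = roi_polygon(v, label),
         polyline = roi_polyline(v, label),
         stop_retinaquant(paste0("unknown ROI kind: ", kind), "roi_kind_error"))
}

# Minimal ImageJ .roi reader: big-endian; header gives type and bounds,
# n coordinates follow as int16 offsets from (top, left).
.read_imagej_roi <- function(path) {
  r <- readBin(path, "raw", file.size(path))
  u16 <- function(off) .raw_to_u(r[(off + 1):(off + 2)], 2, "big")
  type <- as.integer(r[7])
  top <- u16(8); left <- u16(10)
  n <- u16(16)
  if (n < 1)
    stop_retinaquant("ImageJ ROI has no vertices", "roi_kind_error")
  xs <- vapply(seq_len(n), function(i) u16(64 + 2 * (i - 1)), 0)
  ys <- vapply(seq_len(n), function(i) u16(64 + 2 * n + 2 * (i - 1)), 0)
  v <- cbind(row = top + ys, col = left + xs)
  # ImageJ types: 0 polygon, 2 polygon, 3 freehand area, 4 traced,
  # 5 polyline, 6 freeline, 7 angle
  if (type %in% c(5, 6, 7)) roi_polyline(v, "imagej")
  else roi_polygon(v, "imagej")
}
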