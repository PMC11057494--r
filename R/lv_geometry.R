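# Scalar geometry extracted from masks and traces: areas, LV length and the
# shape-feature vector feeding the length model. All quantities are in pixel
# units; EF is dimensionless so the calibration cancels downstream.

#' Per-frame LV area curve
#'
#' @param masks logical `(row, col, frame)` array or list of logical matrices.
#' @return An `AreaCurve`: list with `areas` (px^2) and 0-based
#'   `frame_indices`.
#' @export
area_curve <- function(masks) {
  if (is.list(masks)) {
    areas <- vapply(masks, sum, numeric(1))
  } else {
    stop_if(length(dim(masks)) != 3L, "masks must be a (row, col, frame) array")
    areas <- apply(masks, 3, sum)
  }
  new_area_curve(as.numeric(areas))
}

#' Construct an AreaCurve from raw per-frame areas
#'
#' @param areas numeric vector of per-frame areas (px^2, >= 0).
#' @param frame_indices 0-based frame indices (defaults to `0:(n-1)`).
#' @return An `AreaCurve`.
#' @export
new_area_curve <- function(areas, frame_indices = seq_along(areas) - 1L) {
  stop_if(length(areas) != length(frame_indices),
          "areas and frame_indices must have equal length")
  stop_if(any(areas < 0), "areas must be non-negative")
  structure(list(areas = as.numeric(areas),
                 frame_indices = as.integer(frame_indices)),
            class = "AreaCurve")
}

#' LV area of a binary mask
#'
#' The LV area is simply the number of foreground pixels of the segmentation
#' mask.
#'
#' @param mask logical matrix.
#' @return area in px^2.
#' @export
mask_area <- function(mask) sum(mask)

#' Shoelace area of a polygon
#'
#' @param points n x 2 matrix of ordered `(x, y)` vertices, n >= 3.
#' @return absolute polygon area (px^2), orientation-independent.
#' @export
polygon_area <- function(points) {
  points <- as.matrix(points)
  stop_if(nrow(points) < 3, "a polygon needs at least 3 points")
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Rasterise a polygon to a binary mask
#'
#' Even-odd scanline fill with the pixel-centre convention: a pixel is
#' foreground when its centre `(x, y)` (0-based integers) lies inside the
#' polygon.
#'
#' @param points n x 2 `(x, y)` vertex matrix.
#' @param canvas `(rows, cols)`.
#' @return logical `(rows, cols)` matrix.
#' @export
rasterise_polygon <- function(points, canvas) {
  points <- as.matrix(points)
  stop_if(nrow(points) < 3, "a polygon needs at least 3 points")
  H <- canvas[1]; W <- canvas[2]
  m <- matrix(FALSE, H, W)
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  for (row in 0:(H - 1)) {
    crosses <- (y <= row & yn > row) | (yn <= row & y > row)
    if (!any(crosses)) next
    xc <- x[crosses] + (row - y[crosses]) * (xn[crosses] - x[crosses]) /
      (yn[crosses] - y[crosses])
    xc <- sort(xc)
    for (k in seq(1, length(xc) - 1, by = 2)) {
      lo <- ceiling(xc[k]); hi <- ceiling(xc[k + 1]) - 1L
      lo <- max(lo, 0L); hi <- min(hi, W - 1L)
      if (lo <= hi) m[row + 1L, (lo:hi) + 1L] <- TRUE
    }
  }
  m
}

#' LV length between two landmark points
#'
#' The LV length is the Euclidean distance from the mid-annular point to the
#' apex.
#'
#' @param p,q `(x, y)` coordinate pairs.
#' @return distance in px.
#' @export
lv_length <- function(p, q) sqrt(sum((as.numeric(p) - as.numeric(q))^2))

#' Shape features of an LV mask
#'
#' Computes the fixed-length feature vector used by the LV-length model:
#' pixel-count area, the extent (height) along the mask's principal axis
#' (from the second moments of the foreground pixels), and the perpendicular
#' widths at 5 levels placed at 10/30/50/70/90% of the height. When the mask
#' has several connected components the largest is used (with a warning).
#'
#' @param mask logical matrix, non-empty.
#' @param k number of width levels (default 5).
#' @return A `ShapeFeatures` list: `area` (px^2), `height` (px), `widths`
#'   (length-`k` numeric, px).
#' @export
extract_features <- function(mask, k = 5L) {
  stop_if(sum(mask) == 0, "cannot extract features from an empty mask")
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) > 1) {
    warning("mask has multiple connected components; using the largest")
    counts <- tabulate(lab[lab > 0])
    mask <- lab == which.max(counts)
  }
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(x = idx[, 2] - 1, y = idx[, 1] - 1)  # 0-based pixel centres
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  if (nrow(pts) == 1L) {
    v1 <- c(1, 0); v2 <- c(0, 1)
  } else {
    ev <- eigen(stats::cov(d), symmetric = TRUE)
    v1 <- ev$vectors[, 1]; v2 <- ev$vectors[, 2]
  }
  proj <- d %*% v1
  perp <- d %*% v2
  height <- max(proj) - min(proj) + 1
  levels <- min(proj) - 0.5 + c(0.1, 0.3, 0.5, 0.7, 0.9)[seq_len(k)] * height
  if (k != 5L) levels <- min(proj) - 0.5 + (seq_len(k) * 2 - 1) / (2 * k) * height
  widths <- vapply(levels, function(lv) {
    band <- abs(proj - lv) <= 0.5
    if (!any(band)) return(0)
    max(perp[band]) - min(perp[band]) + 1
  }, numeric(1))
  structure(list(area = sum(mask), height = as.numeric(height), widths = widths),
            class = "ShapeFeatures")
}

#' Flatten shape features to a named model row
#'
#' @param features a `ShapeFeatures` object (or list of them).
#' @return named numeric vector (or matrix) with columns
#'   `area, height, w1..wk`.
#' @export
features_row <- function(features) {
  if (inherits(features, "ShapeFeatures")) features <- list(features)
  rows <- t(vapply(features, function(f) c(f$area, f$height, f$widths),
                   numeric(2 + length(features[[1]]$widths))))
  colnames(rows) <- c("area", "height", paste0("w", seq_along(features[[1]]$widths)))
  if (nrow(rows) == 1L) rows[1, ] else rows
}
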