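# Seed morphometrics from flatbed-scanner RGB images: watershed
# segmentation followed by per-seed shape descriptors (area, Crofton
# perimeter, moment-ellipse axes, eccentricity, convex-hull solidity) in
# millimetre units.

#' Segment seeds in a scanner image
#'
#' Converts to grayscale by the standard Rec. 601 luminance, auto-detects
#' polarity from the border median (seeds are assumed darker than the
#' scanner bed; an image whose border is dark is inverted), thresholds
#' globally by Otsu's method, fills holes, removes specks below 0.1 mm^2,
#' labels 8-connected components and splits touching seeds by watershed
#' on the distance transform with h-maxima suppression at 10\% of the
#' maximum distance.
#'
#' @param image RGB array (height x width x 3, values in `[0, 1]`),
#'   grayscale matrix, or path to a PNG file.
#' @param dpi Scanner resolution (dots per inch, default 1200).
#' @param min_area_mm2 Minimum object area retained (default 0.1 mm^2).
#' @param watershed_h H-maxima suppression as a fraction of the maximum
#'   distance-transform value (default 0.1).
#' @return Integer label matrix (0 = background); a blank image yields an
#'   all-zero matrix, not an error.
#' @export
segment_seeds <- function(image, dpi = 1200, min_area_mm2 = 0.1,
                          watershed_h = 0.1) {
  if (is.character(image)) image <- png::readPNG(image)
  if (dpi <= 0) stop("dpi must be positive")
  gray <- if (length(dim(image)) == 3) {
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else {
    image
  }
  if (max(gray) - min(gray) < 1e-6) {
    return(matrix(0L, nrow(gray), ncol(gray)))
  }
  border <- c(gray[1, ], gray[nrow(gray), ], gray[, 1], gray[, ncol(gray)])
  thr <- EBImage::otsu(EBImage::Image(gray), range = range(gray))
  mask <- if (stats::median(border) >= thr) gray < thr else gray > thr
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = watershed_h * max(dm),
                               ext = 1)
  labels <- EBImage::imageData(labels)
  # drop specks below the minimum area
  min_px <- min_area_mm2 / (25.4 / dpi)^2
  keep <- which(tabulate(labels[labels > 0]) >= min_px)
  relab <- integer(max(labels, 1))
  relab[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(labels), ncol(labels))
  pos <- labels > 0
  out[pos] <- relab[labels[pos]]
  out
}

# Crofton 4-direction perimeter estimate: pi/4 times the intercept counts
# (foreground entries along scan lines) in the horizontal, vertical and
# two diagonal directions, diagonal lines weighted by their 1/sqrt(2)
# spacing.
crofton_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  nr <- nrow(m); nc <- ncol(m)
  cur <- m[2:nr, 2:nc]
  n_h <- sum(cur == 1 & m[2:nr, 1:(nc - 1)] == 0)      # left neighbor
  n_v <- sum(cur == 1 & m[1:(nr - 1), 2:nc] == 0)      # up neighbor
  n_d1 <- sum(cur == 1 & m[1:(nr - 1), 1:(nc - 1)] == 0) # up-left
  inner <- m[2:nr, 1:(nc - 1)]
  n_d2 <- sum(inner == 1 & m[1:(nr - 1), 2:nc] == 0)   # up-right
  pi / 4 * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

# Convex hull area over pixel corners (shoelace), guaranteeing
# solidity <= 1 for any region.
hull_area_px <- function(rows, cols) {
  pts <- cbind(
    c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5),
    c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5)
  )
  h <- chull(pts)
  hp <- pts[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3) return(length(rows))
  x <- hp[, 1]; y <- hp[, 2]
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Shape descriptors for one labeled seed
#'
#' Area is the pixel count scaled by `(25.4 / dpi)^2`; axis lengths come
#' from the eigenvalues of the second central moment matrix
#' (equivalent-ellipse convention, full axis `4 sqrt(lambda)`);
#' eccentricity is `sqrt(1 - (minor/major)^2)`; perimeter is the Crofton
#' 4-direction estimate; solidity is area over convex-hull area.  The
#' aspect ratio `minor/major` is also reported.
#'
#' @param labels Integer label matrix from [segment_seeds()].
#' @param label Which label to measure.
#' @param dpi Scanner resolution for the mm conversion.
#' @return One-row data frame: label, area (mm^2), perimeter (mm),
#'   major_axis, minor_axis (mm), eccentricity, aspect_ratio, solidity,
#'   n_pixels, degenerate flag.
#' @export
shape_descriptors <- function(labels, label, dpi = 1200) {
  idx <- which(labels == label, arr.ind = TRUE)
  if (!nrow(idx)) stop("label ", label, " not present in mask")
  px <- 25.4 / dpi
  n <- nrow(idx)
  if (n < 4) {
    return(data.frame(label = label, area = n * px^2, perimeter = NA_real_,
                      major_axis = NA_real_, minor_axis = NA_real_,
                      eccentricity = NA_real_, aspect_ratio = NA_real_,
                      solidity = NA_real_, n_pixels = n, degenerate = TRUE))
  }
  r <- idx[, 1]; cc <- idx[, 2]
  mu_rr <- mean((r - mean(r))^2)
  mu_cc <- mean((cc - mean(cc))^2)
  mu_rc <- mean((r - mean(r)) * (cc - mean(cc)))
  tr2 <- (mu_rr + mu_cc) / 2
  det_rt <- sqrt(max(0, ((mu_rr - mu_cc) / 2)^2 + mu_rc^2))
  l1 <- tr2 + det_rt
  l2 <- max(0, tr2 - det_rt)
  major <- 4 * sqrt(l1) * px
  minor <- 4 * sqrt(l2) * px
  ratio <- if (major > 0) minor / major else NA_real_
  mask <- matrix(0L, max(r) - min(r) + 3, max(cc) - min(cc) + 3)
  mask[cbind(r - min(r) + 2, cc - min(cc) + 2)] <- 1L
  data.frame(
    label = label, area = n * px^2,
    perimeter = crofton_perimeter(mask) * px,
    major_axis = major, minor_axis = minor,
    eccentricity = sqrt(max(0, 1 - ratio^2)),
    aspect_ratio = ratio,
    solidity = n / hull_area_px(r, cc),
    n_pixels = n, degenerate = FALSE
  )
}

#' Per-sample summary of seed shapes
#'
#' Unweighted means over retained (non-degenerate) seeds.
#'
#' @param shapes Data frame of per-seed descriptors
#'   ([shape_descriptors()] rows).
#' @return List with `n_seeds` and `means` (named vector); an empty or
#'   all-degenerate input yields `n_seeds = 0` and `NULL` means.
#' @export
sample_summary <- function(shapes) {
  if (!is.null(shapes$degenerate)) {
    shapes <- shapes[!shapes$degenerate, , drop = FALSE]
  }
  if (is.null(shapes) || !nrow(shapes)) {
    return(list(n_seeds = 0L, means = NULL))
  }
  cols <- c("area", "perimeter", "major_axis", "minor_axis",
            "eccentricity", "aspect_ratio", "solidity")
  list(n_seeds = nrow(shapes),
       means = vapply(cols, function(cl) mean(shapes[[cl]]), numeric(1)))
}

#' Segment and measure all seeds in an image
#'
#' Convenience driver: [segment_seeds()], [shape_descriptors()] per label,
#' [sample_summary()], plus an optional mask overlay written as PNG for
#' visual inspection.
#'
#' @inheritParams segment_seeds
#' @param overlay_path Optional path; when given, a PNG is written with
#'   segmented seeds tinted red on the original image.
#' @return List with `labels`, `shapes` (per-seed data frame) and
#'   `summary`.
#' @export
analyze_seed_image <- function(image, dpi = 1200, min_area_mm2 = 0.1,
                               watershed_h = 0.1, overlay_path = NULL) {
  if (is.character(image)) image <- png::readPNG(image)
  labels <- segment_seeds(image, dpi, min_area_mm2, watershed_h)
  n <- max(labels)
  shapes <- if (n > 0) {
    do.call(rbind, lapply(seq_len(n), function(l)
      shape_descriptors(labels, l, dpi)))
  } else {
    data.frame()
  }
  if (!is.null(overlay_path)) {
    ov <- if (length(dim(image)) == 3) image else
      array(rep(image, 3), dim = c(dim(image), 3))
    hit <- labels > 0
    ov[, , 1][hit] <- pmin(1, ov[, , 1][hit] + 0.4)
    png::writePNG(ov, overlay_path)
  }
  list(labels = labels, shapes = shapes, summary = sample_summary(shapes))
}
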