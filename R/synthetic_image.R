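# Rendering of synthetic flatbed-scanner seed images: dark ellipses on a
# light background with analytic per-seed shape ground truth, emulating an
# RGB scan at a known dots-per-inch resolution.

#' Render a synthetic seed-scan image with analytic ground truth
#'
#' Draws filled dark ellipses (seeds) on a light background (scanner bed)
#' and returns both the RGB image and the analytic shape descriptors of
#' every ellipse: area `pi a b`, perimeter by Ramanujan's approximation,
#' full axes `2a`/`2b`, eccentricity `sqrt(1 - (b/a)^2)` and solidity 1,
#' converted to millimetres at `25.4 / dpi` mm per pixel.
#'
#' @param seed_params Data frame (or list of rows) with columns `cx`, `cy`
#'   (center, pixels), `a`, `b` (semi-axes, pixels, `a >= b`) and `theta`
#'   (orientation, radians).
#' @param image_size `c(height, width)` in pixels.
#' @param background_level Background gray level in `[0, 1]` (seeds are
#'   rendered darker, at `seed_level`).
#' @param seed_level Seed gray level.
#' @param noise_sd Standard deviation of additive pixel noise.
#' @param dpi Scanner resolution used for the mm conversion.
#' @param rng_seed Integer seed for the pixel noise.
#' @return List with `image` (height x width x 3 array in `[0, 1]`) and
#'   `truth` (data frame of per-seed analytic descriptors in mm units).
#' @examples
#' sp <- data.frame(cx = 40, cy = 40, a = 20, b = 10, theta = 0.5)
#' img <- render_seed_image(sp, image_size = c(80, 80))
#' img$truth$eccentricity # sqrt(3)/2
#' @export
render_seed_image <- function(seed_params, image_size = c(400, 600),
                              background_level = 0.85, seed_level = 0.25,
                              noise_sd = 0.01, dpi = 1200, rng_seed = 42L) {
  seed_params <- as.data.frame(seed_params)
  stopifnot(all(c("cx", "cy", "a", "b", "theta") %in% names(seed_params)))
  if (any(seed_params$b > seed_params$a))
    stop("semi-axes must satisfy a >= b")
  h <- image_size[1]; w <- image_size[2]
  # bounding half-extents of each rotated ellipse must fit the canvas
  ex <- sqrt((seed_params$a * cos(seed_params$theta))^2 +
             (seed_params$b * sin(seed_params$theta))^2)
  ey <- sqrt((seed_params$a * sin(seed_params$theta))^2 +
             (seed_params$b * cos(seed_params$theta))^2)
  if (any(seed_params$cx - ex < 1 | seed_params$cx + ex > w |
          seed_params$cy - ey < 1 | seed_params$cy + ey > h))
    stop("ellipse extends outside the canvas")

  xs <- matrix(rep(seq_len(w), each = h), nrow = h)
  ys <- matrix(rep(seq_len(h), times = w), nrow = h)
  mask <- matrix(FALSE, h, w)
  for (i in seq_len(nrow(seed_params))) {
    p <- seed_params[i, ]
    dx <- xs - p$cx; dy <- ys - p$cy
    u <- dx * cos(p$theta) + dy * sin(p$theta)
    v <- -dx * sin(p$theta) + dy * cos(p$theta)
    mask <- mask | ((u / p$a)^2 + (v / p$b)^2 <= 1)
  }
  set.seed(substream_seed(rng_seed, 1L))
  gray <- ifelse(mask, seed_level, background_level)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    img[, , ch] <- pmin(pmax(gray + rnorm(h * w, sd = noise_sd), 0), 1)
  }

  px_mm <- 25.4 / dpi
  truth <- data.frame(
    seed = seq_len(nrow(seed_params)),
    area = pi * seed_params$a * seed_params$b * px_mm^2,
    perimeter = ramanujan_perimeter(seed_params$a, seed_params$b) * px_mm,
    major_axis = 2 * seed_params$a * px_mm,
    minor_axis = 2 * seed_params$b * px_mm,
    eccentricity = sqrt(1 - (seed_params$b / seed_params$a)^2),
    solidity = 1
  )
  list(image = img, truth = truth)
}

#' Randomly place non-overlapping elliptical seeds on a canvas
#'
#' Rejection-samples ellipse centers until the requested number of seeds
#' fit with at least `min_gap` pixels between bounding circles (use a
#' negative gap to force touching pairs).
#'
#' @param n Number of seeds.
#' @param image_size `c(height, width)` in pixels.
#' @param a_range,ecc_range Ranges for the semi-major axis (pixels) and
#'   eccentricity draws.
#' @param min_gap Minimum gap between bounding circles, pixels.
#' @param margin Border margin, pixels.
#' @param rng_seed Integer seed.
#' @return Data frame suitable for [render_seed_image()].
#' @export
random_seed_layout <- function(n, image_size = c(400, 600),
                               a_range = c(30, 45),
                               ecc_range = c(0.3, 0.7),
                               min_gap = 8, margin = 10, rng_seed = 42L) {
  set.seed(substream_seed(rng_seed, 2L))
  h <- image_size[1]; w <- image_size[2]
  out <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                    b = numeric(0), theta = numeric(0))
  tries <- 0
  while (nrow(out) < n) {
    if ((tries <- tries + 1) > 20000)
      stop("could not place ", n, " seeds on a ", h, "x", w, " canvas")
    a <- runif(1, a_range[1], a_range[2])
    ecc <- runif(1, ecc_range[1], ecc_range[2])
    b <- a * sqrt(1 - ecc^2)
    cx <- runif(1, margin + a + 1, w - margin - a)
    cy <- runif(1, margin + a + 1, h - margin - a)
    if (nrow(out) == 0 ||
        all(sqrt((out$cx - cx)^2 + (out$cy - cy)^2) >
            out$a + a + min_gap)) {
      out <- rbind(out, data.frame(cx = cx, cy = cy, a = a, b = b,
                                   theta = runif(1, 0, pi)))
    }
  }
  out
}
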