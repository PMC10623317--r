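render1 <- function(a, b, theta = 0, size = 200, dpi = 1200,
                    noise = 0.01, seed = 5) {
  render_seed_image(data.frame(cx = size / 2, cy = size / 2, a = a,
                               b = b, theta = theta),
                    image_size = c(size, size), dpi = dpi,
                    noise_sd = noise, rng_seed = seed)
}

test_that("a rendered circle measures as a circle: eccentricity near 0,
          area within 2%, high solidity", {
  r <- render1(50, 50, size = 160)
  out <- analyze_seed_image(r$image)
  expect_equal(out$summary$n_seeds, 1)
  s <- out$shapes
  expect_lte(s$eccentricity, 0.02)
  expect_lt(abs(s$area - r$truth$area) / r$truth$area, 0.02)
  expect_lt(abs(s$perimeter - r$truth$perimeter) / r$truth$perimeter,
            0.03)
  expect_gte(s$solidity, 0.98)
  expect_lte(s$solidity, 1)
})

test_that("a 2:1 ellipse measures eccentricity 0.866 within 0.02 at any
          orientation", {
  for (th in c(0, 0.64, 2.1)) {
    out <- analyze_seed_image(render1(60, 30, theta = th)$image)
    expect_lt(abs(out$shapes$eccentricity - sqrt(3) / 2), 0.02)
    expect_lt(abs(out$shapes$aspect_ratio - 0.5), 0.02)
  }
})

test_that("counts are exact on disjoint seeds and touching pairs are
          split by the watershed", {
  lay <- random_seed_layout(12, c(420, 620), rng_seed = 9)
  r <- render_seed_image(lay, image_size = c(420, 620), rng_seed = 9)
  out <- analyze_seed_image(r$image)
  expect_equal(out$summary$n_seeds, 12)

  # touching pair: centers 1.8 semi-axes apart
  rt <- render_seed_image(
    data.frame(cx = c(100, 172), cy = 100, a = 40, b = 40, theta = 0),
    image_size = c(200, 300))
  expect_equal(analyze_seed_image(rt$image)$summary$n_seeds, 2)
})

test_that("blank and empty images give zero labels, not errors", {
  blank <- array(1, dim = c(50, 50, 3))
  expect_equal(max(segment_seeds(blank)), 0)
  out <- analyze_seed_image(blank)
  expect_equal(out$summary$n_seeds, 0)
  expect_null(out$summary$means)
})

test_that("rotation changes area and eccentricity by less than 2%", {
  base <- analyze_seed_image(render1(55, 33, theta = 0)$image)$shapes
  rot <- analyze_seed_image(
    render1(55, 33, theta = 37 * pi / 180)$image)$shapes
  expect_lt(abs(rot$area - base$area) / base$area, 0.02)
  expect_lt(abs(rot$eccentricity - base$eccentricity), 0.02)
})

test_that("mm outputs are dpi-equivariant: the same physical seed at
          600 and 1200 dpi agrees within 1%", {
  # 1.2 mm semi-major, 0.7 mm semi-minor
  out <- lapply(c(600, 1200), function(dpi) {
    a_px <- 1.2 * dpi / 25.4
    b_px <- 0.7 * dpi / 25.4
    analyze_seed_image(render1(a_px, b_px, theta = 0.4, size = 200,
                               dpi = dpi)$image, dpi = dpi)$shapes
  })
  for (f in c("area", "perimeter", "major_axis", "minor_axis")) {
    expect_lt(abs(out[[1]][[f]] - out[[2]][[f]]) / out[[2]][[f]], 0.01)
  }
})

test_that("sample summary averages retained seeds and matches renderer
          ground truth on a 50-seed scatter", {
  two <- data.frame(area = c(2, 3), perimeter = c(5, 6),
                    major_axis = c(2, 2), minor_axis = c(1, 1),
                    eccentricity = c(0.5, 0.7),
                    aspect_ratio = c(0.87, 0.71),
                    solidity = c(1, 1), degenerate = FALSE)
  s <- sample_summary(two)
  expect_equal(s$n_seeds, 2)
  expect_equal(unname(s$means["area"]), 2.5)
  one <- sample_summary(two[1, ])
  expect_equal(unname(one$means["eccentricity"]), 0.5)

  lay <- random_seed_layout(50, c(800, 1200), a_range = c(22, 30),
                            ecc_range = c(0.3, 0.7), rng_seed = 10)
  r <- render_seed_image(lay, image_size = c(800, 1200), rng_seed = 10)
  out <- analyze_seed_image(r$image)
  expect_equal(out$summary$n_seeds, 50)
  expect_lt(abs(out$summary$means["eccentricity"] -
                  mean(r$truth$eccentricity)), 0.02)
  expect_lt(abs(out$summary$means["area"] - mean(r$truth$area)) /
              mean(r$truth$area), 0.02)
})

test_that("the mask overlay is written for inspection", {
  r <- render1(30, 20, size = 100)
  path <- tempfile(fileext = ".png")
  analyze_seed_image(r$image, overlay_path = path)
  expect_true(file.exists(path))
  ov <- png::readPNG(path)
  expect_equal(dim(ov), c(100, 100, 3))
})
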