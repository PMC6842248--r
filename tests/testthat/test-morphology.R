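# Structure labelling, Euclidean descriptors, classification and MN.

test_that("labelling finds 8-connected components", {
  img <- matrix(0L, 12, 12)
  img[2:4, 2:4] <- 255L
  img[8:10, 8:10] <- 255L
  expect_length(label_structures(img, 1), 2L)
  # diagonal corner contact joins components under 8-connectivity
  img2 <- matrix(0L, 8, 8)
  img2[2:3, 2:3] <- 255L
  img2[4:5, 4:5] <- 255L
  expect_length(label_structures(img2, 1), 1L)
  expect_length(label_structures(matrix(0L, 5, 5), 1), 0L)
})

test_that("labelling enforces binary images and a positive calibration", {
  img <- matrix(0L, 4, 4); img[2, 2] <- 128L; img[3, 3] <- 255L
  expect_error(label_structures(img, 1), "binary")
  expect_error(label_structures(matrix(0L, 4, 4), 0), "positive")
  # 0/1 images are accepted alongside 0/255
  expect_length(label_structures(matrix(c(0L, 1L, 0L, 1L), 2, 2), 1), 1L)
})

test_that("descriptors of a filled square match hand geometry", {
  img <- image_from_pixels(as.matrix(expand.grid(3:12, 3:12)), 16, 16)
  d <- shape_descriptors(label_structures(img, 1)[[1]])
  expect_equal(d$area_um2, 100)
  expect_equal(d$feret_max_um, sqrt(200), tolerance = 1e-12)
  expect_equal(d$feret_min_um, 10, tolerance = 1e-12)
  expect_equal(d$aspect_ratio, sqrt(2), tolerance = 1e-12)
  expect_equal(d$solidity, 1.0)
})

test_that("a 1-pixel-wide line keeps a nonzero minimum Feret", {
  img <- image_from_pixels(cbind(5L, 3:12), 10, 16)
  d <- shape_descriptors(label_structures(img, 1)[[1]])
  expect_equal(d$feret_max_um, sqrt(101), tolerance = 1e-12)
  expect_equal(d$feret_min_um, 1)
  expect_equal(d$solidity, 1.0)
  expect_equal(d$area_um2, 10)
})

test_that("a rasterized disc is nearly isotropic with near-unit solidity", {
  sp <- image_spec(140, 140, 1, pellets = list(pellet_spec(c(70, 70), 100)))
  d <- measure_structures(render_culture_image(sp)$image, 1)
  expect_equal(d$feret_max_um, 100, tolerance = 0.02)
  expect_equal(d$feret_min_um, 100, tolerance = 0.02)
  expect_gte(d$solidity, 0.98)
})

test_that("Feret extremes agree with the 3600-angle projection oracle", {
  shapes <- list(
    square = as.matrix(expand.grid(3:12, 3:12)),
    line = cbind(5L, 3:12),
    ell = as.matrix(expand.grid(2:4, 2:9))[-(1:3), ])
  set.seed(55)
  for (i in 1:5) {  # random blobs around a centre
    pts <- unique(cbind(round(rnorm(200, 20, 4)), round(rnorm(200, 20, 7))))
    shapes[[paste0("blob", i)]] <- pts[pts[, 1] > 0 & pts[, 2] > 0, ]
  }
  for (pix in shapes) {
    img <- image_from_pixels(pix, max(pix[, 1]) + 2, max(pix[, 2]) + 2)
    masks <- label_structures(img, 1)
    for (mask in masks) {
      d <- shape_descriptors(mask)
      oracle <- feret_oracle(corner_points(mask$pixels))
      expect_equal(d$feret_max_um, oracle$feret_max, tolerance = 0.01)
      expect_equal(d$feret_min_um, oracle$feret_min, tolerance = 0.01)
    }
  }
})

test_that("area classification uses the 95 and 500 um^2 boundaries inclusively", {
  expect_equal(classify_structure(500.0), "pellet")
  expect_equal(classify_structure(95.0), "dispersed")
  expect_equal(classify_structure(94.9), "excluded")
  expect_equal(classify_structure(10000), "pellet")
  expect_equal(classify_structure(499.999), "dispersed")
  expect_error(classify_structure(0), "positive")
})

test_that("Morphology Number reproduces closed-form shapes", {
  r <- 50
  expect_equal(morphology_number(pi * r^2, 1, 2 * r, 1), 1.0,
               tolerance = 1e-12)
  s <- 7
  expect_equal(morphology_number(s^2, 1, s * sqrt(2), sqrt(2)),
               1 / sqrt(pi), tolerance = 1e-12)
  expect_equal(morphology_number(100, 1, 20, 2), 20 / (sqrt(pi) * 40),
               tolerance = 1e-12)
  expect_error(morphology_number(-1, 1, 1, 1), "positive")
  expect_error(morphology_number(1, 1.2, 1, 1), "solidity")
  expect_error(morphology_number(1, 1, 1, 0.5), "aspect")
})

test_that("MN is monotone in solidity and aspect ratio", {
  sol <- seq(0.2, 1, by = 0.1)
  expect_true(all(diff(morphology_number(100, sol, 20, 2)) > 0))
  ar <- seq(1, 5, by = 0.5)
  expect_true(all(diff(morphology_number(100, 0.9, 20, ar)) < 0))
})

test_that("MN of a rendered ellipse is rotation-robust", {
  mns <- vapply(seq(0, 90, by = 15), function(ang) {
    sp <- image_spec(300, 300, 0.5,
                     pellets = list(pellet_spec(c(75, 75), 100, 60,
                                                orientation_deg = ang)))
    measure_structures(render_culture_image(sp)$image, 0.5)$morphology_number
  }, numeric(1))
  expect_lt((max(mns) - min(mns)) / mean(mns), 0.03)
})

test_that("descriptors scale consistently with the pixel size", {
  sp <- image_spec(200, 200, 1,
                   pellets = list(pellet_spec(c(100, 100), 90, 50,
                                              orientation_deg = 30)))
  img <- render_culture_image(sp)$image
  d1 <- shape_descriptors(label_structures(img, 1)[[1]])
  d2 <- shape_descriptors(label_structures(img, 2)[[1]])
  expect_equal(d2$area_um2, 4 * d1$area_um2)
  expect_equal(d2$feret_max_um, 2 * d1$feret_max_um)
  expect_equal(d2$feret_min_um, 2 * d1$feret_min_um)
  expect_equal(d2$solidity, d1$solidity)
  expect_equal(d2$aspect_ratio, d1$aspect_ratio)
  expect_equal(morphology_number(d2$area_um2, d2$solidity, d2$feret_max_um,
                                 d2$aspect_ratio),
               morphology_number(d1$area_um2, d1$solidity, d1$feret_max_um,
                                 d1$aspect_ratio), tolerance = 1e-12)
})

test_that("culture summaries follow the measured-area convention", {
  metrics <- data.frame(
    object_id = 1:3,
    area_um2 = c(1500, 300, 50),
    size_class = c("pellet", "dispersed", "excluded"),
    morphology_number = c(0.9, 0.5, NA))
  s <- summarize_culture(metrics)
  expect_equal(s$n_pellets, 1L)
  expect_equal(s$n_dispersed, 1L)
  expect_equal(s$n_excluded, 1L)
  expect_equal(s$pellet_area_fraction_pct, 100 * 1500 / 1800,
               tolerance = 1e-12)
  expect_equal(s$mn_values, 0.9)  # pellets only
  only_pellets <- metrics[1, ]
  expect_equal(summarize_culture(only_pellets)$pellet_area_fraction_pct, 100)
  empty <- summarize_culture(metrics[0, ])
  expect_true(is.na(empty$pellet_area_fraction_pct))
  expect_equal(empty$n_pellets + empty$n_dispersed + empty$n_excluded, 0L)
})

test_that("classification of rendered objects matches the generator's truth table", {
  sp <- image_spec(600, 600, 1,
                   pellets = list(pellet_spec(c(150, 150), 80),
                                  pellet_spec(c(420, 420), 40, 30)),
                   fragments = list(fragment_spec(c(150, 450), 120),
                                    fragment_spec(c(450, 150), 480, "line"),
                                    fragment_spec(c(300, 50), 60)))
  out <- render_culture_image(sp)
  measured <- measure_structures(out$image, 1)
  expect_equal(nrow(measured), nrow(out$truth))
  # match structures to truth by nearest area
  idx <- vapply(out$truth$true_area_um2,
                function(a) which.min(abs(measured$area_um2 - a)), integer(1))
  expect_equal(measured$size_class[idx], out$truth$size_class)
})
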