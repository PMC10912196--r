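test_that("CLAHE preserves flat tiles, range and segmentation hue", {
  flat <- array(0.5, dim = c(32, 32, 3))
  expect_equal(equalize_contrast(flat), flat, tolerance = 1 / 255)

  tile <- render_plot_tile(0.4, 0.4, image_size = 64, seed = 1)
  eq <- equalize_contrast(tile$rgb)
  expect_equal(dim(eq), dim(tile$rgb))
  expect_true(min(eq) >= 0 && max(eq) <= 1)
  # hue preserved: the mask is unchanged by equalization
  expect_equal(mask_canopy(eq), mask_canopy(tile$rgb))
  expect_error(equalize_contrast(tile$rgb * 300), "8-bit")
})

test_that("CLAHE increases local contrast on a two-band tile", {
  # two vertical halves of low-contrast texture around 40 and 200 / 255
  set.seed(42)
  v <- cbind(matrix(40 + sample(-5:5, 32 * 16, TRUE), 32, 16),
             matrix(200 + sample(-5:5, 32 * 16, TRUE), 32, 16)) / 255
  rgb <- array(rep(v, 3), dim = c(32, 32, 3))
  eq <- equalize_contrast(rgb)
  spread <- function(m) diff(range(m))
  left <- 1:16; right <- 17:32
  expect_gt(spread(eq[, left, 1]), spread(rgb[, left, 1]) - 1e-9)
  expect_gt(spread(eq[, right, 1]), spread(rgb[, right, 1]) - 1e-9)
  # dark half stays darker than bright half
  expect_lt(mean(eq[, left, 1]), mean(eq[, right, 1]))
})

test_that("HSV mask follows the componentwise bounds", {
  inside <- tile_from_hsv(90, 128, 128)
  expect_true(all(mask_canopy(inside) == 255))
  below_hue <- tile_from_hsv(10, 200, 200)
  expect_true(all(mask_canopy(below_hue) == 0))
  soil <- tile_from_hsv(12, 150, 120)
  expect_true(all(mask_canopy(soil) == 0))
})

test_that("masking is idempotent and monotone in the hue lower bound", {
  tile <- render_plot_tile(0.35, 0.3, image_size = 48, seed = 9)
  mask <- mask_canopy(tile$rgb)
  # zero out soil pixels as the segmentation step does, re-mask
  seg <- tile$rgb
  for (ch in 1:3) {
    plane <- seg[, , ch]; plane[mask == 0] <- 0; seg[, , ch] <- plane
  }
  expect_equal(mask_canopy(seg), mask)
  # raising the lower hue bound can only shrink the canopy set
  sizes <- sapply(c(20, 50, 64, 70), function(h)
    sum(mask_canopy(tile$rgb, seg_config(hsv_lower = c(h, 0, 0))) == 255))
  expect_true(all(diff(sizes) <= 0))
})

test_that("canopy cover is the masked fraction of the measurement area", {
  m <- matrix(0L, 100, 100)
  m[seq_len(2000)] <- 255L
  expect_equal(canopy_cover(m), 0.2)
  expect_equal(canopy_cover(matrix(255L, 10, 10)), 1)
  expect_error(canopy_cover(m, aom_pixel_count = 0), "empty")
  tile <- render_plot_tile(0.37, 0.3, image_size = 100, seed = 4)
  expect_equal(canopy_cover(mask_canopy(tile$rgb)), 0.37,
               tolerance = 1 / 10000)
})

test_that("canopy height normalizes to the soil baseline", {
  dem <- matrix(0.10, 20, 20)
  mask <- matrix(0L, 20, 20)
  mask[1:10, ] <- 255L
  dem[mask == 255] <- 0.55
  ch <- canopy_height(dem, mask)
  expect_equal(ch$CH, 0.45)
  expect_equal(ch$CH90, 0.45)

  empty <- canopy_height(dem, matrix(0L, 20, 20))
  expect_equal(empty$CH, 0)
  expect_equal(empty$CH90, 0)
  expect_equal(empty$deciles, rep(0, 10))
  expect_error(canopy_height(dem, matrix(0L, 5, 5)), "shape")

  # ten known heights: mean 0.55, percentiles by linear interpolation
  dem2 <- matrix(0, 2, 5)
  dem2[] <- seq(0.1, 1.0, by = 0.1)
  full <- matrix(255L, 2, 5)
  ch2 <- canopy_height(dem2, full)
  # no soil: ground reference is the 5th percentile of the tile
  ground <- quantile(dem2, 0.05, names = FALSE)
  h <- pmax(as.vector(dem2) - ground, 0)
  expect_equal(ch2$CH, mean(h))
  expect_equal(ch2$CH90, quantile(h, 0.9, names = FALSE, type = 7))
})

test_that("height and cover are invariant to pixel permutation", {
  tile <- render_plot_tile(0.3, 0.5, image_size = 30, seed = 11)
  mask <- mask_canopy(tile$rgb)
  perm <- latentyield:::with_seed(1, sample(length(mask)))
  pmask <- matrix(mask[perm], nrow(mask))
  pdem <- matrix(tile$dem[perm], nrow(mask))
  expect_equal(canopy_cover(pmask), canopy_cover(mask))
  expect_equal(canopy_height(pdem, pmask)$CH,
               canopy_height(tile$dem, mask)$CH)
  prgb <- tile$rgb
  for (ch in 1:3) prgb[, , ch] <- matrix(tile$rgb[, , ch][perm], nrow(mask))
  expect_equal(excess_green(prgb, pmask), excess_green(tile$rgb, mask))
})

test_that("excess green matches the per-pixel chromatic formula", {
  gray <- array(0.5, dim = c(4, 4, 3))
  allmask <- matrix(255L, 4, 4)
  expect_equal(excess_green(gray, allmask), 0)
  green <- array(0, dim = c(2, 2, 3)); green[, , 2] <- 1
  expect_equal(excess_green(green, matrix(255L, 2, 2)), 2)
  expect_true(is.na(excess_green(gray, matrix(0L, 4, 4))))

  mixed <- latentyield:::with_seed(5, array(runif(3 * 25), dim = c(5, 5, 3)))
  mask <- matrix(c(rep(255L, 15), rep(0L, 10)), 5, 5)
  # brute-force pixel loop oracle
  vals <- c()
  for (i in 1:5) for (j in 1:5) if (mask[i, j] == 255) {
    px <- mixed[i, j, ]; tot <- sum(px)
    vals <- c(vals, 2 * px[2] / tot - px[1] / tot - px[3] / tot)
  }
  expect_equal(excess_green(mixed, mask), mean(vals), tolerance = 1e-12)
})

test_that("ExG normalization is a monotone map onto [0, 1]", {
  expect_equal(normalize_exg(c(-0.1, 0.4, 0.9)), c(0, 0.5, 1))
  x <- c(0, 0.3, 0.7, 1)
  expect_equal(normalize_exg(x), x)
  y <- latentyield:::with_seed(2, rnorm(50))
  expect_equal(order(normalize_exg(y)), order(y))
  expect_warning(out <- normalize_exg(rep(0.4, 5)), "equal")
  expect_equal(out, rep(0.5, 5))
})

test_that("trait extraction round-trips rendered fixtures", {
  td <- withr::local_tempdir()
  targets <- data.frame(cc = c(0.15, 0.45, 0.80), h = c(0.10, 0.30, 0.50))
  man <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
    tile <- render_plot_tile(targets$cc[i], targets$h[i], image_size = 80,
                             seed = i)
    rp <- file.path(td, sprintf("p%d.png", i))
    dp <- file.path(td, sprintf("p%d.tif", i))
    write_tile_pair(tile, rp, dp)
    data.frame(plot_id = sprintf("p%d", i), genotype = "G1", year = "2021",
               dap = 30 * i, rgb_path = rp, dem_path = dp)
  }))
  # the single canopy hue makes every raw ExG equal: normalization warns
  tt <- suppressWarnings(extract_trait_table(man))
  expect_equal(nrow(tt), 3)
  expect_equal(tt$CC, targets$cc, tolerance = 1 / 6400 + 1e-9)
  expect_equal(tt$CH, targets$h, tolerance = 1e-6)
  expect_equal(tt$CV, tt$CC * tt$CH, tolerance = 1e-12)
  expect_equal(tt$CV90, tt$CC * tt$CH90, tolerance = 1e-12)
  expect_false(any(tt$missing))

  # missing file flagged, not fatal
  man2 <- man
  man2$rgb_path[2] <- file.path(td, "absent.png")
  w <- capture_warnings(tt2 <- extract_trait_table(man2))
  expect_true(any(grepl("missing tile", w)))
  expect_equal(tt2$missing, c(FALSE, TRUE, FALSE))
  expect_true(is.na(tt2$CC[2]))
})
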