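make_mask <- function(m) {
  structure(m, class = "pressure_mask")
}

test_that("otsu threshold separates bimodal histograms and matches brute force", {
  h <- rep(0L, 256)
  h[1] <- 50L; h[256] <- 50L       # intensities 0 and 255
  t1 <- otsu_threshold(h)
  expect_gt(t1, 0)
  expect_lte(t1, 255)
  expect_true(all(0 < t1))        # marked iff intensity >= t: separates modes
  h2 <- rep(0L, 256)
  h2[11] <- 50L; h2[13] <- 50L    # intensities 10 and 12
  t2 <- otsu_threshold(h2)
  expect_gt(t2, 10)
  expect_lte(t2, 12)

  for (seed in 1:20) {
    h3 <- withr::with_seed(seed, tabulate(sample(0:255, 200, replace = TRUE) + 1L,
                                          nbins = 256))
    expect_identical(otsu_threshold(h3), oracle_otsu(h3))
  }
  expect_error(otsu_threshold(rep(c(10L, 0L), c(1, 255))), "degenerate")
})

test_that("redness mask applies the threshold-and-dominance rule", {
  px <- array(0L, dim = c(1, 3, 3))
  px[1, 1, ] <- c(220, 40, 40)    # marked: 220 >= 100, dominance 180 >= 30
  px[1, 2, ] <- c(100, 100, 100)  # unmarked: dominance 0
  px[1, 3, ] <- c(90, 10, 10)     # unmarked: below threshold
  params <- segmentation_params("fixed", fixed_threshold = 100)
  m <- redness_mask(pressure_image(px), params)
  expect_identical(as.vector(m), c(TRUE, FALSE, FALSE))

  flat <- pressure_image(array(rep(c(50L, 0L, 0L), each = 4), dim = c(2, 2, 3)))
  expect_error(redness_mask(flat, segmentation_params("otsu")), "degenerate")
})

test_that("redness mask on synthetic images recovers the ground-truth pixels", {
  for (seed in 1:5) {
    gen <- generate_pressure_image(synthetic_foot_spec(0.6 + 0.3 * seed, seed = seed))
    m <- redness_mask(gen$image)
    expect_identical(matrix(as.logical(m), nrow(m)), gen$truth$mask)
  }
})

test_that("area opening removes exactly the small components and is idempotent", {
  m <- matrix(FALSE, 20, 20)
  m[2:3, 2:3] <- TRUE             # area 4
  m[8:14, 8:14] <- TRUE           # area 49
  out <- area_opening(make_mask(m), min_blob_area = 10, connectivity = 8)
  expect_identical(sum(out), 49L)
  expect_true(all(out[8:14, 8:14]))
  expect_identical(unclass(area_opening(make_mask(m), 1, 8)), m)
  twice <- area_opening(area_opening(make_mask(m), 10, 8), 10, 8)
  expect_identical(unclass(twice), unclass(out))
})

test_that("close_and_fill fills holes, is extensive, and is idempotent", {
  sq <- matrix(FALSE, 12, 12)
  sq[2:11, 2:11] <- TRUE
  sq[6, 6] <- FALSE
  out <- close_and_fill(make_mask(sq), closing_radius = 0, connectivity = 8)
  expect_true(out[6, 6])
  expect_identical(sum(out), 100L)

  solid <- matrix(FALSE, 10, 10)
  solid[3:8, 3:8] <- TRUE
  expect_identical(unclass(close_and_fill(make_mask(solid), 0, 8)), solid)

  for (seed in 1:10) {
    m <- random_mask(seed, 32, 32)
    once <- close_and_fill(make_mask(m), 2, 8)
    expect_true(all(once[m]))  # never removes a marked pixel
    again <- close_and_fill(make_mask(unclass(once)), 2, 8)
    expect_identical(unclass(again), unclass(once))
  }
})

test_that("filling an annulus marks exactly the in-radius disk interior", {
  H <- 41; W <- 41; cr <- 21; cc <- 21
  d2 <- (row(matrix(0, H, W)) - cr)^2 + (col(matrix(0, H, W)) - cc)^2
  ring <- d2 <= 15^2 & d2 >= 12^2
  filled <- close_and_fill(make_mask(ring), closing_radius = 0, connectivity = 8)
  # brute-force interior enumeration: every pixel within the outer radius
  expect_identical(unclass(filled), d2 <= 15^2)
  expect_identical(sum(filled), sum(d2 <= 15^2))
})

test_that("blob statistics are exact on a hand-built image", {
  px <- array(0L, dim = c(6, 6, 3))
  px[2:3, 2:3, 1] <- 200L; px[2:3, 2:3, 2] <- 10L; px[2:3, 2:3, 3] <- 10L
  m <- matrix(FALSE, 6, 6); m[2:3, 2:3] <- TRUE
  blobs <- find_blobs(make_mask(m), pressure_image(px), connectivity = 8)
  expect_equal(nrow(blobs), 1)
  expect_equal(blobs$area_px, 4)
  expect_equal(blobs$mean_r, 200)
  expect_equal(blobs$mean_g, 10)
  expect_equal(blobs$total_red_intensity, 800)
  expect_equal(blobs$centroid_row, 2.5)
  expect_equal(c(blobs$row_min, blobs$col_min, blobs$row_max, blobs$col_max),
               c(2, 2, 3, 3))
})

test_that("diagonal contact joins blobs under 8- but not 4-connectivity", {
  m <- matrix(FALSE, 4, 4)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE
  img <- pressure_image(array(100L, dim = c(4, 4, 3)))
  expect_equal(nrow(find_blobs(make_mask(m), img, connectivity = 8)), 1)
  expect_equal(nrow(find_blobs(make_mask(m), img, connectivity = 4)), 2)
  expect_equal(nrow(find_blobs(make_mask(matrix(FALSE, 4, 4)), img, 8)), 0)
})

test_that("component labeling matches the flood-fill oracle on random masks", {
  for (seed in 1:25) {
    m <- random_mask(seed)
    for (conn in c(4L, 8L)) {
      expect_identical(label_components(m, conn), oracle_label(m, conn))
    }
  }
})

test_that("area opening and hole filling match their oracles on random masks", {
  for (seed in 26:45) {
    m <- random_mask(seed)
    min_area <- withr::with_seed(seed * 1000L, sample(2:30, 1))
    expect_identical(unclass(area_opening(make_mask(m), min_area, 8)),
                     oracle_area_open(m, min_area, 8))
    expect_identical(unclass(close_and_fill(make_mask(m), 0, 8)),
                     oracle_fill_holes(m, 8))
  }
})

test_that("pipeline is monotone and blob areas sum to the mask area", {
  for (seed in 46:55) {
    gen <- generate_pressure_image(
      synthetic_foot_spec(withr::with_seed(seed, runif(1, 0.4, 2.2)),
                          seed = seed, noise_sd = 4))
    raw <- redness_mask(gen$image)
    opened <- area_opening(raw)
    expect_true(all(raw[opened]))          # opening never adds
    final <- close_and_fill(opened)
    expect_true(all(final[opened]))        # closing/filling never removes
    blobs <- find_blobs(final, gen$image)
    expect_identical(sum(blobs$area_px), sum(final))
    expect_equal(sum(blobs$total_red_intensity),
                 region_pressure(matrix(as.logical(final), nrow(final)), gen$image))
  }
})
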