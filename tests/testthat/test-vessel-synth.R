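test_that("adaptive thresholding recovers a bright band and rejects flat images", {
  # constant image: no local contrast anywhere -> all background
  flat <- binarize_vessel_image(matrix(0.7, 40, 40), window_size = 9L)
  expect_true(all(flat$mask == 0L))

  # one bright 10-px horizontal band on a dark background
  img <- matrix(0.05, 80, 80)
  band <- 36:45
  img[band, ] <- 1
  got <- binarize_vessel_image(img, window_size = 21L)
  truth <- matrix(0L, 80, 80); truth[band, ] <- 1L
  jaccard <- sum(got$mask & truth) / sum(got$mask | truth)
  expect_gte(jaccard, 0.9)

  # inverting the image and the polarity yields the identical mask
  inv <- binarize_vessel_image(max(img) - img, window_size = 21L,
                               polarity = "dark")
  expect_identical(inv$mask, got$mask)

  expect_error(binarize_vessel_image(matrix(1, 5, 5), window_size = 4L),
               "odd")
  expect_error(binarize_vessel_image(matrix(numeric(0), 0, 0)), "empty")
})

test_that("binarization is idempotent and strictly binary", {
  img <- matrix(0.05, 60, 60); img[20:30, ] <- 1
  m1 <- binarize_vessel_image(img, window_size = 15L)
  m2 <- binarize_vessel_image(m1$mask + 0, window_size = 15L)
  expect_true(all(m1$mask %in% c(0L, 1L)))
  expect_identical(m2$mask, m1$mask)
})

test_that("procedural vessel maps are deterministic and tunable", {
  g <- grid64()
  a <- generate_vessel_map(42, g)
  b <- generate_vessel_map(42, g)
  expect_identical(a$mask, b$mask)
  expect_gt(vessel_fraction(a), 0)
  c <- generate_vessel_map(43, g)
  expect_false(identical(a$mask, c$mask))
  expect_error(generate_vessel_map(1, g, n_trunks = 0L), "n_trunks")
  empty <- generate_vessel_map(1, g, n_trunks = 0L, allow_empty = TRUE)
  expect_identical(sum(empty$mask), 0L)
})

test_that("two-tube phantom has two components at the requested separation", {
  g <- grid64()
  for (sep in c(2L, 6L, 10L)) {
    ph <- two_tube_phantom(g, 5L, sep)
    rows <- which(rowSums(ph$mask) > 0)
    runs <- rle(seq_len(g$n_rows) %in% rows)
    expect_identical(sum(runs$values), 2L)          # two row bands
    expect_identical(runs$lengths[runs$values], c(5L, 5L))
    gap <- diff(range(rows)) - 9L                   # distance minus widths
    expect_identical(gap, sep)
  }
  vert <- two_tube_phantom(g, 5L, 6L, orientation = "vertical")
  expect_identical(t(vert$mask), two_tube_phantom(g, 5L, 6L)$mask)
})

test_that("roi sampling crops deterministically and covers the mask", {
  g <- acoustic_grid(100L, 100L)
  m <- generate_vessel_map(3, g)
  full <- sample_roi(m, 100L, seed = 1)
  expect_identical(full$mask, m$mask)
  a <- sample_roi(m, 32L, seed = 5)
  b <- sample_roi(m, 32L, seed = 5)
  expect_identical(a$mask, b$mask)
  expect_identical(dim(a$mask), c(32L, 32L))
  expect_error(sample_roi(m, 200L), "larger")
  corners <- vapply(1:50, function(s) {
    sum(sample_roi(m, 32L, seed = s)$mask)
  }, numeric(1))
  expect_gt(length(unique(corners)), 1L)
})

test_that("masks round-trip through image files", {
  skip_if_not_installed("png")
  g <- grid64()
  m <- two_tube_phantom(g, 5L, 10L)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask(m, path)
  back <- read_mask(path)
  expect_identical(back$mask, m$mask)
})
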