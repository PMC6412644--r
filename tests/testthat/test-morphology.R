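test_that("reconstruction by dilation matches the fixed-point oracle", {
  set.seed(101)
  for (rep in 1:40) {
    nr <- sample(4:8, 1); nc <- sample(4:8, 1)
    levels <- sample(c(2, 4), 1) # binary and 4-level grayscale
    mask <- random_test_raster(nr, nc, levels)
    marker <- pmin(random_test_raster(nr, nc, levels), mask)
    for (conn in c(4, 8)) {
      expect_equal(reconstruct_dilate(marker, mask, conn),
                   oracle_reconstruct_dilate(marker, mask, conn))
    }
  }
})

test_that("reconstruction by erosion is the exact dual", {
  set.seed(102)
  for (rep in 1:20) {
    mask <- random_test_raster(6, 6, 4)
    marker <- pmax(random_test_raster(6, 6, 4), mask)
    expect_equal(reconstruct_erode(marker, mask),
                 oracle_reconstruct_erode(marker, mask))
  }
})

test_that("opening by reconstruction restores shapes and kills speckles", {
  b <- se_disk(2)
  # blob larger than the element is restored exactly
  g <- matrix(0, 16, 16)
  g[4:12, 4:12] <- 0.8
  expect_equal(open_reconstruction(g, g, b), g)
  # isolated speckle smaller than the element disappears
  g2 <- g
  g2[15, 15] <- 1
  out <- open_reconstruction(g2, g2, b)
  expect_equal(out[15, 15], 0)
  expect_equal(out[4:12, 4:12], g[4:12, 4:12])
})

test_that("open/close/hybrid reconstructions match the geodesic oracle", {
  set.seed(103)
  b <- se_disk(1)
  for (rep in 1:15) {
    g <- random_test_raster(8, 8, 4)
    r <- pmax(g, random_test_raster(8, 8, 4))
    expect_equal(open_reconstruction(g, r, b),
                 oracle_open_reconstruction(g, r, b))
    expect_equal(close_reconstruction(g, pmin(g, r - 0.5), b),
                 oracle_close_reconstruction(g, pmin(g, r - 0.5), b))
    o <- oracle_open_reconstruction(g, g, b)
    expect_equal(hybrid_reconstruction(g, g, b),
                 oracle_close_reconstruction(o, o, b))
  }
})

test_that("close reconstruction fills dark pinholes", {
  b <- se_disk(2)
  g <- matrix(0.8, 16, 16)
  g[8, 8] <- 0 # pinhole smaller than the element
  out <- close_reconstruction(g, g, b)
  expect_equal(out[8, 8], 0.8)
  # image without dark speckles is a fixed point
  flat <- matrix(0.5, 10, 10)
  expect_equal(close_reconstruction(flat, flat, b), flat)
})

test_that("hybrid reconstruction removes salt and pepper and is ordered", {
  b <- se_disk(1)
  clean <- matrix(0.5, 12, 12)
  clean[4:9, 4:9] <- 0.1
  noisy <- clean
  noisy[2, 2] <- 1    # salt
  noisy[6, 6] <- 0    # pepper inside the object
  expect_equal(hybrid_reconstruction(noisy, noisy, b),
               hybrid_reconstruction(clean, clean, b))
  # order of the two stages matters on an asymmetric image
  g <- matrix(c(1, 2, 0, 2, 2, 0, 0, 0, 1, 2, 2, 2, 2, 1, 1, 2, 0,
                3, 3, 1, 0, 3, 2, 0, 1, 3, 2, 1, 0, 1, 1, 2, 0, 1, 1, 3),
              6, 6) / 3
  open_first <- hybrid_reconstruction(g, g, b)
  cl <- close_reconstruction(g, g, b)
  close_first <- open_reconstruction(cl, cl, b)
  expect_false(identical(open_first, close_first))
})

test_that("regional minima match an exhaustive plateau scan", {
  set.seed(104)
  for (rep in 1:15) {
    x <- random_test_raster(7, 7, 5)
    for (conn in c(4, 8)) {
      expect_equal(regional_minima(x, conn),
                   oracle_regional_minima(x, conn))
      expect_equal(regional_maxima(x, conn),
                   oracle_regional_minima(-x, conn))
    }
  }
})

test_that("minima imposition leaves exactly the marker minima", {
  # a single marked pixel becomes the unique regional minimum
  set.seed(105)
  g <- random_test_raster(9, 9)
  mk <- matrix(FALSE, 9, 9)
  mk[5, 5] <- TRUE
  out <- impose_minima(g, mk)
  expect_equal(which(regional_minima(out)), which(mk))
  expect_error(impose_minima(g, matrix(FALSE, 9, 9)), "at least one")
  expect_error(impose_minima(g, mk[1:4, 1:4]), "dimensions")
})

test_that("imposed minima equal the marker set on random reliefs", {
  set.seed(106)
  for (rep in 1:25) {
    g <- random_test_raster(16, 16, 8)
    mk <- matrix(runif(256) < 0.06, 16, 16)
    if (!any(mk)) mk[sample(256, 1)] <- TRUE
    out <- impose_minima(g, mk)
    expect_equal(regional_minima(out), oracle_regional_minima(out))
    expect_equal(which(regional_minima(out)), which(mk))
  }
})

test_that("connected components are labeled deterministically", {
  m <- matrix(FALSE, 6, 6)
  m[1:2, 1:2] <- TRUE
  m[5:6, 5:6] <- TRUE
  m[1, 6] <- TRUE
  lab <- label_components(m)
  expect_equal(max(lab), 3L)
  expect_equal(sort(unique(as.vector(lab))), 0:3)
  expect_equal(lab[1, 1], 1L) # raster order assignment
  # diagonal touch merges under 8- but not 4-connectivity
  d <- matrix(FALSE, 4, 4)
  d[1, 1] <- d[2, 2] <- TRUE
  expect_equal(max(label_components(d, 8)), 1L)
  expect_equal(max(label_components(d, 4)), 2L)
})

test_that("watershed splits a double-well profile at its barrier", {
  # 1-D double well embedded in a matrix
  prof <- c(5, 1, 2, 3, 9, 3, 2, 1, 5) / 10
  surface <- matrix(rep(prof, each = 3), 3, 9)
  markers <- matrix(0L, 3, 9)
  markers[2, 2] <- 1L
  markers[2, 8] <- 2L
  lab <- watershed_transform(surface, markers)
  expect_true(all(lab[, 1:4] == 1L))
  expect_true(all(lab[, 6:9] == 2L))
  # one marker floods everything
  one <- matrix(0L, 3, 9)
  one[2, 5] <- 1L
  expect_true(all(watershed_transform(surface, one) == 1L))
  expect_error(watershed_transform(surface, matrix(0L, 3, 9)), "marker")
})

test_that("watershed agrees with the naive ordered-flooding oracle", {
  set.seed(107)
  for (rep in 1:25) {
    surface <- matrix(runif(100), 10, 10)
    k <- sample(2:4, 1)
    markers <- matrix(0L, 10, 10)
    pts <- sample(100, k)
    markers[pts] <- seq_len(k)
    for (ar in c(TRUE, FALSE)) {
      expect_equal(watershed_transform(surface, markers, assign_ridge = ar),
                   oracle_watershed(surface, markers, assign_ridge = ar))
    }
  }
})

test_that("watershed labels partition the flooded area deterministically", {
  set.seed(108)
  surface <- matrix(runif(400), 20, 20)
  markers <- matrix(0L, 20, 20)
  markers[c(5, 210, 395)] <- 1:3
  a <- watershed_transform(surface, markers)
  b <- watershed_transform(surface, markers)
  expect_identical(a, b)
  expect_true(all(a > 0)) # ridge pixels assigned
  # without ridge assignment the only labels are the marker labels and 0
  c0 <- watershed_transform(surface, markers, assign_ridge = FALSE)
  expect_true(all(c0 %in% 0:3))
  expect_true(all(c0[markers > 0] == markers[markers > 0]))
  expect_equal(sort(unique(as.vector(a))), 1:3)
})
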