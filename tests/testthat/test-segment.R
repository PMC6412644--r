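test_that("preprocess converts RGB to BT.601 luma and respects polarity", {
  red <- array(0, dim = c(8, 8, 3))
  red[, , 1] <- 1
  img <- carrier_image(red, scale = 0.01)
  expect_equal(preprocess(img), matrix(0.299, 8, 8), tolerance = 1e-3)
  # grayscale input passes through (smoothing of a constant is identity)
  flat <- carrier_image(matrix(0.4, 6, 6), scale = 0.01)
  expect_equal(preprocess(flat), matrix(0.4, 6, 6), tolerance = 1e-4)
  # bright-spot polarity is inverted so droplets end up dark
  bright <- carrier_image(matrix(0.9, 6, 6), scale = 0.01,
                          polarity = "bright")
  expect_equal(preprocess(bright), matrix(0.1, 6, 6), tolerance = 1e-4)
  expect_error(carrier_image(array(0, c(4, 4, 2)), scale = 1), "channels")
})

test_that("median smoothing suppresses single-pixel noise", {
  g <- matrix(0.2, 9, 9)
  g[5, 5] <- 1
  img <- carrier_image(g, scale = 0.01)
  out <- preprocess(img)
  expect_equal(out[5, 5], 0.2, tolerance = 1e-3)
})

test_that("Otsu binarization separates bimodal images", {
  half <- matrix(rep(c(0.2, 0.8), each = 32), 8, 8)
  bw <- otsu_binarize(half)
  expect_equal(bw, half < 0.5) # dark side is foreground
  tiny <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(otsu_binarize(tiny), tiny == 0)
  expect_warning(bwc <- otsu_binarize(matrix(0.5, 4, 4)), "constant")
  expect_false(any(bwc))
})

test_that("Otsu threshold matches exhaustive between-class variance search", {
  set.seed(201)
  for (rep in 1:10) {
    x <- matrix(c(rnorm(600, 0.25, 0.05), rnorm(424, 0.75, 0.05)), 32, 32)
    x <- pmin(pmax(x, 0), 1)
    expect_equal(otsu_binarize(x), x <= oracle_otsu_threshold(x))
  }
})

test_that("gradient magnitude is a Sobel response", {
  expect_equal(gradient_magnitude(matrix(0.3, 10, 10)), matrix(0, 10, 10))
  # vertical step edge: maximal response on the edge, zero far away
  step <- cbind(matrix(0, 10, 5), matrix(1, 10, 5))
  g <- gradient_magnitude(step)
  expect_true(all(g[, 5:6] == max(g)))
  expect_true(all(g[, c(1:3, 8:10)] == 0))
  # hand-checkable random image equals direct convolution
  set.seed(202)
  for (rep in 1:5) {
    x <- random_test_raster(5, 5)
    expect_equal(gradient_magnitude(x), oracle_sobel_magnitude(x))
  }
  # morphological gradient of a constant image is zero
  expect_equal(gradient_magnitude(matrix(0.7, 8, 8), "morphological"),
               matrix(0, 8, 8))
})

test_that("shape degree has its analytic values", {
  r <- c(1, 5.5, 40)
  expect_equal(shape_degree(pi * r^2, 2 * pi * r), rep(1, 3))
  expect_equal(shape_degree(4^2, 4 * 4), pi / 4)
  # limiting dumbbell: two unit disks joined at a point
  expect_equal(shape_degree(2 * pi, 4 * pi), 0.5)
  expect_error(shape_degree(0, 1), "positive")
  expect_error(shape_degree(1, 0), "positive")
})

test_that("digital disks approach shape degree 1 with the chain-code estimator", {
  for (r in c(5, 10, 20, 40)) {
    m <- disk_mask(r)
    f <- region_features(label_components(m))
    expect_equal(nrow(f), 1L)
    expect_gt(f$shape_degree, 0.95)
    expect_lte(f$shape_degree, 1)
    expect_equal(f$area_px, sum(m))
    # perimeter estimate within 3% of the true circumference
    expect_equal(f$perimeter_px, 2 * pi * r, tolerance = 0.03)
  }
})

test_that("area threshold is the mean region area", {
  expect_equal(area_threshold(40), 40)
  expect_equal(area_threshold(c(10, 20, 30)), 20)
  set.seed(203)
  a <- runif(1000, 5, 500)
  expect_equal(area_threshold(a), sum(a) / 1000)
  expect_error(area_threshold(numeric()), "at least one")
})

test_that("adhesion decision combines shape degree and area", {
  d <- 100
  expect_true(classify_adhesion(0.86, 50, d = d))    # typical single
  expect_false(classify_adhesion(0.48, 50, d = d))   # typical adhesive
  expect_false(classify_adhesion(0.9, 200, d = d))   # large circular blob
  expect_equal(shape_degree_threshold(), 0.67)
  expect_equal(shape_degree_threshold(0.86, 0.48), (0.86 + 0.48) / 2)
})

test_that("foreground markers mark each isolated droplet once", {
  g <- matrix(0.9, 48, 48)
  g[disk_mask(6, c(14, 14), 48, 48)] <- 0.15
  g[disk_mask(5, c(34, 34), 48, 48)] <- 0.2
  fm <- foreground_markers(g)
  expect_equal(max(label_components(fm)), 2L)
  one <- matrix(0.9, 32, 32)
  d1 <- disk_mask(6, c(16, 16), 32, 32)
  one[d1] <- 0.1
  fm1 <- foreground_markers(one)
  expect_equal(max(label_components(fm1)), 1L)
  expect_true(all(d1[fm1])) # markers strictly inside the droplet
})

test_that("foreground markers recover every droplet of a synthetic scene", {
  sp <- scene_spec(n_droplets = 50, adhesion_fraction = 0, width_px = 384,
                   height_px = 384, radius_meanlog = log(6), seed = 3)
  sc <- generate_scene(sp)
  fm <- foreground_markers(preprocess(sc$image))
  expect_equal(max(label_components(fm)), 50L)
})

test_that("background markers run between droplets, never through them", {
  two <- disk_mask(5, c(12, 16), 32, 32) | disk_mask(5, c(22, 16), 32, 32)
  bm <- background_markers(two)
  expect_false(any(bm & two))
  # a ridge passes between the two disks (row 17 separates the centers)
  expect_true(any(bm[16:18, ]))
  # single centered disk: border ring only, disjoint from the disk
  one <- disk_mask(6, c(16, 16), 32, 32)
  bm1 <- background_markers(one)
  expect_false(any(bm1 & one))
  expect_true(all(bm1[c(1, 32), ]) && all(bm1[, c(1, 32)]))
  expect_warning(background_markers(matrix(TRUE, 4, 4)), "all-foreground")
  sc <- generate_scene(scene_spec(n_droplets = 30, width_px = 256,
                                  height_px = 256, seed = 5))
  bm2 <- background_markers(otsu_binarize(preprocess(sc$image)))
  expect_false(any(bm2 & truth_mask(sc)))
})

test_that("mmcws keeps disjoint disks intact and splits fused pairs", {
  # 20 disjoint disks: 20 labels, no region lost or split
  set.seed(204)
  g <- matrix(0.05, 200, 200)
  centers <- expand.grid(r = seq(25, 175, length.out = 5)[1:4],
                         c = seq(25, 175, length.out = 5))
  for (k in 1:20)
    g[disk_mask(7, c(centers$r[k], centers$c[k]), 200, 200)] <- 0.9
  img <- carrier_image(pmin(g + matrix(rnorm(4e4, 0, 0.01), 200, 200), 1),
                       scale = 0.002, polarity = "bright")
  seg <- mmcws(img)
  expect_equal(nrow(seg$regions), 20L)
  # two overlapping disks: one connected component, two final labels
  h <- matrix(0.05, 64, 64)
  # centers 1.5 r apart: one fused component
  h[disk_mask(8, c(32, 26), 64, 64) | disk_mask(8, c(32, 38), 64, 64)] <- 0.9
  img2 <- carrier_image(h, scale = 0.002, polarity = "bright")
  seg2 <- mmcws(img2)
  expect_equal(max(label_components(seg2$binary)), 1L)
  expect_equal(nrow(seg2$regions), 2L)
  expect_true(all(seg2$regions$is_adhesive))
})

test_that("mmcws is deterministic and never merges components", {
  sc <- generate_scene(scene_spec(n_droplets = 40, width_px = 256,
                                  height_px = 256, seed = 6))
  a <- mmcws(sc$image)
  b <- mmcws(sc$image)
  expect_identical(a$labels, b$labels)
  n_cc <- max(label_components(a$binary))
  expect_gte(nrow(a$regions), n_cc - sum(a$regions$area_px < 4))
  # labels are contiguous 1..n and live on foreground only
  expect_equal(sort(unique(as.vector(a$labels[a$labels > 0]))),
               seq_len(nrow(a$regions)))
  expect_true(all(a$binary[a$labels > 0]))
})

test_that("mmcws labels partition the kept foreground", {
  sc <- generate_scene(scene_spec(n_droplets = 30, width_px = 256,
                                  height_px = 256, seed = 8))
  seg <- mmcws(sc$image)
  # every kept region's area matches its label count; areas sum to the
  # labeled foreground
  expect_equal(sum(seg$regions$area_px), sum(seg$labels > 0))
  expect_equal(seg$regions$area_px,
               as.numeric(tabulate(seg$labels[seg$labels > 0],
                                   nbins = nrow(seg$regions))))
})

test_that("blank and constant images give an empty result with a warning", {
  img <- carrier_image(matrix(0.5, 32, 32), scale = 0.01)
  w <- capture_warnings(seg <- mmcws(img))
  expect_match(w, "empty foreground|constant", all = FALSE)
  expect_equal(nrow(seg$regions), 0L)
  expect_equal(max(seg$labels), 0L)
})

test_that("structuring element scales down for coarse spatial scales", {
  expect_equal(attr(se_disk(3), "radius"), 3L)
  expect_error(se_disk(0), ">= 1")
  # scale so coarse that droplets span under 6 px: mmcws still works
  sc <- generate_scene(scene_spec(n_droplets = 8, width_px = 96,
                                  height_px = 96, scale = 0.005, seed = 9))
  seg <- mmcws(sc$image)
  expect_gt(nrow(seg$regions), 0L)
})
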