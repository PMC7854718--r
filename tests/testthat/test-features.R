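test_that("gray rebinning maps the range onto the bins", {
  img8 <- matrix(0:255, 16, 16)
  expect_equal(as.vector(rebin_gray(img8, 256)), 0:255)
  expect_equal(sort(unique(as.vector(rebin_gray(matrix(c(0, 255), 1), 2)))),
               c(0L, 1L))
  const <- rebin_gray(matrix(3.7, 4, 4), 16)
  expect_true(all(const == 0L))
  expect_error(rebin_gray(img8, 1), ">= 2")
})

test_that("the worked 2x2 co-occurrence example evaluates exactly", {
  win <- matrix(c(0L, 0L, 1L, 1L), 2, 2)   # [[0,1],[0,1]]
  g <- glcm(win, offset = c(0, 1), levels = 2)
  expect_equal(g$counts, matrix(c(0, 0, 2, 0), 2, 2))
  expect_equal(g$normalized[1, 2], 1)
  expect_equal(sum(g$normalized), 1)
  h <- haralick_features(g)
  expect_equal(h[["contrast"]], 1)
  expect_equal(h[["energy"]], 1)
  expect_equal(h[["homogeneity"]], 0.5)
  expect_equal(h[["correlation"]], 0)      # zero marginal variance

  const <- glcm(matrix(2L, 3, 3), levels = 4)
  expect_equal(const$normalized[3, 3], 1)
  hc <- haralick_features(const)
  expect_equal(hc[["contrast"]], 0)
  expect_equal(hc[["energy"]], 1)
  expect_equal(hc[["homogeneity"]], 1)
  expect_error(glcm(matrix(1L, 2, 2), offset = c(0, 0)), "nonzero")
})

test_that("descriptors match brute-force pair enumeration on random windows", {
  set.seed(17)
  for (trial in 1:30) {
    L <- sample(c(4, 8), 1)
    win <- matrix(sample(0:(L - 1), 25, replace = TRUE), 5, 5)
    off <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(0L, 2L))[[sample(4, 1)]]
    h <- haralick_features(glcm(win, offset = off, levels = L))
    o <- oracle_glcm_descriptors(win, off[1], off[2], L)
    expect_equal(h, o, tolerance = 1e-12)
  }
})

test_that("sliding maps agree with per-window computation and keep shape", {
  set.seed(23)
  img <- matrix(sample(0:7, 15 * 12, replace = TRUE), 15, 12)
  maps <- texture_maps(img, window = 5, offset = c(0, 1))
  expect_identical(dim(maps$contrast), dim(img))
  # spot-check interior pixels against the R single-window route
  for (pt in list(c(5, 5), c(8, 3), c(10, 10))) {
    win <- img[(pt[1] - 2):(pt[1] + 2), (pt[2] - 2):(pt[2] + 2)]
    h <- haralick_features(glcm(win, levels = 8))
    expect_equal(maps$contrast[pt[1], pt[2]], h[["contrast"]],
                 tolerance = 1e-12)
    expect_equal(maps$correlation[pt[1], pt[2]], h[["correlation"]],
                 tolerance = 1e-12)
    expect_equal(maps$energy[pt[1], pt[2]], h[["energy"]],
                 tolerance = 1e-12)
    expect_equal(maps$homogeneity[pt[1], pt[2]], h[["homogeneity"]],
                 tolerance = 1e-12)
  }
  expect_error(texture_maps(img, window = 4), "odd")
})

test_that("constant and step-edge images produce the expected maps", {
  const <- matrix(5L, 10, 10)
  m <- texture_maps(const, window = 5)
  expect_true(all(m$contrast == 0))
  expect_true(all(m$homogeneity == 1))
  expect_true(all(m$energy == 1))

  edge <- cbind(matrix(0L, 9, 6), matrix(7L, 9, 6))
  me <- texture_maps(edge, window = 5)
  # contrast is nonzero only in the band straddling the edge (cols 5..8:
  # windows whose horizontal pairs cross columns 6|7)
  expect_true(all(me$contrast[, c(1:4, 9:12)] == 0))
  expect_true(all(me$contrast[, 5:8] > 0))
})

test_that("descriptor maps are shift invariant under data-range rebinning", {
  set.seed(29)
  base <- matrix(runif(100, 0, 10), 10, 10)
  g1 <- rebin_gray(base, 8)
  g2 <- rebin_gray(base + 137.5, 8)
  expect_identical(g1 + 0L, g2 + 0L)
  m1 <- texture_maps(g1); m2 <- texture_maps(g2)
  expect_equal(m1, m2)
})

test_that("descriptor values stay inside their theoretical bounds", {
  set.seed(31)
  img <- matrix(sample(0:15, 400, replace = TRUE), 20, 20)
  m <- texture_maps(img, window = 5)
  expect_true(all(m$energy > 0 & m$energy <= 1))
  expect_true(all(m$homogeneity > 0 & m$homogeneity <= 1))
  expect_true(all(m$contrast >= 0 & m$contrast <= 15^2))
  e <- entropy_map(img, window = 5)
  expect_true(all(e >= 0 & e <= log2(16) + 1e-12))
})

test_that("entropy map reproduces closed-form histogram entropies", {
  expect_true(all(entropy_map(matrix(3L, 8, 8), 5) == 0))
  two <- matrix(c(0L, 1L), 6, 6)            # half zeros, half ones per window
  # interior windows: 5x5 with alternating rows -> 15/10 or 10/15 split
  e <- entropy_map(two, 5)
  p <- 15 / 25
  expect_equal(e[3, 3], -p * log2(p) - (1 - p) * log2(1 - p),
               tolerance = 1e-12)
  # uniform window over k levels
  u <- matrix(rep(0:4, 5), 5, 5)
  expect_equal(entropy_map(u, 5)[3, 3], log2(5), tolerance = 1e-12)
  set.seed(5)
  img <- matrix(sample(0:9, 121, replace = TRUE), 11, 11)
  e2 <- entropy_map(img, 3)
  expect_equal(e2[6, 6], oracle_entropy(img[5:7, 5:7]), tolerance = 1e-12)
})

test_that("L*u*v* conversion matches the reference converter", {
  white <- array(1, c(1, 1, 3))
  luv_w <- rgb_to_luv(white)
  expect_equal(luv_w[1, 1, "L"], 100, tolerance = 1e-3, ignore_attr = TRUE)
  black <- array(0, c(1, 1, 3))
  expect_equal(as.vector(rgb_to_luv(black)), c(0, 0, 0), tolerance = 1e-9)

  set.seed(37)
  cols <- matrix(runif(30), ncol = 3)
  img <- array(cols, c(10, 1, 3))
  mine <- rgb_to_luv(img)
  ref <- grDevices::convertColor(cols, from = "sRGB", to = "Luv")
  expect_equal(mine[, 1, "L"], ref[, 1], tolerance = 0.1,
               ignore_attr = TRUE)
  expect_equal(mine[, 1, "u"], ref[, 2], tolerance = 0.1,
               ignore_attr = TRUE)
  expect_equal(mine[, 1, "v"], ref[, 3], tolerance = 0.1,
               ignore_attr = TRUE)
  expect_error(rgb_to_luv(matrix(1, 3, 3)), "RGB")
})

test_that("feature stack aligns eleven maps to the image grid", {
  w <- generate_well(well_spec(side = 64, n_colonies = 2, radius_mean = 8,
                               seed = 5))
  st <- feature_stack(w$image)
  expect_named(st, c("R", "G", "B", "L", "u", "v", "contrast",
                     "correlation", "energy", "homogeneity", "entropy"))
  for (m in st) expect_identical(dim(m), c(64L, 64L))
  expect_identical(feature_set_maps("rgb"), c("R", "G", "B"))
  expect_identical(feature_set_maps("luv"), c("L", "u", "v"))
  expect_identical(feature_set_maps("homogeneity"), "homogeneity")
})
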