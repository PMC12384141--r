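test_that("crop follows bounding-box arithmetic and clips at edges", {
  vol <- array(rnorm(100^3 / 100), dim = c(100, 100, 1))
  vol <- array(rnorm(100 * 100 * 40), dim = c(100, 100, 40))
  mask <- array(FALSE, dim = c(100, 100, 40))
  mask[50, 50, 20] <- TRUE
  cr <- crop_subvolume(vol, mask, pad_xy = 30, pad_z = 10)
  expect_equal(dim(cr$volume), c(61, 61, 21))
  expect_true(cr$mask[31, 31, 11])

  # mask touching the edge: clipped, no padding beyond bounds
  mask2 <- array(FALSE, dim = c(100, 100, 40))
  mask2[1, 1, 1] <- TRUE
  cr2 <- crop_subvolume(vol, mask2, pad_xy = 30, pad_z = 10)
  expect_equal(dim(cr2$volume), c(31, 31, 11))

  # zero padding = tight bounding box
  mask3 <- array(FALSE, dim = c(100, 100, 40))
  mask3[10:12, 20:25, 5:6] <- TRUE
  cr3 <- crop_subvolume(vol, mask3, pad_xy = 0, pad_z = 0)
  expect_equal(dim(cr3$volume), c(3, 6, 2))

  expect_error(crop_subvolume(vol, array(FALSE, dim = dim(vol))), "empty")
})

test_that("peritumoral mask is an exact in-plane margin, disjoint from tumor", {
  # single-pixel tumor, margin 1, 3x3 element: 8 peritumoral pixels
  m <- array(FALSE, dim = c(9, 9, 3))
  m[5, 5, 2] <- TRUE
  rm1 <- make_peritumoral_mask(m, margin_px = 1)
  expect_equal(sum(rm1$peritumoral), 8)
  expect_equal(sum(rm1$peritumoral[, , 2]), 8)  # no growth in z

  # margin 5: Chebyshev ball of radius 5 in-plane, 11^2 - 1 shell pixels
  m2 <- array(FALSE, dim = c(15, 15, 3))
  m2[8, 8, 2] <- TRUE
  rm5 <- make_peritumoral_mask(m2, margin_px = 5)
  expect_equal(sum(rm5$peritumoral), 11^2 - 1)

  # disjointness for random blobs
  set.seed(1)
  for (k in 1:5) {
    blob <- array(runif(16 * 16 * 4) > 0.7, dim = c(16, 16, 4))
    if (!any(blob)) next
    rmk <- make_peritumoral_mask(blob, margin_px = 2)
    expect_equal(sum(rmk$tumoral & rmk$peritumoral), 0)
  }
  expect_error(make_peritumoral_mask(m, margin_px = 0), "margin_px")
})

test_that("min-max normalization is affine, bounded and handles constants", {
  v <- array(c(0, 5, 10, 2, 7, 10, 0, 3), dim = c(2, 2, 2))
  out <- minmax_normalize(v)
  expect_equal(range(out), c(0, 1))
  expect_equal(sort(unique(c(out)))[2], 0.2)  # 2/10
  expect_equal(minmax_normalize(array(3, dim = c(2, 2, 2))),
               array(0, dim = c(2, 2, 2)))
  expect_error(minmax_normalize(array(c(1, NA), dim = c(2, 1, 1))), "finite")
})

test_that("GLCM accumulation matches hand counts and normalizes to 1", {
  # 2x1x1 window, levels 0 and 1, offset (1,0,0): symmetric halves
  w <- array(c(0L, 1L), dim = c(2, 1, 1))
  g <- glcm_accumulate(w, c(1, 0, 0), 2)
  expect_equal(g[1, 2], 0.5)
  expect_equal(g[2, 1], 0.5)
  expect_equal(g[1, 1], 0)

  # constant window: single diagonal entry 1
  wc <- array(2L, dim = c(3, 3, 3))
  gc <- glcm_accumulate(wc, c(0, 0, 1), 4)
  expect_equal(gc[3, 3], 1)
  expect_equal(sum(gc), 1)

  # random windows: symmetry and unit mass for every canonical offset
  set.seed(2)
  w3 <- array(sample(0:3, 27, replace = TRUE), dim = c(3, 3, 3))
  offs <- glcm_offsets()
  for (o in seq_len(nrow(offs))) {
    go <- glcm_accumulate(w3, offs[o, ], 4)
    expect_equal(sum(go), 1)
    expect_equal(go, t(go))
  }
  expect_error(glcm_accumulate(w3, c(2, 0, 0), 4), "unit-neighbourhood")
  expect_error(glcm_accumulate(w3, c(1, 0, 0), 2), "range")
})

test_that("constant volumes give Energy 1 and Entropy 0 everywhere", {
  v <- array(0.4, dim = c(5, 5, 4))
  maps <- haralick_maps(v, n_levels = 16)
  expect_true(all(maps$Energy == 1))
  expect_true(all(maps$Entropy == 0))
  expect_true(all(maps$Inertia == 0))
})

test_that("per-voxel maps match the brute-force oracle to 1e-10", {
  set.seed(7)
  for (dims in list(c(5, 5, 5), c(6, 4, 3))) {
    v <- array(runif(prod(dims)), dim = dims)
    got <- haralick_maps(v, n_levels = 8, window_radius = 1)
    want <- oracle_haralick_maps(v, n_levels = 8, window_radius = 1)
    for (f in names(want)) {
      expect_lt(max(abs(got[[f]] - want[[f]])), 1e-10)
    }
  }
})

test_that("maps are invariant to affine intensity rescaling before normalization", {
  set.seed(8)
  v <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  a <- haralick_maps(minmax_normalize(v), 16)
  b <- haralick_maps(minmax_normalize(3 + 40 * v), 16)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("gradient magnitude is spacing-aware and exact on ramps", {
  d <- c(8, 8, 4)
  ramp <- array(rep(seq_len(d[1]) * 0.5, times = prod(d[2:3])), dim = d)
  vol <- ct_subvolume(ramp, spacing = c(2, 1, 1))
  g <- gradient_map(vol)
  # interior gradient = a / spacing = 0.5 / 2
  expect_equal(unique(round(c(g[2:7, , ]), 12)), 0.25)
  expect_equal(gradient_map(array(1, dim = d)), array(0, dim = d))
  expect_warning(gradient_map(array(runif(9), dim = c(3, 3, 1))), "single slice")
})

test_that("region statistics follow the declared conventions", {
  map <- array(0, dim = c(3, 1, 1))
  map[] <- c(1, 2, 3)
  mask <- array(TRUE, dim = c(3, 1, 1))
  s <- region_statistics(map, mask)
  expect_equal(unname(s["mean"]), 2)
  expect_equal(unname(s["median"]), 2)
  expect_equal(unname(s["variance"]), 2 / 3)  # population convention
  expect_equal(unname(s["skewness"]), 0)
  expect_true(s["10thPercentile"] <= s["median"])
  expect_true(s["median"] <= s["90thPercentile"])
  expect_error(region_statistics(map, array(c(TRUE, FALSE, FALSE), dim = c(3, 1, 1))),
               "fewer than 2")
})

test_that("extraction emits exactly 63 named features per region, deterministically", {
  co <- generate_cohort(cohort_config(n_patients = 1, seed = 21))
  f1 <- extract_features(co$volume[[1]], co$tumor_mask[[1]])
  f2 <- extract_features(co$volume[[1]], co$tumor_mask[[1]])
  expect_identical(f1, f2)
  expect_equal(sum(f1$region == "tumoral"), 63)
  expect_equal(sum(f1$region == "peritumoral"), 63)
  # 9 maps x 7 statistics
  maps <- unique(sub("_[^_]+$", "", f1$feature))
  expect_equal(length(maps), 9)
  expect_setequal(unique(sub("^.*_", "", f1$feature)),
                  c("mean", "median", "variance", "skewness", "kurtosis",
                    "10thPercentile", "90thPercentile"))
  expect_true(all(f1$value[grepl("_variance$", f1$feature)] >= 0))
})
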