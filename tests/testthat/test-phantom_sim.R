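test_that("single-tensor signal model matches analytic values", {
  g <- c(1, 0, 0) / 1
  expect_equal(predict_signal(rep(0.001, 3), 1000, c(0, 1, 0), s0 = 1),
               exp(-1), tolerance = 1e-12)
  expect_equal(predict_signal(rep(0.001, 3), 0, c(0, 0, 0), s0 = 7), 7)
  # projection-fiber tensor sampled along z
  expect_equal(predict_signal(c(0.00058, 0.00049, 0.00102), 1000, c(0, 0, 1)),
               exp(-1.02), tolerance = 1e-12)
  expect_error(predict_signal(c(-1e-4, 1e-4, 1e-4), 1000, c(0, 0, 1)),
               "negative")
  expect_error(predict_signal(rep(1e-3, 3), 1000, c(0.5, 0, 0)), "unit")
})

test_that("Rician noise is deterministic under a seed and satisfies the second-moment identity", {
  s <- seq(0, 20, length.out = 11)
  expect_identical(add_rician_noise(s, 0), s)
  a <- add_rician_noise(s, 1.5, seed = 9)
  b <- add_rician_noise(s, 1.5, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, add_rician_noise(s, 1.5, seed = 10)))
  # E[noisy^2] = signal^2 + 2 sigma^2 (checked by brute-force sampling)
  n <- 1e6; sig <- 10; sigma <- 2
  set.seed(3)
  draws <- add_rician_noise(rep(sig, n), sigma)
  expect_equal(mean(draws^2), sig^2 + 2 * sigma^2,
               tolerance = 5 * stats::sd(draws^2) / sqrt(n) / (sig^2))
})

test_that("phantom truth realizes the layout geometry", {
  lay <- small_layout()
  tr <- build_truth(lay)
  expect_equal(dim(tr$label_map), lay$grid_shape)
  # every voxel in the left projection box carries the projection tensor
  pb <- lay$fiber_boxes$left$projection
  for (v in list(pb$lo, pb$hi - 1L)) {
    ijk <- v + 1L
    expect_equal(tr$tensors[ijk[1], ijk[2], ijk[3], 1:3],
                 lay$region_tensors$projection)
  }
  # hemispheres mirror across the mid-sagittal plane
  nx <- lay$grid_shape[1]
  expect_equal(tr$label_map[nx:1, , ] %in% 4:6, tr$label_map %in% 7:9)
  # air voxels have no tensor
  expect_true(all(is.na(tr$tensors[1, 1, 1, ])))
})

test_that("invalid layouts are rejected", {
  expect_error(voxel_box(c(4, 9, 3), c(7, 9, 5)), "empty")
  expect_error(small_layout(ventricle = voxel_box(c(4, 6, 3), c(12, 14, 7))),
               "overlap")
  # fiber tensor with the wrong principal axis is ill-posed for selection
  rt <- random_region_tensors()
  rt$projection <- c(0.002, 0.0005, 0.0004)
  expect_error(small_layout(region_tensors = rt), "projection.*z")
})

test_that("simulated DWI matches the forward model and the acquisition shape", {
  lay <- small_layout(snr = Inf)
  sim <- simulate_dwi(lay, seed = 1)
  expect_equal(dim(sim$dwi$data)[4], 33L)
  # noiseless signals equal predict_signal voxelwise
  pb <- lay$fiber_boxes$left$projection$lo + 1L
  sig <- sim$dwi$data[pb[1], pb[2], pb[3], ]
  expected <- vapply(seq_len(sim$scheme$n_volumes), function(k)
    predict_signal(lay$region_tensors$projection, sim$scheme$bvals[k],
                   sim$scheme$bvecs[k, ], lay$s0), numeric(1))
  expect_equal(sig, expected, tolerance = 1e-12)
  # seeds shift only the noise
  lay30 <- small_layout(snr = 30)
  s1 <- simulate_dwi(lay30, seed = 1)
  s2 <- simulate_dwi(lay30, seed = 2)
  expect_false(identical(s1$dwi$data, s2$dwi$data))
  expect_identical(simulate_dwi(lay30, seed = 1)$dwi$data, s1$dwi$data)
})

test_that("ground-truth ALPS follows the ratio formula and its invariances", {
  expect_equal(truth_alps(phantom_layout())$bilateral_mean,
               mean(c(0.00058, 0.00064)) / mean(c(0.00049, 0.00039)),
               tolerance = 1e-12)
  # all four formula diffusivities equal -> exactly 1
  rt <- list(projection = c(5e-4, 5e-4, 1e-3),
             association = c(5e-4, 1e-3, 5e-4),
             subcortical = c(1e-3, 5e-4, 5e-4),
             ventricle = rep(3e-3, 3), background = rep(8e-4, 3))
  expect_equal(truth_alps(small_layout(region_tensors = rt))$bilateral_mean, 1)
  # scale invariance over random layouts
  set.seed(11)
  for (i in 1:10) {
    rt <- random_region_tensors()
    a1 <- truth_alps(small_layout(region_tensors = rt))$bilateral_mean
    rt2 <- lapply(rt, function(d) d * 2)
    a2 <- truth_alps(small_layout(region_tensors = rt2))$bilateral_mean
    expect_equal(a1, a2, tolerance = 1e-12)
  }
})

test_that("phantom files round-trip with a faithful truth sidecar", {
  lay <- small_layout(snr = 30)
  sim <- simulate_dwi(lay, seed = 4)
  dir <- tempfile(); files <- write_phantom(sim, dir)
  expect_true(all(file.exists(files)))
  side <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  expect_equal(side$true_alps$bilateral_mean,
               truth_alps(lay)$bilateral_mean, tolerance = 1e-12)
  back <- read_volume(files[["nii"]])
  expect_equal(back$data, sim$dwi$data, tolerance = 1e-4)
  expect_equal(back$voxel_size, lay$voxel_size)
})
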