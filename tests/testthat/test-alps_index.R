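fit_small_phantom <- function(snr = Inf, seed = 1, region_tensors = NULL) {
  lay <- small_layout(snr = snr, region_tensors = region_tensors)
  sim <- simulate_dwi(lay, seed = seed)
  list(lay = lay, sim = sim,
       tv = fit_tensor_volume(sim$dwi, sim$scheme,
                              box_mask(lay$brain, lay$grid_shape)))
}

test_that("fiber voxel selection maximizes principal-eigenvector alignment", {
  ph <- fit_small_phantom()
  box <- ph$lay$fiber_boxes$left$projection
  sel <- select_fiber_voxel(ph$tv, box, "z")
  expect_equal(unname(sel$diffusivities),
               ph$lay$region_tensors$projection, tolerance = 1e-12)
  expect_equal(sel$alignment, 1, tolerance = 1e-9)
  # the selected voxel lies inside the search box
  expect_true(all(sel$voxel >= box$lo & sel$voxel < box$hi))
  # uniform box -> tie broken to first voxel in (x, then y, then z) order
  expect_true(sel$tie)
  expect_equal(sel$voxel, box$lo)
  # a strictly better-aligned competitor wins over near-aligned neighbors:
  # association box searched along y picks association voxels, not projection
  sely <- select_fiber_voxel(ph$tv, ph$lay$fiber_boxes$left$association, "y")
  expect_equal(unname(sely$diffusivities),
               ph$lay$region_tensors$association, tolerance = 1e-12)
})

test_that("ALPS ratio matches hand arithmetic and its invariances", {
  d <- list(projection = c(Dxx = 0.00058, Dyy = 0.00049, Dzz = 0.00102),
            association = c(Dxx = 0.00064, Dyy = 0.00101, Dzz = 0.00039))
  expect_equal(compute_alps(d)$alps, 0.00061 / 0.00044, tolerance = 1e-12)
  # equal terms -> exactly 1
  eq <- list(projection = c(Dxx = 5e-4, Dyy = 5e-4, Dzz = 1e-3),
             association = c(Dxx = 5e-4, Dyy = 1e-3, Dzz = 5e-4))
  expect_equal(compute_alps(eq)$alps, 1)
  # global scaling leaves the ratio unchanged
  d2 <- lapply(d, function(v) v * 3.14)
  expect_equal(compute_alps(d2)$alps, compute_alps(d)$alps, tolerance = 1e-12)
  # nonpositive term is a domain error
  bad <- d; bad$projection["Dyy"] <- 0
  expect_error(compute_alps(bad), "Dyy_proj")
})

test_that("noiseless pipeline reproduces ground truth across random layouts", {
  lay <- small_layout()
  sim <- simulate_dwi(lay, seed = 1)
  res <- alps_pipeline(sim$dwi, sim$scheme, default_roi_spec(lay))
  truth <- truth_alps(lay)$bilateral_mean
  expect_lt(abs(res$alps - truth) / truth, 1e-6)
  expect_equal(unname(res$per_hemisphere["left"]),
               unname(res$per_hemisphere["right"]), tolerance = 1e-9)
  expect_equal(res$alps, mean(res$per_hemisphere))
  set.seed(31)
  for (i in 1:5) {
    rt <- random_region_tensors()
    layr <- small_layout(region_tensors = rt)
    simr <- simulate_dwi(layr, seed = i)
    resr <- alps_pipeline(simr$dwi, simr$scheme, default_roi_spec(layr))
    tr <- truth_alps(layr)$bilateral_mean
    expect_lt(abs(resr$alps - tr) / tr, 1e-6)
  }
})

test_that("isotropic fiber regions give an ALPS index of 1", {
  rt <- list(projection = c(5e-4, 5e-4, 5.0001e-4),
             association = c(5e-4, 5.0001e-4, 5e-4),
             subcortical = c(5.0001e-4, 5e-4, 5e-4),
             ventricle = rep(3e-3, 3), background = rep(8e-4, 3))
  lay <- small_layout(region_tensors = rt)
  sim <- simulate_dwi(lay, seed = 1)
  res <- alps_pipeline(sim$dwi, sim$scheme, default_roi_spec(lay))
  expect_equal(res$alps, 1, tolerance = 1e-3)
})

test_that("noisy pipeline stays near truth and is deterministic", {
  lay <- small_layout(snr = 30)
  roi <- default_roi_spec(lay)
  truth <- truth_alps(lay)$bilateral_mean
  # single-voxel selection is noisy; its median error over noise
  # realizations stays within 5% of truth
  errs <- vapply(1:5, function(s) {
    sim <- simulate_dwi(lay, seed = s)
    abs(alps_pipeline(sim$dwi, sim$scheme, roi)$alps - truth) / truth
  }, numeric(1))
  expect_lt(median(errs), 0.05)
  sim <- simulate_dwi(lay, seed = 3)
  res <- alps_pipeline(sim$dwi, sim$scheme, roi)
  res2 <- alps_pipeline(simulate_dwi(lay, seed = 3)$dwi, sim$scheme, roi)
  expect_identical(res$alps, res2$alps)
})

test_that("ALPS increases monotonically with projection-fiber Dxx", {
  vals <- c(4e-4, 5e-4, 6e-4)
  out <- vapply(vals, function(dxx) {
    rt <- list(projection = c(dxx, 0.00049, 0.00102),
               association = c(0.00064, 0.00101, 0.00039),
               subcortical = c(0.00108, 0.00068, 0.00060),
               ventricle = rep(3e-3, 3), background = rep(8e-4, 3))
    lay <- small_layout(region_tensors = rt)
    sim <- simulate_dwi(lay, seed = 1)
    alps_pipeline(sim$dwi, sim$scheme, default_roi_spec(lay))$alps
  }, numeric(1))
  expect_true(all(diff(out) > 0))
})

test_that("pipeline is invariant to S0 rescaling and honors hemisphere modes", {
  lay <- small_layout()
  sim <- simulate_dwi(lay, seed = 1)
  roi <- default_roi_spec(lay)
  res <- alps_pipeline(sim$dwi, sim$scheme, roi)
  scaled <- image_volume(sim$dwi$data * 2.5, lay$voxel_size)
  expect_equal(alps_pipeline(scaled, sim$scheme, roi)$alps, res$alps,
               tolerance = 1e-9)
  left <- alps_pipeline(sim$dwi, sim$scheme, roi, hemisphere_mode = "left")
  right <- alps_pipeline(sim$dwi, sim$scheme, roi, hemisphere_mode = "right")
  expect_equal(mean(c(left$alps, right$alps)), res$alps, tolerance = 1e-12)
})
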