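# Synthetic DWI phantom: axis-aligned fiber blocks around a central ventricle,
# with an analytic ground-truth ALPS index.

#' Axis-aligned voxel box
#'
#' Boxes are 0-based, half-open per axis: a voxel (i, j, k) lies inside when
#' lo <= (i, j, k) < hi componentwise.
#'
#' @param lo,hi Integer length-3 vectors (inclusive lower, exclusive upper).
#' @return A list of class \code{voxel_box}.
#' @export
voxel_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  stopifnot(length(lo) == 3L, length(hi) == 3L)
  if (any(hi <= lo))
    stop("empty voxel box: hi must exceed lo on every axis", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "voxel_box")
}

boxes_overlap <- function(a, b) all(a$lo < b$hi & b$lo < a$hi)

box_inside <- function(inner, outer)
  all(inner$lo >= outer$lo) && all(inner$hi <= outer$hi)

mirror_box_x <- function(b, nx) voxel_box(c(nx - b$hi[1], b$lo[2:3]),
                                          c(nx - b$lo[1], b$hi[2:3]))

#' Logical mask of a box on a grid
#' @param box A \code{\link{voxel_box}}.
#' @param grid_shape Length-3 integer grid dimensions.
#' @return Logical 3D array.
#' @export
box_mask <- function(box, grid_shape) {
  m <- array(FALSE, grid_shape)
  m[(box$lo[1] + 1):box$hi[1], (box$lo[2] + 1):box$hi[2],
    (box$lo[3] + 1):box$hi[3]] <- TRUE
  m
}

.fiber_types <- c("projection", "association", "subcortical")
.fiber_axis <- c(projection = 3L, association = 2L, subcortical = 1L)

rot_about_axis <- function(axis, theta) {
  u <- c(0, 0, 0); u[axis] <- 1
  ct <- cos(theta); st <- sin(theta)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ct * diag(3) + st * ux + (1 - ct) * tcrossprod(u)
}

tensor6_to_mat <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

mat_to_tensor6 <- function(m)
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])

#' Define a periventricular DWI phantom layout
#'
#' The phantom is a rectangular "brain" of isotropic tissue containing a
#' central CSF-filled ventricle box flanked, in each hemisphere, by three
#' fiber blocks whose diffusion tensors are diagonal in scanner axes:
#' projection fibers (fastest diffusion along z), association fibers (along
#' y) and subcortical fibers (along x). Voxels outside the brain carry zero
#' signal. Default diffusivities are representative periventricular values
#' (mm^2/s); the default grid is 32 x 32 x 16 voxels at 2 x 2 x 2.25 mm.
#'
#' @param grid_shape Length-3 integer grid dimensions.
#' @param voxel_size Voxel edge lengths in mm.
#' @param brain Brain (tissue) box.
#' @param ventricle Ventricle (CSF) box.
#' @param fiber_boxes_left Named list of \code{projection}, \code{association},
#'   \code{subcortical} boxes for the left hemisphere; the right hemisphere is
#'   their mirror across the mid-sagittal plane unless
#'   \code{fiber_boxes_right} is given.
#' @param fiber_boxes_right Optional explicit right-hemisphere boxes.
#' @param region_tensors Named list with entries \code{projection},
#'   \code{association}, \code{subcortical}, \code{ventricle},
#'   \code{background}; each a length-3 diagonal (Dxx, Dyy, Dzz in mm^2/s).
#' @param s0 Baseline (b = 0) signal.
#' @param snr Signal-to-noise ratio s0/sigma; \code{Inf} means noiseless.
#' @param rotation_deg Optional angle (degrees) by which every fiber block's
#'   tensor is rotated about the axis following its own principal axis, to
#'   test robustness of eigenvector-based voxel selection.
#' @return An object of class \code{phantom_layout}.
#' @export
phantom_layout <- function(grid_shape = c(32L, 32L, 16L),
                           voxel_size = c(2, 2, 2.25),
                           brain = voxel_box(c(4, 4, 2), c(28, 28, 14)),
                           ventricle = voxel_box(c(14, 12, 6), c(18, 20, 10)),
                           fiber_boxes_left = list(
                             projection  = voxel_box(c(8, 10, 6), c(12, 14, 8)),
                             association = voxel_box(c(8, 14, 6), c(12, 18, 8)),
                             subcortical = voxel_box(c(8, 18, 6), c(12, 22, 8))),
                           fiber_boxes_right = NULL,
                           region_tensors = list(
                             projection  = c(0.00058, 0.00049, 0.00102),
                             association = c(0.00064, 0.00101, 0.00039),
                             subcortical = c(0.00108, 0.00068, 0.00060),
                             ventricle   = c(0.003, 0.003, 0.003),
                             background  = c(0.0008, 0.0008, 0.0008)),
                           s0 = 1000, snr = Inf, rotation_deg = 0) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0))
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)", call. = FALSE)
  if (!all(.fiber_types %in% names(fiber_boxes_left)))
    stop("fiber_boxes_left must name projection, association and subcortical boxes",
         call. = FALSE)
  if (is.null(fiber_boxes_right))
    fiber_boxes_right <- lapply(fiber_boxes_left, mirror_box_x, nx = grid_shape[1])
  need <- c(.fiber_types, "ventricle", "background")
  if (!all(need %in% names(region_tensors)))
    stop(sprintf("region_tensors must name: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  for (nm in need) {
    d <- region_tensors[[nm]]
    if (length(d) != 3L || any(!is.finite(d)) || any(d <= 0))
      stop(sprintf("region tensor '%s' must be three positive diffusivities", nm),
           call. = FALSE)
  }
  for (f in .fiber_types)
    if (which.max(region_tensors[[f]]) != .fiber_axis[[f]])
      stop(sprintf("%s fiber tensor must have its largest diffusivity along the %s axis",
                   f, c("x", "y", "z")[.fiber_axis[[f]]]), call. = FALSE)
  named_boxes <- c(list(ventricle = ventricle),
                   stats::setNames(fiber_boxes_left, paste0(.fiber_types, "_left")),
                   stats::setNames(fiber_boxes_right, paste0(.fiber_types, "_right")))
  full <- voxel_box(c(0, 0, 0), grid_shape)
  for (nm in names(named_boxes)) {
    if (!box_inside(named_boxes[[nm]], brain))
      stop(sprintf("region '%s' lies outside the brain box", nm), call. = FALSE)
  }
  if (!box_inside(brain, full))
    stop("brain box lies outside the grid", call. = FALSE)
  nms <- names(named_boxes)
  for (i in seq_along(named_boxes)) for (j in seq_len(i - 1L))
    if (boxes_overlap(named_boxes[[i]], named_boxes[[j]]))
      stop(sprintf("overlapping phantom regions: %s and %s", nms[j], nms[i]),
           call. = FALSE)
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be positive", call. = FALSE)
  if (is.na(snr) || snr <= 0) stop("snr must be positive (Inf = noiseless)", call. = FALSE)
  tens6 <- lapply(region_tensors, function(d) c(d, 0, 0, 0))
  if (rotation_deg != 0) {
    th <- rotation_deg * pi / 180
    for (f in .fiber_types) {
      ax <- .fiber_axis[[f]] %% 3L + 1L   # rotate about the next axis
      R <- rot_about_axis(ax, th)
      D <- tensor6_to_mat(tens6[[f]])
      tens6[[f]] <- mat_to_tensor6(R %*% D %*% t(R))
    }
  }
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 brain = brain, ventricle = ventricle,
                 fiber_boxes = list(left = fiber_boxes_left,
                                    right = fiber_boxes_right),
                 region_tensors = region_tensors, region_tensors6 = tens6,
                 s0 = s0, snr = snr, rotation_deg = rotation_deg),
            class = "phantom_layout")
}

.region_levels <- c("air", "background", "ventricle",
                    "projection_left", "association_left", "subcortical_left",
                    "projection_right", "association_right", "subcortical_right")

#' Ground truth of a phantom layout
#'
#' @param layout A \code{\link{phantom_layout}}.
#' @return A list of class \code{phantom_truth}: integer \code{label_map}
#'   (levels in \code{attr(, "levels")}), \code{tensors} (nx x ny x nz x 6
#'   array: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz; NA in air), and \code{true_alps}
#'   (per hemisphere and bilateral mean).
#' @export
build_truth <- function(layout) {
  stopifnot(inherits(layout, "phantom_layout"))
  gs <- layout$grid_shape
  lab <- array(1L, gs)                                   # air
  lab[box_mask(layout$brain, gs)] <- 2L                  # background tissue
  lab[box_mask(layout$ventricle, gs)] <- 3L
  k <- 4L
  for (h in c("left", "right")) {
    for (f in .fiber_types) {
      lab[box_mask(layout$fiber_boxes[[h]][[f]], gs)] <- k
      k <- k + 1L
    }
  }
  # reorder: levels above are air, background, ventricle, then left triplet, right triplet
  tens <- array(NA_real_, c(gs, 6L))
  region_of_label <- c(NA, "background", "ventricle",
                       "projection", "association", "subcortical",
                       "projection", "association", "subcortical")
  for (lev in 2:9) {
    sel <- lab == lev
    d6 <- layout$region_tensors6[[region_of_label[lev]]]
    for (c6 in 1:6) {
      slab <- tens[, , , c6]
      slab[sel] <- d6[c6]
      tens[, , , c6] <- slab
    }
  }
  attr(lab, "levels") <- .region_levels
  ta <- truth_alps(layout)
  structure(list(label_map = lab, tensors = tens, true_alps = ta,
                 layout = layout), class = "phantom_truth")
}

#' Predict the diffusion-weighted signal of a single tensor
#'
#' Single-tensor Stejskal-Tanner model: S = s0 * exp(-b g' D g).
#'
#' @param tensor_diag Either a length-3 diagonal (Dxx, Dyy, Dzz), a length-6
#'   vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), or a symmetric 3 x 3 matrix, in
#'   mm^2/s.
#' @param b b-value (s/mm^2).
#' @param g Gradient direction (unit vector when b > 0).
#' @param s0 Baseline signal.
#' @return The noise-free signal.
#' @export
predict_signal <- function(tensor_diag, b, g, s0 = 1) {
  if (is.matrix(tensor_diag)) D <- tensor_diag
  else if (length(tensor_diag) == 3L) D <- diag(as.numeric(tensor_diag))
  else if (length(tensor_diag) == 6L) D <- tensor6_to_mat(as.numeric(tensor_diag))
  else stop("tensor must be a 3-vector, 6-vector or 3x3 matrix", call. = FALSE)
  if (any(diag(D) < 0)) stop("negative diffusivity", call. = FALSE)
  if (b < 0) stop("b must be nonnegative", call. = FALSE)
  g <- as.numeric(g)
  if (b > 0 && abs(sqrt(sum(g^2)) - 1) > 1e-3)
    stop("gradient direction must be a unit vector when b > 0", call. = FALSE)
  as.numeric(s0 * exp(-b * drop(t(g) %*% D %*% g)))
}

#' Add Rician noise to magnitude signals
#'
#' The noisy magnitude is |S + n1 + i n2| with independent n1, n2 ~
#' Normal(0, sigma^2), the standard model for magnitude MRI.
#'
#' @param signal Numeric vector/array of noise-free magnitudes.
#' @param sigma Gaussian channel noise SD (same units as signal).
#' @param seed Optional integer seed; the call is deterministic given it.
#' @return Noisy magnitudes, same shape as \code{signal}.
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be nonnegative", call. = FALSE)
  if (sigma == 0) return(signal)
  if (!is.null(seed)) set.seed(seed)
  n <- length(signal)
  out <- sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

#' Default acquisition scheme: one b0 plus 32 directions at b = 1000
#'
#' Directions are spread over the sphere by a golden-angle (Fibonacci)
#' spiral, giving a well-conditioned tensor design.
#'
#' @param n_directions Number of diffusion-weighted directions.
#' @param bval Diffusion b-value (s/mm^2).
#' @param n_b0 Number of leading b = 0 volumes.
#' @return A \code{\link{gradient_scheme}} with \code{n_b0 + n_directions}
#'   volumes.
#' @export
default_gradient_scheme <- function(n_directions = 32L, bval = 1000, n_b0 = 1L) {
  i <- seq_len(n_directions) - 1L
  z <- 1 - (2 * i + 1) / n_directions
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  dirs <- cbind(r * cos(phi), r * sin(phi), z)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  gradient_scheme(c(rep(0, n_b0), rep(bval, n_directions)),
                  rbind(matrix(0, n_b0, 3), dirs))
}

#' Simulate a 4D diffusion-weighted series from a phantom layout
#'
#' Per voxel and volume, the noise-free signal follows the single-tensor
#' model; Rician noise with sigma = s0/snr is then applied independently per
#' measurement. Voxels outside the brain have zero underlying signal.
#'
#' @param layout A \code{\link{phantom_layout}}.
#' @param scheme A \code{\link{gradient_scheme}} (default: 1 b0 + 32
#'   directions at b = 1000).
#' @param seed Integer seed for the noise (ignored when noiseless).
#' @return A list of class \code{phantom_sim}: \code{dwi}
#'   (\code{\link{image_volume}}, 4D), \code{scheme}, \code{truth}
#'   (\code{\link{build_truth}} output) and \code{seed}.
#' @export
simulate_dwi <- function(layout, scheme = default_gradient_scheme(), seed = 1L) {
  stopifnot(inherits(layout, "phantom_layout"), inherits(scheme, "gradient_scheme"))
  truth <- build_truth(layout)
  gs <- layout$grid_shape
  nvox <- prod(gs)
  tmat <- matrix(truth$tensors, nvox, 6L)      # rows: voxels
  air <- is.na(tmat[, 1])
  tmat[air, ] <- 0
  g <- scheme$bvecs
  design <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                  2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  expo <- tmat %*% t(design * scheme$bvals)    # nvox x nvol, b * g'Dg
  sig <- layout$s0 * exp(-expo)
  sig[air, ] <- 0
  if (is.finite(layout$snr)) {
    sigma <- layout$s0 / layout$snr
    sig <- add_rician_noise(sig, sigma, seed = seed)
  }
  dwi <- image_volume(array(sig, c(gs, scheme$n_volumes)), layout$voxel_size)
  structure(list(dwi = dwi, scheme = scheme, truth = truth, seed = seed),
            class = "phantom_sim")
}

#' Ground-truth ALPS index of a layout
#'
#' Applies the ALPS ratio mean(Dxx_projection, Dxx_association) /
#' mean(Dyy_projection, Dzz_association) to the layout's region tensors.
#'
#' @param layout A \code{\link{phantom_layout}}.
#' @return List with \code{left}, \code{right} and \code{bilateral_mean}
#'   true ALPS values (identical unless hemispheres are customized).
#' @export
truth_alps <- function(layout) {
  stopifnot(inherits(layout, "phantom_layout"))
  t6 <- layout$region_tensors6
  num <- mean(c(t6$projection[1], t6$association[1]))
  den <- mean(c(t6$projection[2], t6$association[3]))
  if (den <= 0) stop("degenerate layout: ALPS denominator is not positive",
                     call. = FALSE)
  v <- num / den
  list(left = v, right = v, bilateral_mean = v)
}

#' Fiber-search ROI matching a phantom's own geometry
#'
#' @param layout A \code{\link{phantom_layout}}.
#' @return An \code{\link{roi_spec}} whose search boxes are the phantom's
#'   fiber blocks.
#' @export
default_roi_spec <- function(layout) {
  roi_spec(left = layout$fiber_boxes$left, right = layout$fiber_boxes$right)
}

#' Write a simulated phantom to disk
#'
#' Writes the 4D series as NIfTI, the scheme as FSL bval/bvec, and a JSON
#' truth sidecar (region boxes, region tensors, true ALPS, seed).
#'
#' @param sim Output of \code{\link{simulate_dwi}}.
#' @param dir Destination directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the four paths, invisibly.
#' @export
write_phantom <- function(sim, dir, prefix = "phantom") {
  stopifnot(inherits(sim, "phantom_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, prefix)
  write_volume(sim$dwi, paste0(p, ".nii.gz"))
  write_gradient_scheme(sim$scheme, paste0(p, ".bval"), paste0(p, ".bvec"))
  lay <- sim$truth$layout
  boxes <- c(list(brain = lay$brain, ventricle = lay$ventricle),
             stats::setNames(lay$fiber_boxes$left, paste0(.fiber_types, "_left")),
             stats::setNames(lay$fiber_boxes$right, paste0(.fiber_types, "_right")))
  sidecar <- list(
    grid_shape = lay$grid_shape, voxel_size = lay$voxel_size,
    region_boxes = lapply(boxes, function(b) list(lo = b$lo, hi = b$hi)),
    region_tensors = lay$region_tensors,
    s0 = lay$s0, snr = lay$snr,
    true_alps = sim$truth$true_alps, seed = sim$seed)
  jsonlite::write_json(sidecar, paste0(p, "_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(nii = paste0(p, ".nii.gz"), bval = paste0(p, ".bval"),
              bvec = paste0(p, ".bvec"), truth = paste0(p, "_truth.json")))
}
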