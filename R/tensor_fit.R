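# Voxelwise diffusion-tensor reconstruction by log-linear least squares,
# plus the brain-mask generation (threshold, smooth, defragment) that
# precedes it.

shift_array <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  xi <- sx - dx; yi <- sy - dy; zi <- sz - dz
  okx <- xi >= 1 & xi <= d[1]; oky <- yi >= 1 & yi <= d[2]; okz <- zi >= 1 & zi <= d[3]
  out[sx[okx], sy[oky], sz[okz]] <- a[xi[okx], yi[oky], zi[okz]]
  out
}

#' Majority filter of a binary 3D image
#'
#' A voxel is kept on when strictly more than half of the voxels in its
#' (2r+1)^3 cube neighborhood (image borders padded with background) are on.
#'
#' @param mask Logical 3D array.
#' @param radius Neighborhood radius in voxels; 0 returns the input.
#' @return Filtered logical array.
#' @export
majority_filter <- function(mask, radius = 1L) {
  if (radius < 1L) return(mask)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius, dz = -radius:radius)
  acc <- array(0L, dim(mask))
  m <- array(as.integer(mask), dim(mask))
  for (i in seq_len(nrow(offs)))
    acc <- acc + shift_array(m, offs$dx[i], offs$dy[i], offs$dz[i])
  acc > nrow(offs) / 2
}

.conn26 <- local({
  o <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(o[!(o$dx == 0 & o$dy == 0 & o$dz == 0), ])
})

#' Largest 26-connected component of a binary 3D image
#'
#' @param mask Logical 3D array.
#' @return Logical array keeping only the largest component (ties broken by
#'   lowest linear index of the component seed).
#' @export
largest_component <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nvox <- prod(d)
  idx_of <- function(v) v[1] + d[1] * (v[2] - 1L) + d[1] * d[2] * (v[3] - 1L)
  cur <- 0L
  sizes <- integer(0)
  todo <- which(mask)
  for (seed in todo) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    queue <- seed
    lab[seed] <- cur
    sz <- 0L
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      sz <- sz + 1L
      k <- v - 1L
      x <- k %% d[1] + 1L; k <- k %/% d[1]
      y <- k %% d[2] + 1L; z <- k %/% d[2] + 1L
      nb <- cbind(x + .conn26[, 1], y + .conn26[, 2], z + .conn26[, 3])
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      li <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      li <- li[mask[li] & lab[li] == 0L]
      if (length(li)) {
        lab[li] <- cur
        queue <- c(queue, li)
      }
    }
    sizes[cur] <- sz
  }
  if (cur == 0L) return(mask)
  lab == which.max(sizes)
}

#' Brain mask by thresholding, smoothing and defragmentation
#'
#' Thresholds the b = 0 image at a fraction of its robust maximum (99th
#' percentile), applies a binary majority filter, and keeps the largest
#' 26-connected component.
#'
#' @param b0_volume 3D array or \code{\link{image_volume}} of nonnegative
#'   intensities.
#' @param threshold_fraction Fraction of the 99th-percentile intensity below
#'   which voxels are background; 0 keeps every voxel.
#' @param smoothing_radius Majority-filter radius in voxels (0 = none).
#' @return Logical 3D array of class \code{brain_mask} with a
#'   \code{provenance} attribute (threshold fraction, smoothing radius, kept
#'   component size).
#' @export
compute_brain_mask <- function(b0_volume, threshold_fraction = 0.1,
                               smoothing_radius = 1L) {
  if (inherits(b0_volume, "image_volume")) b0_volume <- b0_volume$data
  stopifnot(length(dim(b0_volume)) == 3L)
  if (threshold_fraction < 0) stop("threshold_fraction must be >= 0", call. = FALSE)
  if (threshold_fraction == 0) {
    m <- array(TRUE, dim(b0_volume))
  } else {
    robust_max <- stats::quantile(b0_volume, 0.99, names = FALSE)
    m <- b0_volume > threshold_fraction * robust_max
    if (!any(m))
      stop("empty brain mask: no voxel exceeds the threshold", call. = FALSE)
    if (smoothing_radius >= 1L) {
      sm <- majority_filter(m, smoothing_radius)
      if (any(sm)) m <- sm     # never smooth a mask out of existence
    }
    m <- largest_component(m)
  }
  structure(m, class = c("brain_mask", class(m)),
            provenance = list(threshold_fraction = threshold_fraction,
                              smoothing_radius = smoothing_radius,
                              kept_component_size = sum(m)))
}

tensor_design <- function(scheme) {
  g <- scheme$bvecs
  -scheme$bvals * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                        2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                        2 * g[, 2] * g[, 3])
}

#' Fit the diffusion tensor in one voxel
#'
#' Ordinary least squares on the log signal ratio: ln(S/S0) =
#' -b (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz) . (Dxx, Dyy, Dzz, Dxy,
#' Dxz, Dyz), with S0 the mean of the b = 0 volumes. Exact on noiseless
#' single-tensor signals.
#'
#' @param signals Numeric vector, one signal per volume of \code{scheme}.
#' @param scheme A \code{\link{gradient_scheme}} with at least one b0 and six
#'   non-collinear diffusion directions.
#' @return Named length-6 tensor (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) in mm^2/s.
#' @export
fit_tensor_voxel <- function(signals, scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"),
            length(signals) == scheme$n_volumes)
  if (any(signals <= 0))
    stop("nonpositive signal: voxel cannot be fit", call. = FALSE)
  b0 <- scheme$bvals == 0
  s0 <- mean(signals[b0])
  X <- tensor_design(scheme)[!b0, , drop = FALSE]
  if (qr(X)$rank < 6L)
    stop("rank-deficient gradient design: need >= 6 independent directions",
         call. = FALSE)
  y <- log(signals[!b0] / s0)
  d <- qr.solve(X, y)
  names(d) <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  d
}

#' Fit diffusion tensors across a masked volume
#'
#' Applies the log-linear least-squares fit of \code{\link{fit_tensor_voxel}}
#' to every in-mask voxel (vectorized as a single multi-RHS solve), computes
#' the eigensystem, clamps negative eigenvalues to zero (flagging the voxel),
#' and derives FA and MD maps. Voxels with nonpositive signals are excluded
#' and flagged.
#'
#' @param dwi 4D \code{\link{image_volume}} (or array) matching
#'   \code{scheme}.
#' @param scheme A \code{\link{gradient_scheme}}.
#' @param mask Logical 3D array; default masks nothing.
#' @return An object of class \code{tensor_volume}: \code{tensor} (nx x ny x
#'   nz x 6), \code{evals} (... x 3, descending), \code{e1} (... x 3, unit
#'   principal eigenvector), \code{fa}, \code{md}, logical \code{clamped} and
#'   \code{excluded} maps, and the \code{mask}. Out-of-mask voxels are NA.
#' @export
fit_tensor_volume <- function(dwi, scheme, mask = NULL) {
  if (inherits(dwi, "image_volume")) dwi <- dwi$data
  stopifnot(length(dim(dwi)) == 4L, dim(dwi)[4] == scheme$n_volumes)
  gs <- dim(dwi)[1:3]
  if (is.null(mask)) mask <- array(TRUE, gs)
  stopifnot(all(dim(mask) == gs))
  b0 <- scheme$bvals == 0
  X <- tensor_design(scheme)[!b0, , drop = FALSE]
  if (qr(X)$rank < 6L)
    stop("rank-deficient gradient design: need >= 6 independent directions",
         call. = FALSE)
  nvox <- prod(gs)
  sig <- matrix(dwi, nvox, scheme$n_volumes)
  idx <- which(as.vector(mask))
  sig <- sig[idx, , drop = FALSE]
  pos <- rowSums(sig <= 0) == 0L
  excluded <- array(FALSE, gs); excluded[idx[!pos]] <- TRUE
  idx <- idx[pos]; sig <- sig[pos, , drop = FALSE]
  tensor <- array(NA_real_, c(gs, 6L))
  evals <- array(NA_real_, c(gs, 3L))
  e1 <- array(NA_real_, c(gs, 3L))
  fa <- array(NA_real_, gs); md <- array(NA_real_, gs)
  clamped <- array(FALSE, gs)
  if (length(idx)) {
    s0 <- rowMeans(sig[, b0, drop = FALSE])
    Y <- log(sig[, !b0, drop = FALSE] / s0)     # nvox x ndwi
    D <- t(qr.solve(X, t(Y)))                    # nvox x 6
    ev <- matrix(NA_real_, length(idx), 3L)
    v1 <- matrix(NA_real_, length(idx), 3L)
    cl <- logical(length(idx))
    for (i in seq_along(idx)) {
      es <- eigen(tensor6_to_mat(D[i, ]), symmetric = TRUE)
      lam <- es$values                           # descending
      if (lam[3] < 0) { lam <- pmax(lam, 0); cl[i] <- TRUE }
      ev[i, ] <- lam
      v1[i, ] <- es$vectors[, 1]
    }
    lbar <- rowMeans(ev)
    ss <- rowSums(ev^2)
    fav <- ifelse(ss > 0, sqrt(1.5 * rowSums((ev - lbar)^2) / ss), 0)
    for (c6 in 1:6) { a <- tensor[, , , c6]; a[idx] <- D[, c6]; tensor[, , , c6] <- a }
    for (c3 in 1:3) {
      a <- evals[, , , c3]; a[idx] <- ev[, c3]; evals[, , , c3] <- a
      a <- e1[, , , c3]; a[idx] <- v1[, c3]; e1[, , , c3] <- a
    }
    fa[idx] <- fav; md[idx] <- lbar; clamped[idx] <- cl
  }
  structure(list(tensor = tensor, evals = evals, e1 = e1, fa = fa, md = md,
                 clamped = clamped, excluded = excluded, mask = mask,
                 n_fitted = length(idx)),
            class = "tensor_volume")
}

#' FA and MD maps of a fitted tensor volume
#'
#' FA = sqrt(3/2) * sqrt(sum (lambda_i - mean)^2) / sqrt(sum lambda_i^2)
#' (0 for an all-zero tensor); MD = mean eigenvalue (mm^2/s).
#'
#' @param tensorvol A \code{\link{fit_tensor_volume}} result.
#' @return List with \code{fa} and \code{md} 3D arrays.
#' @export
scalar_maps <- function(tensorvol) {
  stopifnot(inherits(tensorvol, "tensor_volume"))
  list(fa = tensorvol$fa, md = tensorvol$md)
}
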