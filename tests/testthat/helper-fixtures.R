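# Shared fixtures: a desk-scale phantom layout, random SPD tensors, and a
# brute-force Mann-Whitney enumeration oracle.

small_layout <- function(snr = Inf, region_tensors = NULL, ...) {
  args <- list(
    grid_shape = c(20L, 20L, 10L),
    voxel_size = c(2, 2, 2.25),
    brain = voxel_box(c(2, 2, 1), c(18, 18, 9)),
    ventricle = voxel_box(c(8, 8, 3), c(12, 14, 7)),
    fiber_boxes_left = list(
      projection  = voxel_box(c(4, 6, 3),  c(7, 9, 5)),
      association = voxel_box(c(4, 9, 3),  c(7, 12, 5)),
      subcortical = voxel_box(c(4, 12, 3), c(7, 15, 5))),
    snr = snr)
  if (!is.null(region_tensors)) args$region_tensors <- region_tensors
  args <- utils::modifyList(args, list(...))
  do.call(phantom_layout, args)
}

# random diffusivities obeying the per-fiber principal-axis constraints
random_region_tensors <- function() {
  rd <- function(axis) {
    d <- stats::runif(3, 3e-4, 9e-4)
    d[axis] <- stats::runif(1, 1e-3, 2e-3)
    d
  }
  list(projection = rd(3), association = rd(2), subcortical = rd(1),
       ventricle = rep(stats::runif(1, 2e-3, 3.5e-3), 3),
       background = rep(stats::runif(1, 6e-4, 9e-4), 3))
}

random_spd_tensor <- function(scale = 1e-3) {
  A <- matrix(stats::rnorm(9), 3, 3)
  S <- crossprod(A) + diag(3) * 0.1
  S * scale / max(diag(S))
}

# two-sided Mann-Whitney p by full enumeration of group labelings,
# p = 2 * min(P(U <= u), P(U >= u)) capped at 1, on midranks
mw_enum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- utils::combn(n1 + n2, n1, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}
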