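# DTI-ALPS index: fiber-voxel selection within a periventricular ROI and the
# diffusivity ratio mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc).

#' Per-hemisphere fiber search ROI
#'
#' Rectangular search boxes (0-based, half-open voxel intervals) at the level
#' of the lateral-ventricle body, one per fiber type and hemisphere. The
#' fiber-axis map is fixed: projection fibers run along z
#' (superior-inferior), association along y (anterior-posterior), subcortical
#' along x (left-right).
#'
#' @param left,right Named lists with \code{projection}, \code{association}
#'   and \code{subcortical} \code{\link{voxel_box}} entries.
#' @return An object of class \code{roi_spec}.
#' @export
roi_spec <- function(left, right) {
  for (h in list(left, right)) {
    if (!all(.fiber_types %in% names(h)))
      stop("each hemisphere needs projection, association and subcortical boxes",
           call. = FALSE)
    for (f in .fiber_types)
      if (!inherits(h[[f]], "voxel_box"))
        stop(sprintf("'%s' search region must be a voxel_box", f), call. = FALSE)
  }
  structure(list(left = left[.fiber_types], right = right[.fiber_types],
                 fiber_axis = .fiber_axis),
            class = "roi_spec")
}

box_voxels <- function(box) {
  g <- expand.grid(x = box$lo[1]:(box$hi[1] - 1L),
                   y = box$lo[2]:(box$hi[2] - 1L),
                   z = box$lo[3]:(box$hi[3] - 1L))
  # lexicographic (x, then y, then z) scan order
  as.matrix(g[order(g$x, g$y, g$z), , drop = FALSE])
}

#' Select the best-aligned fiber voxel in a search box
#'
#' Returns the in-box voxel whose principal eigenvector has maximal absolute
#' component along the fiber's canonical axis ("maximum orientation"). Ties
#' are broken by lexicographic voxel order (x, then y, then z). Alternative
#' criterion \code{"diffusivity"} picks the voxel with maximal axis-aligned
#' diffusivity instead.
#'
#' @param tensorvol A \code{\link{fit_tensor_volume}} result.
#' @param box \code{\link{voxel_box}} search region (0-based, half-open).
#' @param fiber_axis 1 (x), 2 (y) or 3 (z), or one of "x", "y", "z".
#' @param criterion "eigenvector" (default) or "diffusivity".
#' @return List with \code{voxel} (0-based length-3 index),
#'   \code{diffusivities} (named Dxx, Dyy, Dzz in mm^2/s), \code{alignment}
#'   (the maximized |e1 . axis|), and \code{tie} (TRUE when the maximum was
#'   not unique).
#' @export
select_fiber_voxel <- function(tensorvol, box, fiber_axis,
                               criterion = c("eigenvector", "diffusivity")) {
  stopifnot(inherits(tensorvol, "tensor_volume"), inherits(box, "voxel_box"))
  criterion <- match.arg(criterion)
  if (is.character(fiber_axis)) fiber_axis <- match(fiber_axis, c("x", "y", "z"))
  stopifnot(fiber_axis %in% 1:3)
  gs <- dim(tensorvol$fa)
  if (any(box$lo < 0) || any(box$hi > gs))
    stop("search box extends outside the image grid", call. = FALSE)
  vox <- box_voxels(box)
  ijk <- vox + 1L
  score <- if (criterion == "eigenvector") {
    abs(tensorvol$e1[cbind(ijk, fiber_axis)])
  } else {
    tensorvol$tensor[cbind(ijk, fiber_axis)]   # Dxx/Dyy/Dzz are components 1:3
  }
  ok <- which(!is.na(score))
  if (!length(ok))
    stop("no fitted voxel inside the search box (all masked or excluded)",
         call. = FALSE)
  best <- ok[which.max(score[ok])]             # first maximizer in (x,y,z) order
  ties <- sum(score[ok] == score[best])
  dvox <- tensorvol$tensor[cbind(matrix(ijk[best, ], 3, 3, byrow = TRUE), 1:3)]
  names(dvox) <- c("Dxx", "Dyy", "Dzz")
  list(voxel = as.integer(unname(vox[best, ])), diffusivities = dvox,
       alignment = as.numeric(score[best]), tie = ties > 1L)
}

#' Compute the ALPS index from selected fiber diffusivities
#'
#' ALPS = mean(Dxx_projection, Dxx_association) /
#' mean(Dyy_projection, Dzz_association). Subcortical diffusivities, when
#' present, are carried through for reporting but never enter the ratio.
#'
#' @param d Named list with \code{projection} and \code{association} (each a
#'   named vector with Dxx, Dyy, Dzz), optionally \code{subcortical}.
#' @return List of class \code{alps_result} with \code{alps}, the four
#'   formula terms, and the input diffusivities.
#' @export
compute_alps <- function(d) {
  if (!all(c("projection", "association") %in% names(d)))
    stop("need projection and association diffusivities", call. = FALSE)
  gx <- function(v, nm) {
    x <- if (is.list(v)) v$diffusivities[[nm]] else v[[nm]]
    as.numeric(x)
  }
  terms <- c(Dxx_proj = gx(d$projection, "Dxx"),
             Dxx_assoc = gx(d$association, "Dxx"),
             Dyy_proj = gx(d$projection, "Dyy"),
             Dzz_assoc = gx(d$association, "Dzz"))
  if (any(!is.finite(terms)))
    stop("missing diffusivity term", call. = FALSE)
  if (any(terms <= 0))
    stop(sprintf("nonpositive diffusivity term(s): %s",
                 paste(names(terms)[terms <= 0], collapse = ", ")), call. = FALSE)
  den <- mean(terms[c("Dyy_proj", "Dzz_assoc")])
  structure(list(alps = mean(terms[c("Dxx_proj", "Dxx_assoc")]) / den,
                 terms = terms, diffusivities = d),
            class = "alps_result")
}

#' Full ALPS pipeline: mask, tensor fit, voxel selection, index
#'
#' Runs brain-mask generation, voxelwise tensor reconstruction, per-hemisphere
#' fiber-voxel selection and the ALPS ratio, with full provenance of the
#' selected voxels.
#'
#' @param dwi 4D \code{\link{image_volume}} or array.
#' @param scheme Matching \code{\link{gradient_scheme}}.
#' @param roi An \code{\link{roi_spec}}.
#' @param hemisphere_mode "bilateral_mean" (default), "left" or "right".
#' @param mask Optional precomputed logical mask; by default
#'   \code{\link{compute_brain_mask}} is run on the mean b0 with
#'   \code{threshold_fraction} and \code{smoothing_radius}.
#' @param threshold_fraction,smoothing_radius Mask parameters.
#' @param criterion Voxel-selection criterion, see
#'   \code{\link{select_fiber_voxel}}.
#' @return List of class \code{alps_pipeline_result}: \code{alps} (per the
#'   mode), \code{per_hemisphere} values, \code{hemispheres} (selection and
#'   diffusivity detail incl. subcortical), \code{mode}, \code{roi} and the
#'   fitted \code{tensor_volume}.
#' @export
alps_pipeline <- function(dwi, scheme, roi,
                          hemisphere_mode = c("bilateral_mean", "left", "right"),
                          mask = NULL, threshold_fraction = 0.1,
                          smoothing_radius = 1L,
                          criterion = c("eigenvector", "diffusivity")) {
  hemisphere_mode <- match.arg(hemisphere_mode)
  criterion <- match.arg(criterion)
  stopifnot(inherits(roi, "roi_spec"))
  if (inherits(dwi, "image_volume")) dwi <- dwi$data
  if (is.null(mask)) {
    b0 <- which(scheme$bvals == 0)
    b0vol <- apply(dwi[, , , b0, drop = FALSE], 1:3, mean)
    mask <- compute_brain_mask(b0vol, threshold_fraction, smoothing_radius)
  }
  tv <- fit_tensor_volume(dwi, scheme, mask)
  sides <- switch(hemisphere_mode, bilateral_mean = c("left", "right"),
                  left = "left", right = "right")
  hemis <- list()
  vals <- c()
  for (h in sides) {
    sel <- lapply(.fiber_types, function(f)
      select_fiber_voxel(tv, roi[[h]][[f]], .fiber_axis[[f]], criterion))
    names(sel) <- .fiber_types
    res <- compute_alps(sel)
    hemis[[h]] <- list(selection = sel, alps = res$alps, terms = res$terms)
    vals[h] <- res$alps
  }
  alps <- if (hemisphere_mode == "bilateral_mean") mean(vals) else unname(vals)
  structure(list(alps = alps, per_hemisphere = vals, hemispheres = hemis,
                 mode = hemisphere_mode, criterion = criterion, roi = roi,
                 tensor_volume = tv),
            class = "alps_pipeline_result")
}

#' @export
print.alps_pipeline_result <- function(x, ...) {
  cat(sprintf("DTI-ALPS index (%s): %.5f\n", x$mode, x$alps))
  if (length(x$per_hemisphere) > 1L)
    cat(sprintf("  left: %.5f  right: %.5f\n",
                x$per_hemisphere["left"], x$per_hemisphere["right"]))
  invisible(x)
}
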