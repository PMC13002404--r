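#' Construct a diffusion gradient scheme
#'
#' A gradient scheme pairs each volume of a 4D diffusion-weighted series with
#' its b-value (s/mm^2) and unit gradient direction. At least one b = 0 volume
#' is required so the tensor fit has a baseline signal; b = 0 rows may carry
#' the conventional zero vector.
#'
#' @param bvals Numeric vector of b-values, one per volume (s/mm^2).
#' @param bvecs Numeric matrix with one row per volume and three columns
#'   (x, y, z components). Rows with b > 0 must be unit vectors.
#' @return An object of class \code{gradient_scheme}: a list with elements
#'   \code{bvals}, \code{bvecs} (n x 3 matrix) and \code{n_volumes}.
#' @export
gradient_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  storage.mode(bvecs) <- "double"
  dimnames(bvecs) <- NULL
  if (ncol(bvecs) != 3L)
    stop("bvecs must have three columns (x, y, z)", call. = FALSE)
  if (length(bvals) != nrow(bvecs))
    stop(sprintf("gradient count mismatch: %d b-values vs %d directions",
                 length(bvals), nrow(bvecs)), call. = FALSE)
  if (any(!is.finite(bvals)) || any(!is.finite(bvecs)))
    stop("gradient scheme contains non-finite entries", call. = FALSE)
  if (any(bvals < 0))
    stop("b-values must be nonnegative", call. = FALSE)
  if (!any(bvals == 0))
    stop("gradient scheme needs at least one b = 0 volume", call. = FALSE)
  nrm <- sqrt(rowSums(bvecs^2))
  bad <- which(bvals > 0 & abs(nrm - 1) > 1e-3)
  if (length(bad))
    stop(sprintf("non-unit gradient direction at b > 0 volume(s): %s (norms %s)",
                 paste(bad, collapse = ", "),
                 paste(signif(nrm[bad], 4), collapse = ", ")), call. = FALSE)
  structure(list(bvals = bvals, bvecs = bvecs, n_volumes = length(bvals)),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("Gradient scheme: %d volumes (%d b0, %d diffusion-weighted), b = %s s/mm^2\n",
              x$n_volumes, sum(x$bvals == 0), sum(x$bvals > 0),
              paste(unique(x$bvals[x$bvals > 0]), collapse = "/")))
  invisible(x)
}

#' Read an FSL-style bval/bvec pair
#'
#' Reads whitespace-delimited gradient text files in the FSL convention
#' (b-values on one row; directions as three rows, one per axis). A
#' transposed, column-per-line variant is auto-detected from the array shape.
#'
#' @param bval_source,bvec_source Paths to the bval and bvec text files.
#' @return A validated \code{\link{gradient_scheme}}.
#' @export
read_gradient_scheme <- function(bval_source, bvec_source) {
  bvals <- scan(bval_source, what = double(), quiet = TRUE)
  lines <- readLines(bvec_source)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
  if (any(vapply(rows, anyNA, logical(1))))
    stop("non-numeric entry in bvec file", call. = FALSE)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("ragged bvec file: unequal row lengths", call. = FALSE)
  m <- do.call(rbind, rows)
  if (nrow(m) == 3L && ncol(m) != 3L) {
    m <- t(m)                      # FSL: 3 rows x n volumes
  } else if (ncol(m) == 3L) {
    # column-per-line variant: n rows x 3; keep as is
  } else if (nrow(m) == 3L && ncol(m) == 3L) {
    # ambiguous 3x3: FSL row convention assumed
    m <- t(m)
  } else {
    stop("bvec file is neither 3 x n nor n x 3", call. = FALSE)
  }
  if (length(bvals) != nrow(m))
    stop(sprintf("gradient count mismatch: %d b-values vs %d directions",
                 length(bvals), nrow(m)), call. = FALSE)
  gradient_scheme(bvals, m)
}

#' Write a gradient scheme as FSL-style bval/bvec files
#'
#' @param scheme A \code{\link{gradient_scheme}}.
#' @param bval_path,bvec_path Destination paths.
#' @return Invisibly, the two paths.
#' @export
write_gradient_scheme <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  writeLines(paste(format(scheme$bvals, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_path)
  writeLines(apply(t(scheme$bvecs), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Construct an image volume
#'
#' Voxel data are stored in scanner axes: x = left-right, y =
#' anterior-posterior, z = superior-inferior. Voxel indexing elsewhere in the
#' package is 0-based with half-open ROI intervals.
#'
#' @param data 3D or 4D numeric array.
#' @param voxel_size Length-3 numeric, voxel edge lengths in mm.
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(data, voxel_size = c(2, 2, 2.25)) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L))
    stop("image data must be a 3D or 4D array", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size,
                 axis_convention = "x=LR, y=AP, z=SI"),
            class = "image_volume")
}

#' Read a NIfTI-1 volume
#'
#' Images carrying a full spatial transform are reoriented to the nearest
#' canonical (RAS) axes on load, so that array axes match the scanner-axis
#' convention the ALPS computation assumes.
#'
#' @param path Path to a .nii or .nii.gz file.
#' @return An \code{\link{image_volume}}.
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("not a readable NIfTI file: %s (%s)",
                                                   path, conditionMessage(e)), call. = FALSE),
                  warning = function(w) stop(sprintf("not a readable NIfTI file: %s (%s)",
                                                     path, conditionMessage(w)), call. = FALSE))
  ort <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(ort) && nzchar(ort) && ort != "RAS")
    tryCatch(RNifti::orientation(img) <- "RAS", error = function(e) invisible(NULL))
  vs <- RNifti::pixdim(img)[seq_len(min(3L, length(RNifti::pixdim(img))))]
  if (length(vs) < 3L) vs <- c(vs, rep(1, 3L - length(vs)))
  dm <- dim(img)
  image_volume(array(as.numeric(img), dm), voxel_size = vs)
}

#' Write an image volume as NIfTI-1
#'
#' Data are written as float32; round-trips are exact to float32 precision.
#'
#' @param vol An \code{\link{image_volume}} (or bare array).
#' @param path Destination .nii or .nii.gz path.
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (!inherits(vol, "image_volume")) vol <- image_volume(vol)
  img <- RNifti::asNifti(vol$data)
  nd <- length(dim(vol$data))
  pd <- c(-1, vol$voxel_size, rep(1, 5 - 3))
  img$pixdim <- c(pd, rep(0, 8 - length(pd)))[1:8]
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

.cohort_required <- c("subject_id", "group", "alps")
.cohort_group_levels <- c("responder", "non_responder")
.cohort_logical <- c("eeg_discharges", "mri_abnormality", "na_blocker_prior", "male")

#' Read a cohort table from CSV
#'
#' Expects a comma-delimited file with header row containing at least
#' \code{subject_id}, \code{group} (\code{responder}/\code{non_responder})
#' and \code{alps}. Recognised clinical covariates (\code{age},
#' \code{age_onset}, \code{asm_burden}, \code{followup_months}, and the
#' booleans \code{eeg_discharges}, \code{mri_abnormality},
#' \code{na_blocker_prior}, \code{male}) are typed; unknown columns are
#' preserved as-is.
#'
#' @param path Path to the CSV file.
#' @return A \code{data.frame} of class \code{cohort_table}.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_cohort_table(df)
}

#' Validate (and type) a cohort table
#'
#' @param df A data.frame with cohort columns.
#' @return The typed \code{cohort_table}.
#' @export
validate_cohort_table <- function(df) {
  missing_cols <- setdiff(.cohort_required, names(df))
  if (length(missing_cols))
    stop(sprintf("cohort table is missing mandatory column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  if (nrow(df)) {
    alps <- suppressWarnings(as.numeric(df$alps))
    bad <- which(is.na(alps) & !is.na(df$alps))
    if (length(bad))
      stop(sprintf("non-numeric alps value in row(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    df$alps <- alps
    if (any(df$alps <= 0, na.rm = TRUE))
      stop("alps values must be positive", call. = FALSE)
    badg <- setdiff(unique(df$group), .cohort_group_levels)
    if (length(badg))
      stop(sprintf("unknown group label(s): %s", paste(badg, collapse = ", ")),
           call. = FALSE)
    for (cn in intersect(c("age", "age_onset", "asm_burden", "followup_months"),
                         names(df)))
      df[[cn]] <- as.numeric(df[[cn]])
    for (cn in intersect(.cohort_logical, names(df)))
      df[[cn]] <- as.logical(df[[cn]])
    if ("asm_burden" %in% names(df) && any(df$asm_burden < 2, na.rm = TRUE))
      stop("asm_burden must be >= 2 (drug resistance requires two failed trials)",
           call. = FALSE)
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table to CSV
#'
#' @param table A cohort \code{data.frame}.
#' @param path Destination CSV path.
#' @return The path, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
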