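# Gray-matter volume I/O and preprocessing: the in-memory cohort container,
# NIfTI-1 read/write, Gaussian smoothing by FWHM, and removal of nuisance
# covariates by voxelwise regression.

#' In-memory gray-matter cohort
#'
#' Holds a cohort of co-registered 3-D gray-matter maps as a voxels-by-
#' subjects matrix together with the shared grid, affine, and mask.
#' Voxel indices are 0-based in the affine convention: world (mm)
#' coordinates of voxel `(i,j,k)` (1-based R indices) are
#' `affine %*% c(i-1, j-1, k-1, 1)`.
#'
#' @param vols list of 3-D arrays (one per subject), or a voxels x subjects
#'   matrix.
#' @param mask logical 3-D array (same grid); must contain at least one
#'   `TRUE` voxel.
#' @param affine 4x4 voxel-to-world matrix (mm). Defaults to a centered
#'   grid at `voxel_size` spacing.
#' @param voxel_size numeric length-3, mm.
#' @param subject_ids character vector.
#' @return an object of class `gm_cohort`.
#' @export
gm_cohort <- function(vols, mask, affine = NULL, voxel_size = c(3, 3, 3),
                      subject_ids = NULL) {
  if (is.list(vols)) {
    dm <- dim(vols[[1]])
    for (v in vols)
      if (!identical(dim(v), dm))
        stop("volume grids differ: ", paste(dim(v), collapse = "x"),
             " vs ", paste(dm, collapse = "x"))
    data <- vapply(vols, as.numeric, numeric(prod(dm)))
  } else {
    data <- as.matrix(vols)
    dm <- dim(mask)
    if (nrow(data) != prod(dm)) stop("data rows do not match mask grid")
  }
  dm <- dim(mask)
  if (!is.logical(mask)) mask <- array(mask != 0, dm)
  if (!any(mask)) stop("mask has no in-mask voxel")
  if (is.null(affine)) affine <- .default_affine(dm, voxel_size)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%04d", seq_len(ncol(data)))
  structure(list(data = data, dim = dm, mask = mask, affine = affine,
                 voxel_size = abs(c(affine[1, 1], affine[2, 2], affine[3, 3])),
                 subject_ids = subject_ids),
            class = "gm_cohort")
}

.default_affine <- function(dm, voxel_size) {
  a <- diag(c(voxel_size, 1))
  a[1:3, 4] <- -voxel_size * (dm - 1) / 2
  a
}

#' @export
print.gm_cohort <- function(x, ...) {
  cat("gm_cohort:", length(x$subject_ids), "subjects on a",
      paste(x$dim, collapse = "x"), "grid,",
      sum(x$mask), "in-mask voxels,",
      paste(signif(x$voxel_size, 3), collapse = "x"), "mm voxels\n")
  invisible(x)
}

#' Extract one subject's volume as a 3-D array
#' @param cohort a [gm_cohort()].
#' @param i subject index or id.
#' @return a 3-D numeric array.
#' @export
cohort_volume <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$subject_ids)
  array(cohort$data[, i], cohort$dim)
}

#' Voxel-to-world coordinate mapping
#'
#' @param affine 4x4 voxel-to-world matrix with 0-based index convention.
#' @param ijk n x 3 matrix of 1-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  h <- cbind(ijk - 1, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

#' Read a cohort of NIfTI-1 gray-matter images
#'
#' Reads one image per subject plus a binary mask, validates that all
#' images share the grid and affine, and (when a symptom table is given)
#' orders subjects to match the table's `subject_id` column regardless of
#' the order of `paths`.
#'
#' @param paths character vector of NIfTI file paths, or a manifest
#'   `data.frame` with columns `subject_id` and `path`.
#' @param mask_path path of the binary mask image.
#' @param table optional `symptom_table`; when given, subject order follows
#'   the table and every table subject must be present.
#' @return a [gm_cohort()].
#' @export
read_gm_cohort <- function(paths, mask_path, table = NULL) {
  if (is.data.frame(paths)) {
    ids <- paths$subject_id
    paths <- paths$path
  } else {
    ids <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  }
  if (!is.null(table)) {
    m <- match(table$subject_id, ids)
    if (anyNA(m))
      stop("missing volume for subject(s): ",
           paste(table$subject_id[is.na(m)], collapse = ", "))
    paths <- paths[m]; ids <- ids[m]
  }
  mask_img <- RNifti::readNifti(mask_path)
  mask <- array(as.array(mask_img) != 0, dim(mask_img))
  affine <- structure(RNifti::xform(mask_img), class = NULL)
  vols <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    img <- RNifti::readNifti(paths[i])
    if (!identical(dim(img), dim(mask)))
      stop("grid mismatch: ", paths[i], " is ",
           paste(dim(img), collapse = "x"), " but mask is ",
           paste(dim(mask), collapse = "x"))
    if (max(abs(structure(RNifti::xform(img), class = NULL) - affine)) > 1e-4)
      stop("affine mismatch between ", paths[i], " and mask")
    vols[[i]] <- as.array(img)
  }
  gm_cohort(vols, mask, affine = affine, subject_ids = ids)
}

#' Write a cohort as NIfTI-1 files
#'
#' Writes one `.nii.gz` per subject plus `mask.nii.gz` and a manifest TSV
#' mapping `subject_id` to file path.
#'
#' @param cohort a [gm_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest `data.frame`, invisibly.
#' @export
write_gm_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(cohort$subject_ids, ".nii.gz"))
  for (i in seq_along(paths)) {
    img <- RNifti::asNifti(array(cohort$data[, i], cohort$dim))
    RNifti::qform(img) <- structure(cohort$affine, code = 2L)
    RNifti::writeNifti(img, paths[i])
  }
  mask_img <- RNifti::asNifti(array(as.numeric(cohort$mask), cohort$dim))
  RNifti::qform(mask_img) <- structure(cohort$affine, code = 2L)
  RNifti::writeNifti(mask_img, file.path(dir, "mask.nii.gz"))
  manifest <- data.frame(subject_id = cohort$subject_ids, path = paths,
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# 1-D truncated discrete Gaussian kernel (unit sum), sigma in voxels
.gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

# convolution along one axis of a 3-D array via a banded matrix product;
# zero boundary (kernel mass falling outside the grid is dropped)
.axis_conv <- function(arr, kern, axis) {
  if (length(kern) == 1) return(arr)
  dm <- dim(arr)
  n <- dm[axis]
  r <- (length(kern) - 1) / 2
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    B[i, j[ok]] <- kern[which(ok)]
  }
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  a <- B %*% matrix(a, n)
  a <- array(a, dm[perm])
  aperm(a, order(perm))
}

#' Gaussian smoothing by full-width-at-half-maximum
#'
#' Separable 3-D Gaussian smoothing with per-axis standard deviation
#' `sigma = fwhm / (2 sqrt(2 log 2))` expressed in mm and converted to
#' voxels using the grid spacing (anisotropic voxels supported). The
#' kernel is truncated at 4 sigma and normalized to unit sum, so total
#' image mass is conserved away from the grid boundary. `fwhm = 0` is the
#' identity.
#'
#' @param x 3-D array, or a [gm_cohort()] (every subject smoothed).
#' @param fwhm mm; scalar (isotropic) or length-3.
#' @param voxel_size mm per voxel along each axis (taken from the cohort
#'   when `x` is a `gm_cohort`).
#' @return object of the same type as `x`.
#' @export
gaussian_smooth_fwhm <- function(x, fwhm, voxel_size = c(1, 1, 1)) {
  if (any(fwhm < 0)) stop("fwhm must be non-negative")
  if (inherits(x, "gm_cohort")) {
    fw <- rep(fwhm, length.out = 3)
    for (i in seq_len(ncol(x$data)))
      x$data[, i] <- as.numeric(gaussian_smooth_fwhm(
        array(x$data[, i], x$dim), fw, x$voxel_size))
    return(x)
  }
  fw <- rep(fwhm, length.out = 3)
  sig <- fw / (2 * sqrt(2 * log(2))) / rep(voxel_size, length.out = 3)
  for (ax in 1:3) x <- .axis_conv(x, .gauss_kernel_1d(sig[ax]), ax)
  x
}

# builds the nuisance design matrix from a covariate data frame:
# intercept + numeric columns as-is + factors dummy-coded (reference level
# dropped)
.nuisance_design <- function(covs, n) {
  if (is.null(covs)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  covs <- as.data.frame(covs)
  if (nrow(covs) != n) stop("covariate rows (", nrow(covs),
                            ") do not match number of volumes (", n, ")")
  keep <- vapply(covs, function(z) !(is.factor(z) && nlevels(droplevels(z)) < 2),
                 logical(1))
  covs <- covs[, keep, drop = FALSE]
  for (j in seq_along(covs)) if (is.character(covs[[j]]))
    covs[[j]] <- factor(covs[[j]])
  for (j in seq_along(covs)) if (is.factor(covs[[j]]))
    covs[[j]] <- droplevels(covs[[j]])
  if (ncol(covs) == 0) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  model.matrix(~ ., data = covs)
}

#' Remove nuisance covariates from voxel data
#'
#' At every in-mask voxel, replaces the data by the residuals of the
#' regression on `intercept + covariates` (numeric covariates entered
#' linearly, categorical covariates dummy-coded with a dropped reference
#' level). Residuals are exactly orthogonal to the design columns and the
#' operation is idempotent.
#'
#' @param cohort a [gm_cohort()], or a subjects x features numeric matrix.
#' @param covs data frame of per-subject covariates aligned with the
#'   cohort (e.g. columns `age`, `site`); `NULL` means intercept only
#'   (mean-centering).
#' @return object of the same type with residualized values (out-of-mask
#'   voxels untouched for a cohort).
#' @export
residualize_covariates <- function(cohort, covs = NULL) {
  is_cohort <- inherits(cohort, "gm_cohort")
  Y <- if (is_cohort) t(cohort$data[cohort$mask, , drop = FALSE]) else as.matrix(cohort)
  X <- .nuisance_design(covs, nrow(Y))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("nuisance design is rank-deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  R <- qr.resid(qx, Y)
  if (!is_cohort) return(R)
  cohort$data[cohort$mask, ] <- t(R)
  cohort
}

#' Ellipsoidal analysis mask
#'
#' A binary mask of the lattice points inside the axis-aligned ellipsoid
#' inscribed in a fraction of the grid: a desk-scale stand-in for a
#' brain-shaped gray-matter mask.
#'
#' @param grid_shape integer length-3.
#' @param semi_frac semi-axes as a fraction of each half grid extent.
#' @return logical 3-D array.
#' @export
ellipsoid_mask <- function(grid_shape, semi_frac = 0.82) {
  ctr <- (grid_shape + 1) / 2
  semi <- pmax((grid_shape - 1) / 2 * semi_frac, 1)
  g <- expand.grid(i = seq_len(grid_shape[1]), j = seq_len(grid_shape[2]),
                   k = seq_len(grid_shape[3]))
  d <- ((g$i - ctr[1]) / semi[1])^2 + ((g$j - ctr[2]) / semi[2])^2 +
    ((g$k - ctr[3]) / semi[3])^2
  array(d <= 1, grid_shape)
}
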