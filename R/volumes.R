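#' BOLD run container
#'
#' A 4D BOLD acquisition on a voxel grid: the scalar field, the voxel-to-world
#' affine (mm) and the repetition time (s). This is the unit every temporal
#' operation in the package consumes.
#'
#' @param data numeric 4D array (x, y, z, t).
#' @param affine 4x4 voxel-to-world matrix (mm); voxel indices are 0-based in
#'   world mapping, following the NIfTI convention.
#' @param tr repetition time in seconds.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, affine = diag(4), tr = 1) {
  stopifnot(length(dim(data)) == 4L, tr > 0)
  check_affine(affine)
  structure(list(data = data, affine = affine, tr = tr), class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %d x %d x %d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' @param mask logical or 0/1 3D array on the same grid as the runs it will be
#'   applied to.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @param name label for the region.
#' @param hemisphere optional hemisphere tag ("left"/"right").
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, affine = diag(4), name = "roi", hemisphere = NULL) {
  stopifnot(length(dim(mask)) == 3L)
  check_affine(affine)
  structure(list(mask = array(as.logical(mask), dim(mask)), affine = affine,
                 name = name, hemisphere = hemisphere),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d voxels on a %s grid\n", x$name,
              sum(x$mask), paste(dim(x$mask), collapse = " x ")))
  invisible(x)
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix", call. = FALSE)
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("affine must be invertible", call. = FALSE)
  invisible(affine)
}

same_grid <- function(a, b, tol = 1e-6) {
  da <- if (inherits(a, "bold_run")) dim(a$data)[1:3] else dim(a$mask)
  db <- if (inherits(b, "bold_run")) dim(b$data)[1:3] else dim(b$mask)
  all(da == db) && max(abs(a$affine - b$affine)) < tol
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b))
    stop("incompatible grids: dimensions or affines differ", call. = FALSE)
  invisible(TRUE)
}

#' Read a NIfTI-1 volume as a BOLD run or ROI mask
#'
#' 4D images are returned as [bold_run()] (the repetition time is taken from
#' the NIfTI header unless overridden); 3D images as [roi_mask()].
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param tr repetition time override in seconds (4D only).
#' @param name region name for masks.
#' @return A `bold_run` or `roi_mask`.
#' @export
read_volume <- function(path, tr = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  attributes(aff) <- list(dim = c(4L, 4L))
  nd <- length(dim(img))
  if (nd == 4L) {
    if (is.null(tr)) {
      pd <- RNifti::pixdim(img)
      tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
    }
    bold_run(array(as.numeric(img), dim(img)), aff, tr)
  } else if (nd == 3L) {
    roi_mask(array(as.numeric(img) != 0, dim(img)), aff,
             name = name %||% sub("\\.nii(\\.gz)?$", "", basename(path)))
  } else {
    stop("expected a 3D mask or 4D run, got ", nd, " dimensions", call. = FALSE)
  }
}

#' Write a BOLD run or ROI mask as NIfTI-1
#'
#' Masks are written as unsigned 8-bit; runs as 32-bit float with the
#' repetition time in the header. Round-trips preserve data and affine to
#' float precision.
#'
#' @param x `bold_run` or `roi_mask`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "bold_run")) {
    vox <- sqrt(colSums(x$affine[1:3, 1:3]^2))
    hdr <- RNifti::niftiHeader(list(pixdim = c(-1, vox, x$tr, 0, 0, 0)))
    img <- RNifti::asNifti(x$data, hdr, datatype = "float")
    img <- RNifti::`sform<-`(img, structure(x$affine, code = 2L))
  } else if (inherits(x, "roi_mask")) {
    img <- RNifti::asNifti(array(as.integer(x$mask), dim(x$mask)),
                           datatype = "uint8")
    img <- RNifti::`sform<-`(img, structure(x$affine, code = 2L))
  } else {
    stop("x must be a bold_run or roi_mask", call. = FALSE)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' World coordinates of voxel centers
#'
#' @param ijk integer matrix of 0-based voxel indices (n x 3).
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- rbind(t(ijk), 1)
  t(affine %*% ijk)[, 1:3, drop = FALSE]
}

#' Spherical seed ROI from a world-space coordinate
#'
#' Places a closed-ball sphere (membership by Euclidean distance from the
#' voxel center to `center_mm` less than or equal to `radius_mm`) on the grid,
#' the standard construction for coordinate-table seed regions (4 mm radius
#' spheres on published MNI coordinates).
#'
#' @param dim grid dimensions (3 integers).
#' @param affine 4x4 voxel-to-world matrix.
#' @param center_mm world coordinate of the sphere center (mm).
#' @param radius_mm sphere radius (mm), > 0.
#' @param name region name.
#' @return A `roi_mask`.
#' @export
sphere_roi <- function(dim, affine, center_mm, radius_mm, name = "sphere") {
  stopifnot(radius_mm > 0, length(center_mm) == 3L)
  check_affine(affine)
  ijk <- as.matrix(expand.grid(i = 0:(dim[1] - 1), j = 0:(dim[2] - 1),
                               k = 0:(dim[3] - 1)))
  xyz <- voxel_to_world(ijk, affine)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
    (xyz[, 3] - center_mm[3])^2
  m <- array(d2 <= radius_mm^2 + 1e-9, dim)
  if (!any(m))
    stop("sphere center lies outside the field of view: empty mask",
         call. = FALSE)
  roi_mask(m, affine, name = name)
}

#' Split an ROI into anterior/posterior or medial/lateral halves
#'
#' Anterior-posterior: the split plane sits midway between the most anterior
#' and most posterior occupied coronal (y) slice; with an odd slice count the
#' middle slice joins the posterior half. Medial-lateral: computed per coronal
#' slice around that slice's in-ROI median column (x), approximating a
#' proximo-distal division; columns at the median join the lateral half, where
#' "lateral" is the direction of increasing |world x|.
#'
#' @param roi a `roi_mask` spanning at least 2 slices along the requested axis.
#' @param axis `"anterior-posterior"` or `"medial-lateral"`.
#' @return Named list of two disjoint `roi_mask` objects whose union is the
#'   input: `anterior`/`posterior` or `medial`/`lateral`.
#' @export
split_roi_axis <- function(roi, axis = c("anterior-posterior", "medial-lateral")) {
  axis <- match.arg(axis)
  stopifnot(inherits(roi, "roi_mask"))
  idx <- which(roi$mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty ROI", call. = FALSE)
  m1 <- array(FALSE, dim(roi$mask)); m2 <- m1
  if (axis == "anterior-posterior") {
    ys <- sort(unique(idx[, 2]))
    if (length(ys) < 2L) stop("ROI spans a single coronal slice: unsplittable",
                              call. = FALSE)
    # world y increases anteriorly under an MNI-like affine; use world coords
    yw <- voxel_to_world(cbind(0, ys - 1L, 0), roi$affine)[, 2]
    mid <- (min(yw) + max(yw)) / 2
    ant_slices <- ys[yw > mid + 1e-9]   # middle slice (yw == mid) -> posterior
    ant <- idx[, 2] %in% ant_slices
    m1[idx[ant, , drop = FALSE]] <- TRUE
    m2[idx[!ant, , drop = FALSE]] <- TRUE
    list(anterior  = roi_mask(m1, roi$affine, paste0(roi$name, "_anterior"),
                              roi$hemisphere),
         posterior = roi_mask(m2, roi$affine, paste0(roi$name, "_posterior"),
                              roi$hemisphere))
  } else {
    xs_all <- unique(idx[, 1])
    if (length(xs_all) < 2L) stop("ROI spans a single column: unsplittable",
                                  call. = FALSE)
    # split each coronal slice at its in-ROI median of world x; the lateral
    # side is the one with the larger mean |world x| for that ROI
    xw_all <- voxel_to_world(idx - 1L, roi$affine)[, 1]
    lateral_is_high <- mean(abs(xw_all[xw_all >= stats::median(xw_all)])) >=
      mean(abs(xw_all[xw_all <= stats::median(xw_all)]))
    for (y in unique(idx[, 2])) {
      sl <- idx[idx[, 2] == y, , drop = FALSE]
      xw <- voxel_to_world(sl - 1L, roi$affine)[, 1]
      med <- stats::median(xw)
      lat <- if (lateral_is_high) xw >= med - 1e-9 else xw <= med + 1e-9
      m2[sl[lat, , drop = FALSE]] <- TRUE
      m1[sl[!lat, , drop = FALSE]] <- TRUE
    }
    list(medial  = roi_mask(m1, roi$affine, paste0(roi$name, "_medial"),
                            roi$hemisphere),
         lateral = roi_mask(m2, roi$affine, paste0(roi$name, "_lateral"),
                            roi$hemisphere))
  }
}

#' Canonical voxel ordering of a mask
#'
#' Voxels are ordered lexicographically by (i, j, k), 1-based array indices,
#' which is R's column-major order of `which()`. All matrices with an
#' ROI-voxel dimension in this package use this order.
#'
#' @param mask a `roi_mask`.
#' @return Tibble with voxel indices `i`, `j`, `k` (1-based) and world
#'   coordinates `x`, `y`, `z` (mm), one row per in-mask voxel.
#' @export
mask_coordinates <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  ord <- order_mask_indices(mask$mask)
  xyz <- voxel_to_world(ord - 1L, mask$affine)
  tibble::tibble(i = ord[, 1], j = ord[, 2], k = ord[, 3],
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

order_mask_indices <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
}

#' Extract a time-by-voxel matrix from a run
#'
#' Columns follow the canonical voxel order of [mask_coordinates()], so the
#' same mask always yields the same column order regardless of how it was
#' stored.
#'
#' @param run a `bold_run`.
#' @param mask a `roi_mask` on the same grid.
#' @return Matrix of dimension volumes x in-mask voxels, with the coordinate
#'   tibble attached as attribute `"coordinates"`.
#' @export
extract_timeseries <- function(run, mask) {
  stopifnot(inherits(run, "bold_run"), inherits(mask, "roi_mask"))
  stop_if_grid_mismatch(run, mask)
  ord <- order_mask_indices(mask$mask)
  if (nrow(ord) == 0L) stop("empty ROI", call. = FALSE)
  d <- dim(run$data)
  flat <- matrix(run$data, prod(d[1:3]), d[4])
  lin <- ord[, 1] + d[1] * (ord[, 2] - 1L) + d[1] * d[2] * (ord[, 3] - 1L)
  out <- t(flat[lin, , drop = FALSE])
  attr(out, "coordinates") <- mask_coordinates(mask)
  out
}

#' Scatter per-voxel values back into a 3D volume
#'
#' Inverse of the spatial part of [extract_timeseries()]: values in canonical
#' voxel order are written into the mask, elsewhere `fill`.
#'
#' @param values numeric vector, one per in-mask voxel (canonical order).
#' @param mask a `roi_mask`.
#' @param fill value outside the mask.
#' @return 3D array on the mask grid.
#' @export
scatter_to_volume <- function(values, mask, fill = 0) {
  ord <- order_mask_indices(mask$mask)
  stopifnot(length(values) == nrow(ord))
  out <- array(fill, dim(mask$mask))
  out[ord] <- values
  out
}

#' @importFrom rlang %||%
NULL
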