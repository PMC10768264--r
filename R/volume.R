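#' Volumetric binary mask of a segmented nodule
#'
#' A `volume_mask` wraps a 3D 0/1 array with its anisotropic voxel spacing.
#' Array dimensions are ordered (x, y, z); physical coordinates are voxel
#' centres, `(index - 0.5) * spacing` in mm. The three orthogonal
#' reformation planes are: axial = (x, y) at fixed z, coronal = (x, z) at
#' fixed y, sagittal = (y, z) at fixed x.
#'
#' @param voxels 3D array coercible to 0/1 (logical or numeric).
#' @param spacing Length-3 positive numeric, mm per voxel along (x, y, z).
#' @return An object of class `volume_mask`.
#' @export
volume_mask <- function(voxels, spacing) {
  if (length(dim(voxels)) != 3) stop("`voxels` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive values (mm/voxel)", call. = FALSE)
  }
  v <- array(as.integer(voxels != 0), dim = dim(voxels))
  structure(list(voxels = v, spacing = spacing, axis_order = "xyz"),
            class = "volume_mask")
}

#' @export
print.volume_mask <- function(x, ...) {
  cat(sprintf("<volume_mask> %s voxels, spacing (%.3g, %.3g, %.3g) mm, %d foreground\n",
              paste(dim(x$voxels), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3], sum(x$voxels)))
  invisible(x)
}

#' Read a nodule mask from a NIfTI volume
#'
#' Voxel spacing is taken from the header (`pixdim`). Any nonzero voxel is
#' foreground.
#'
#' @param path Path to a NIfTI file (.nii or .nii.gz).
#' @return A [volume_mask()].
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  volume_mask(array(as.array(img) != 0, dim = dim(img)[1:3]), sp)
}

#' Write a mask to a NIfTI volume
#'
#' @param mask A [volume_mask()].
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  img <- RNifti::asNifti(mask$voxels)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 2D mask image (PNG/TIFF) as a one-slice volume
#'
#' Spacing is not stored in these formats and must be supplied.
#'
#' @param path Path to a PNG or TIFF image; any nonzero pixel is foreground.
#' @param spacing In-plane spacing, length 2 (mm/pixel); the slice thickness
#'   defaults to 1 mm.
#' @return A [volume_mask()] with a single axial slice.
#' @export
read_mask_image <- function(path, spacing) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(m)) == 3) m <- m[, , 1]
  # image rows are y (top-down); transpose to (x, y)
  m <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  volume_mask(array(m != 0, dim = c(dim(m), 1)), c(spacing[1], spacing[2], 1))
}

plane_slices <- function(mask) {
  v <- mask$voxels; sp <- mask$spacing
  list(
    axial    = list(margin = 3, inplane = c(1, 2), spacing = sp[c(1, 2)]),
    coronal  = list(margin = 2, inplane = c(1, 3), spacing = sp[c(1, 3)]),
    sagittal = list(margin = 1, inplane = c(2, 3), spacing = sp[c(2, 3)])
  )
}

get_slice <- function(voxels, plane, k) {
  switch(plane,
         axial    = voxels[, , k],
         coronal  = voxels[, k, ],
         sagittal = voxels[k, , ])
}

#' Extract the maximal cross-section of a lesion
#'
#' Scans every slice of the three orthogonal orientations (axial, coronal,
#' sagittal), scores each slice by its foreground area (voxel count times
#' the in-plane spacing product), and returns the boundary contour of the
#' largest connected foreground region in the winning slice. Ties between
#' planes resolve with precedence axial > coronal > sagittal. The boundary
#' is the marching-squares iso-contour of the binary slice at level 0.5
#' (sub-voxel vertices, voxel-centre coordinates in mm); of several closed
#' curves the one with the largest area is kept.
#'
#' A binary slice only locates the boundary to half a voxel, and that
#' staircase noise is what limits the chord and angle measurements; the
#' slice is therefore pre-smoothed with a small Gaussian (`sigma` in voxel
#' units) before the 0.5-level contour is taken. For a locally straight
#' boundary the smoothed indicator crosses 0.5 exactly on the true edge, so
#' the contour gains sub-voxel accuracy; `sigma = 0` recovers the raw
#' binary marching-squares boundary.
#'
#' @param mask A [volume_mask()].
#' @param sigma Gaussian pre-smoothing bandwidth in voxels (default 0.7;
#'   0 disables smoothing).
#' @return A [planar_contour()] with `plane` and `slice_index` set.
#' @export
extract_max_cross_section <- function(mask, sigma = 0.7) {
  stopifnot(inherits(mask, "volume_mask"))
  if (sum(mask$voxels) == 0) stop("no lesion: mask has no foreground voxels",
                                  call. = FALSE)
  planes <- plane_slices(mask)
  best <- list(area = -Inf)
  for (pl in names(planes)) {
    info <- planes[[pl]]
    counts <- apply(mask$voxels, info$margin, sum)
    k <- which.max(counts)
    area <- counts[k] * prod(info$spacing)
    if (area > best$area) {   # strict '>' keeps axial > coronal > sagittal
      best <- list(plane = pl, k = k, area = area, spacing = info$spacing)
    }
  }
  slice_contour(get_slice(mask$voxels, best$plane, best$k),
                best$spacing, best$plane, best$k, sigma = sigma)
}

# truncated discrete Gaussian, applied separably with zero (background)
# boundary handling
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  band <- function(n) {
    M <- matrix(0, n, n)
    for (d in -r:r) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1 & j <= n
      M[cbind(i[ok], j[ok])] <- k[d + r + 1L]
    }
    M
  }
  band(nrow(m)) %*% m %*% band(ncol(m))
}

# marching-squares boundary of the largest region in a (pre-smoothed)
# binary 2D slice
slice_contour <- function(m, spacing, plane, slice_index, sigma = 0.7) {
  m <- as.matrix(m)
  pw <- max(2L, ceiling(3 * sigma) + 1L)
  pad <- matrix(0, nrow(m) + 2 * pw, ncol(m) + 2 * pw)
  pad[pw + seq_len(nrow(m)), pw + seq_len(ncol(m))] <- m
  pad <- gauss_smooth(pad, sigma)
  # padded index pw + 1 is the first real voxel, centre 0.5 * spacing
  xs <- (seq_len(nrow(pad)) - pw - 0.5) * spacing[1]
  ys <- (seq_len(ncol(pad)) - pw - 0.5) * spacing[2]
  cl <- grDevices::contourLines(xs, ys, pad, levels = 0.5)
  if (length(cl) == 0) {
    stop("degenerate shape: no closed boundary found in maximal slice",
         call. = FALSE)
  }
  areas <- vapply(cl, function(p) abs(signed_area(cbind(p$x, p$y))), 0)
  p <- cl[[which.max(areas)]]
  v <- cbind(p$x, p$y)
  if (nrow(v) < 4 || max(areas) <= 0) {
    stop("degenerate shape: maximal cross-section has zero area", call. = FALSE)
  }
  planar_contour(v, plane, slice_index)
}
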