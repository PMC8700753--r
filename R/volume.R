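#' 3D image volume
#'
#' A scalar voxel grid with physical geometry: isotropic or anisotropic
#' spacing in mm, world origin, and a 3x3 direction matrix with orthonormal
#' columns. The world coordinate of 0-based voxel index (i, j, k) is
#' `origin + axes %*% (spacing * c(i, j, k))`. Internally all coordinates
#' are right-handed mm (RAS-style); DICOM's LPS convention is converted on
#' read.
#'
#' @param data 3D numeric array.
#' @param spacing mm per voxel along each array dimension (length 3, > 0).
#' @param origin world coordinate of voxel (0, 0, 0) in mm.
#' @param axes 3x3 direction matrix with orthonormal columns.
#' @param modality `"MRI"` or `"CT"`.
#' @return An object of class `cf_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         axes = diag(3), modality = c("MRI", "CT")) {
  modality <- match.arg(modality)
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L,
            length(origin) == 3L, all(dim(axes) == c(3L, 3L)))
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (max(abs(crossprod(axes) - diag(3))) > 1e-6)
    stop("direction matrix is not orthonormal")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), axes = axes,
                 modality = modality),
            class = "cf_volume")
}

#' @export
print.cf_volume <- function(x, ...) {
  cat(sprintf("<cf_volume> %s %s, spacing (%.3g, %.3g, %.3g) mm, range [%.3g, %.3g]\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.cf_volume <- function(x) dim(x$data)

#' Convert voxel indices to world coordinates
#'
#' @param volume a `cf_volume` or `cf_mask`.
#' @param ijk n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(volume, ijk) {
  ijk <- if (is.null(dim(ijk))) matrix(ijk, ncol = 3) else as.matrix(ijk)
  sw <- sweep(ijk, 2, volume$spacing, `*`)
  sw %*% t(volume$axes) +
    matrix(volume$origin, nrow(ijk), 3, byrow = TRUE)
}

#' Convert world coordinates to (fractional, 0-based) voxel indices
#'
#' @param volume a `cf_volume` or `cf_mask`.
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
world_to_voxel <- function(volume, xyz) {
  xyz <- if (is.null(dim(xyz))) matrix(xyz, ncol = 3) else as.matrix(xyz)
  p <- sweep(xyz, 2, volume$origin, `-`) %*% volume$axes
  sweep(p, 2, volume$spacing, `/`)
}

#' World coordinates of every voxel centre
#'
#' @param volume a `cf_volume` or `cf_mask`.
#' @param which optional logical/integer selector over the flattened grid.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_grid_world <- function(volume, which = NULL) {
  d <- dim(volume$data)
  if (is.null(which)) which <- seq_len(prod(d))
  if (is.logical(which)) which <- base::which(which)
  idx0 <- arrayInd(which, d) - 1L
  voxel_to_world(volume, idx0)
}

#' Binary label mask aligned to a parent volume
#'
#' Shares the parent grid geometry (shape, spacing, origin, axes) and tags
#' the tissue it labels. Stored as a 0/1 integer array.
#'
#' @param data 3D array coercible to 0/1.
#' @param parent the `cf_volume` the mask annotates (geometry source).
#' @param label tissue label: one of `"humerus"`, `"cartilage"`, `"ssb"`,
#'   `"sclerosis"`, `"lesion_footprint"`.
#' @return An object of class `cf_mask`.
#' @export
label_mask <- function(data, parent, label = c("humerus", "cartilage",
                       "ssb", "sclerosis", "lesion_footprint")) {
  label <- match.arg(label)
  data <- as.array(data)
  stopifnot(identical(dim(data), dim(parent$data)))
  storage.mode(data) <- "integer"
  data[data != 0L] <- 1L
  structure(list(data = data, spacing = parent$spacing,
                 origin = parent$origin, axes = parent$axes,
                 label = label),
            class = "cf_mask")
}

#' @export
print.cf_mask <- function(x, ...) {
  cat(sprintf("<cf_mask> '%s' %s, %d voxels set\n", x$label,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Dice overlap between two masks on the same grid
#' @param a,b `cf_mask` objects on identical grids.
#' @return Dice coefficient in [0, 1] (1 if both masks are empty).
#' @export
mask_dice <- function(a, b) {
  stopifnot(identical(dim(a$data), dim(b$data)))
  sa <- sum(a$data); sb <- sum(b$data)
  if (sa + sb == 0) return(1)
  2 * sum(a$data & b$data) / (sa + sb)
}

#' Label connected components of a mask
#'
#' @param mask a `cf_mask` (or 0/1 array).
#' @param connectivity 6, 18 or 26 (3D neighbourhood).
#' @return Integer array of component labels, 0 = background, labelled in
#'   scan order.
#' @export
connected_components <- function(mask, connectivity = 26) {
  arr <- if (inherits(mask, "cf_mask")) mask$data else as.array(mask)
  lab <- cf_label_components(as.integer(arr != 0), dim(arr),
                             as.integer(connectivity))
  array(lab, dim(arr))
}

#' Ordered, named landmark set
#'
#' Landmarks are corresponding anatomical points picked in one frame
#' (MRI or CT), matched to the other frame by order and name; at least
#' three non-collinear points are needed for rigid registration.
#'
#' @param points n x 3 matrix of world mm coordinates.
#' @param names character vector of unique landmark names.
#' @param frame `"MRI"` or `"CT"`.
#' @return An object of class `cf_landmarks`.
#' @export
landmark_set <- function(points, names = NULL, frame = c("MRI", "CT")) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L)
  if (nrow(points) < 3L) stop("at least 3 landmarks required")
  if (is.null(names)) names <- paste0("P", seq_len(nrow(points)))
  if (anyDuplicated(names)) stop("landmark names must be unique")
  if (landmarks_collinear(points)) stop("landmarks are collinear")
  rownames(points) <- names
  structure(list(points = points, frame = frame), class = "cf_landmarks")
}

landmarks_collinear <- function(points, tol = 1e-8) {
  c0 <- scale(points, scale = FALSE)
  sv <- svd(c0)$d
  sv[2] <= tol * max(sv[1], 1)
}

#' @export
print.cf_landmarks <- function(x, ...) {
  cat(sprintf("<cf_landmarks> %d points in %s frame: %s\n",
              nrow(x$points), x$frame,
              paste(rownames(x$points), collapse = ", ")))
  invisible(x)
}
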