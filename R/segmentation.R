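#' Threshold specification for tissue segmentation
#'
#' Intensity window plus post-processing: connected components smaller
#' than `min_volume_mm3` (under the given 3D connectivity) are removed.
#' Thresholds are explicit, configurable criteria standing in for the
#' operator-adjusted windows of interactive segmentation.
#'
#' @param lower,upper intensity bounds (lower < upper).
#' @param connectivity 6, 18 or 26.
#' @param min_volume_mm3 minimum component volume to keep.
#' @return An object of class `cf_threshold`.
#' @export
threshold_spec <- function(lower, upper, connectivity = 26,
                           min_volume_mm3 = 0) {
  if (!(lower < upper)) stop("lower must be < upper")
  if (min_volume_mm3 < 0) stop("min_volume_mm3 must be >= 0")
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  structure(list(lower = lower, upper = upper,
                 connectivity = connectivity,
                 min_volume_mm3 = min_volume_mm3),
            class = "cf_threshold")
}

#' Threshold segmentation of one tissue
#'
#' Selects voxels inside the intensity window, then removes connected
#' components below the minimum volume. An empty result is returned with
#' a warning, not an error: the caller decides whether that is a problem.
#'
#' @param volume a `cf_volume`.
#' @param spec a [threshold_spec()].
#' @param tissue label for the resulting mask.
#' @return A [label_mask()].
#' @export
segment_by_threshold <- function(volume, spec, tissue = "humerus") {
  stopifnot(inherits(volume, "cf_volume"), inherits(spec, "cf_threshold"))
  m <- volume$data >= spec$lower & volume$data <= spec$upper
  if (any(m) && spec$min_volume_mm3 > 0) {
    lab <- connected_components(array(as.integer(m), dim(volume$data)),
                                spec$connectivity)
    sizes <- tabulate(lab[lab > 0])
    vox_mm3 <- prod(volume$spacing)
    keep <- which(sizes * vox_mm3 >= spec$min_volume_mm3)
    m <- array(lab %in% keep, dim(volume$data))
  }
  if (!any(m))
    warning("threshold segmentation produced an empty mask for tissue '",
            tissue, "'")
  label_mask(array(as.integer(m), dim(volume$data)), volume, tissue)
}

# ---- shared geometry helpers ---------------------------------------------

# algebraic least-squares sphere fit; 2 trimming rounds against outliers
fit_sphere <- function(points, trim_rounds = 2) {
  pts <- as.matrix(points)
  if (nrow(pts) < 10) stop("too few points for a sphere fit")
  fit1 <- function(p) {
    A <- cbind(2 * p, 1)
    b <- rowSums(p^2)
    coef <- tryCatch(qr.solve(A, b),
                     error = function(e) stop("degenerate sphere fit: ",
                                              conditionMessage(e)))
    centre <- coef[1:3]
    R <- sqrt(coef[4] + sum(centre^2))
    list(centre = centre, radius = R)
  }
  f <- fit1(pts)
  for (i in seq_len(trim_rounds)) {
    resid <- sqrt(rowSums(sweep(pts, 2, f$centre)^2)) - f$radius
    s <- stats::mad(resid)
    keep <- abs(resid - stats::median(resid)) <= max(3 * s, 0.3)
    if (sum(keep) < 10) break
    f <- fit1(pts[keep, , drop = FALSE])
  }
  f
}

# Bin cartilage voxels by radial direction (AP-projected, relative to a
# fitted cap centre). Returns per-bin outer/inner radius and thickness.
cap_direction_bins <- function(points, centre, frame, bin_mm = 0.6,
                               radius_ref = NULL) {
  points <- as.matrix(points)
  rel <- sweep(points, 2, centre)
  r <- sqrt(rowSums(rel^2))
  d <- rel / pmax(r, 1e-9)
  if (is.null(radius_ref)) radius_ref <- stats::median(r)
  u <- as.numeric(d %*% frame$ml) * radius_ref
  v <- as.numeric(d %*% frame$pd) * radius_ref
  iu <- round(u / bin_mm); iv <- round(v / bin_mm)
  key <- paste(iu, iv)
  idx <- split(seq_along(r), key)
  bins <- do.call(rbind, lapply(idx, function(i)
    c(iu = iu[i[1]], iv = iv[i[1]],
      r_out = max(r[i]), r_in = min(r[i]), n = length(i))))
  bins <- as.data.frame(bins)
  bins$u <- bins$iu * bin_mm; bins$v <- bins$iv * bin_mm
  list(bins = bins, bin_mm = bin_mm, radius_ref = radius_ref,
       centre = centre, points = points, r = r, d = d, u = u, v = v,
       key = key)
}

# connected components over integer 2D bin coordinates (8-connectivity)
bin_components <- function(iu, iv) {
  if (length(iu) == 0) return(integer(0))
  ou <- iu - min(iu) + 1L; ov <- iv - min(iv) + 1L
  n1 <- max(ou); n2 <- max(ov)
  m <- array(0L, c(n1, n2, 1L))
  m[cbind(ou, ov, 1L)] <- 1L
  lab <- connected_components(m, 26)
  lab[cbind(ou, ov, 1L)]
}

bin_points_world <- function(bins, centre, frame, radius) {
  # reconstruct a representative surface point per bin
  w2 <- pmax(radius^2 - bins$u^2 - bins$v^2, 0)
  p_local <- cbind(bins$u, bins$v, sqrt(w2))
  B <- cbind(frame$ml, frame$pd, frame$ap)
  sweep(p_local %*% t(B), 2, centre, `+`)
}

# Boundary voxels of the cartilage shell, split into the articular
# (outer) and bone-side (inner) surface by radius about the cap centre
# (the anatomical-frame origin), using the mid-shell radius as divider.
cartilage_boundaries <- function(cartilage, centre) {
  arr <- cartilage$data
  er <- array(cf_box_morph(as.integer(arr), dim(arr), 1L, FALSE), dim(arr))
  all_r <- sqrt(rowSums(sweep(voxel_grid_world(cartilage, arr == 1L),
                              2, centre)^2))
  mid <- stats::median(all_r)
  bpts <- voxel_grid_world(cartilage, arr == 1L & er == 0L)
  r <- sqrt(rowSums(sweep(bpts, 2, centre)^2))
  list(outer = bpts[r > mid, , drop = FALSE],
       inner = bpts[r <= mid, , drop = FALSE])
}

# Reference sphere for the articular surface. Fitting both centre and
# radius of a sphere to a partial cap is ill-conditioned (centre depth
# and radius trade off, and a deformity drags the fit), so the centre
# is anchored at the anatomical-frame origin -- the capitellar centre
# the frame is defined by -- and only the reference radius is
# estimated, as the median radius of the outer boundary voxels. The
# median is robust as long as less than half of the cap is deformed.
cap_reference_sphere <- function(cartilage, frame) {
  centre <- frame$origin
  b <- cartilage_boundaries(cartilage, centre)
  if (nrow(b$inner) < 10 || nrow(b$outer) < 10)
    stop("degenerate cartilage boundary: cannot fit a reference surface")
  r_out <- sqrt(rowSums(sweep(b$outer, 2, centre)^2))
  r_in <- sqrt(rowSums(sweep(b$inner, 2, centre)^2))
  list(centre = centre, radius = stats::median(r_out),
       inner_radius = stats::median(r_in))
}

# ---- detectors -----------------------------------------------------------

#' Detect articular cartilage fissures (ACF)
#'
#' An ACF is a connected low-intensity component inside the cartilage
#' layer whose principal axis is within `angle_tol` of the local outer
#' surface normal, or which spans at least `span_frac` of the local
#' cartilage thickness; components failing both criteria (e.g. a
#' sub-surface slab parallel to the articular surface) are not fissures.
#' The cartilage layer is recovered by morphological closing of the
#' cartilage mask, so the low-signal gap of the fissure itself is
#' searched.
#'
#' @param cartilage cartilage [label_mask()].
#' @param mri the MRI `cf_volume` the mask was segmented from.
#' @param frame a [anatomical_frame()].
#' @param low_intensity upper intensity bound for fissure voxels.
#' @param angle_tol degrees between principal axis and surface normal.
#' @param span_frac minimum radial span as a fraction of local thickness.
#' @param min_voxels minimum component size.
#' @return List of ACF [finding()] objects.
#' @export
detect_fissures <- function(cartilage, mri, frame, low_intensity = 50,
                            angle_tol = 30, span_frac = 0.8,
                            min_voxels = 8) {
  stopifnot(inherits(cartilage, "cf_mask"), inherits(mri, "cf_volume"))
  if (!any(cartilage$data)) stop("cartilage mask is empty")
  arr <- cartilage$data
  closed0 <- cf_box_morph(as.integer(arr), dim(arr), 2L, TRUE)
  closed <- array(cf_box_morph(closed0, dim(arr), 2L, FALSE), dim(arr))
  cand <- closed == 1L & arr == 0L & mri$data <= low_intensity
  if (!any(cand)) return(list())
  sph <- cap_reference_sphere(cartilage, frame)
  cb <- cap_direction_bins(voxel_grid_world(cartilage, arr == 1L),
                           sph$centre, frame)
  lab <- connected_components(array(as.integer(cand), dim(arr)), 26)
  out <- list()
  for (l in seq_len(max(lab))) {
    sel <- lab == l
    if (sum(sel) < min_voxels) next
    pts <- voxel_grid_world(cartilage, sel)
    rel <- sweep(pts, 2, sph$centre)
    r <- sqrt(rowSums(rel^2))
    nrm <- colMeans(rel / r)
    nrm <- nrm / sqrt(sum(nrm^2))
    pc <- svd(scale(pts, scale = FALSE))$v[, 1]
    angle <- acos(min(1, abs(sum(pc * nrm)))) * 180 / pi
    span <- max(r) - min(r) + mean(cartilage$spacing)
    thick <- local_thickness_at(cb, pts, sph, frame)
    if (angle <= angle_tol || (thick > 0 && span / thick >= span_frac))
      out <- c(out, list(finding("ACF", points = pts)))
  }
  out
}

local_thickness_at <- function(cb, pts, sph, frame) {
  rel <- sweep(as.matrix(pts), 2, sph$centre)
  d <- rel / sqrt(rowSums(rel^2))
  u <- mean(as.numeric(d %*% frame$ml) * cb$radius_ref)
  v <- mean(as.numeric(d %*% frame$pd) * cb$radius_ref)
  b <- cb$bins
  near <- sqrt((b$u - u)^2 + (b$v - v)^2) <= 1.5
  if (!any(near)) return(0)
  stats::median(b$r_out[near] - b$r_in[near]) + cb$bin_mm / 2
}

#' Detect articular surface deformities (ASD)
#'
#' Fits a reference sphere to the outer cartilage boundary of the
#' capitellar cap (with trimming so the deformity itself does not drag
#' the fit) and flags contiguous patches whose signed radial residual
#' exceeds `+h_tol` (protrusion) or falls below `-h_tol` (flattening).
#' Patches thinner than `thickness_min` are left to the defect detector.
#'
#' @param cartilage cartilage [label_mask()].
#' @param frame a [anatomical_frame()].
#' @param h_tol residual threshold in mm.
#' @param area_min minimum patch area in the AP projection, mm^2.
#' @param thickness_min cartilage thinner than this is defect territory.
#' @return List of ASD [finding()] objects.
#' @export
detect_surface_deformity <- function(cartilage, frame, h_tol = 0.5,
                                     area_min = 10, thickness_min = 0.5) {
  stopifnot(inherits(cartilage, "cf_mask"))
  if (!any(cartilage$data)) stop("cartilage mask is empty")
  sph <- cap_reference_sphere(cartilage, frame)
  cb <- cap_direction_bins(voxel_grid_world(cartilage,
                                            cartilage$data == 1L),
                           sph$centre, frame, radius_ref = sph$radius)
  b <- cb$bins
  vox <- mean(cartilage$spacing)
  thick <- b$r_out - b$r_in + vox
  resid <- b$r_out - sph$radius
  eligible <- thick >= thickness_min
  bin_key <- paste(b$iu, b$iv)
  out <- list()
  for (side in c("protrusion", "flattening")) {
    sel <- eligible & (if (side == "protrusion") resid > h_tol
                       else resid < -h_tol)
    if (!any(sel)) next
    comp <- bin_components(b$iu[sel], b$iv[sel])
    for (l in unique(comp)) {
      rows <- which(sel)[comp == l]
      area <- length(rows) * cb$bin_mm^2
      if (area < area_min) next
      # voxel-level footprint: outermost-shell voxels of the patch bins,
      # so diameters measured on the finding keep sub-bin accuracy
      keys <- bin_key[rows]
      vsel <- cb$key %in% keys
      r_out_of <- b$r_out[match(cb$key, bin_key)]
      shell <- vsel & cb$r >= r_out_of - vox
      pts <- cb$points[shell, , drop = FALSE]
      if (nrow(pts) == 0)
        pts <- bin_points_world(b[rows, ], sph$centre, frame, sph$radius)
      out <- c(out, list(finding("ASD", points = pts,
                                 asd_subtype = side)))
    }
  }
  out
}

#' Detect articular cartilage defects (ACD)
#'
#' Regions of the capitellar cap where cartilage is absent or thinner
#' than `thickness_min` over at least `area_min` of AP-projected area.
#' The cap support is taken as the convex hull (in the AP projection) of
#' directions that do carry cartilage, so a crater inside the cap is
#' found without knowing the cap extent a priori.
#'
#' @param cartilage cartilage [label_mask()].
#' @param frame a [anatomical_frame()].
#' @param thickness_min mm; thinner counts as defect.
#' @param area_min minimum defect area, mm^2.
#' @return List of ACD [finding()] objects.
#' @export
detect_cartilage_defect <- function(cartilage, frame, thickness_min = 0.5,
                                    area_min = 5) {
  stopifnot(inherits(cartilage, "cf_mask"))
  if (!any(cartilage$data)) stop("cartilage mask is empty")
  sph <- cap_reference_sphere(cartilage, frame)
  cb <- cap_direction_bins(voxel_grid_world(cartilage,
                                            cartilage$data == 1L),
                           sph$centre, frame, radius_ref = sph$radius)
  b <- cb$bins
  vox <- mean(cartilage$spacing)
  # candidate grid: all bins inside the convex hull of occupied bins
  hull <- grDevices::chull(b$u, b$v)
  hx <- b$u[hull]; hy <- b$v[hull]
  urange <- range(b$iu); vrange <- range(b$iv)
  grid <- expand.grid(iu = urange[1]:urange[2], iv = vrange[1]:vrange[2])
  gu <- grid$iu * cb$bin_mm; gv <- grid$iv * cb$bin_mm
  inside <- point_in_polygon(gu, gv, hx, hy, shrink = 0.99)
  key_b <- paste(b$iu, b$iv)
  key_g <- paste(grid$iu, grid$iv)
  thick <- rep(0, nrow(grid))
  mi <- match(key_g, key_b)
  has <- !is.na(mi)
  thick[has] <- b$r_out[mi[has]] - b$r_in[mi[has]] + vox
  sel <- inside & thick < thickness_min
  if (!any(sel)) return(list())
  comp <- bin_components(grid$iu[sel], grid$iv[sel])
  out <- list()
  for (l in unique(comp)) {
    rows <- which(sel)[comp == l]
    area <- length(rows) * cb$bin_mm^2
    if (area < area_min) next
    bb <- data.frame(u = gu[rows], v = gv[rows])
    pts <- bin_points_world(bb, sph$centre, frame, sph$radius)
    out <- c(out, list(finding("ACD", points = pts)))
  }
  out
}

# even-odd ray test, polygon optionally shrunk toward its centroid
point_in_polygon <- function(px, py, vx, vy, shrink = 1) {
  cx <- mean(vx); cy <- mean(vy)
  vx <- cx + (vx - cx) * shrink
  vy <- cy + (vy - cy) * shrink
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

#' Detect segmented subchondral bone (SSB)
#'
#' A candidate fragment is a 3D connected component of the bone mask
#' (26-connectivity) disjoint from the largest component. It qualifies as
#' SSB only when its discontinuity from the parent bone holds in *all
#' three orthogonal planes*: in every axial, sagittal and coronal slice
#' the fragment occupies, it must be 2D-disconnected (8-connectivity)
#' from the main bone in that slice. A fragment bridged to the floor in
#' any plane is rejected.
#'
#' @param bone bone [label_mask()].
#' @param min_voxels minimum fragment size considered.
#' @return A `ssb` [label_mask()] (empty when no fragment qualifies).
#' @export
detect_ssb <- function(bone, min_voxels = 20) {
  stopifnot(inherits(bone, "cf_mask"))
  if (!any(bone$data)) stop("bone mask is empty")
  arr <- bone$data
  d <- dim(arr)
  lab <- connected_components(arr, 26)
  sizes <- tabulate(lab[lab > 0])
  main <- which.max(sizes)
  accept <- array(0L, d)
  for (l in setdiff(which(sizes >= min_voxels), main)) {
    frag <- lab == l
    ok <- TRUE
    for (axis in 1:3) {
      occupied <- which(apply(frag, axis, any))
      for (s in occupied) {
        sl_frag <- slice_of(frag, axis, s)
        sl_main <- slice_of(lab == main, axis, s)
        if (!any(sl_main)) next
        both <- array(as.integer(sl_frag | sl_main),
                      c(dim(sl_frag), 1L))
        l2 <- connected_components(both, 26)
        if (any(l2[array(sl_frag, dim(both))] %in%
                unique(l2[array(sl_main, dim(both))]))) {
          ok <- FALSE
          break
        }
      }
      if (!ok) break
    }
    if (ok) accept[frag] <- 1L
  }
  structure(list(data = accept, spacing = bone$spacing,
                 origin = bone$origin, axes = bone$axes, label = "ssb"),
            class = "cf_mask")
}

slice_of <- function(arr, axis, s) {
  switch(axis, arr[s, , ], arr[, s, ], arr[, , s])
}

#' Highlight subchondral sclerosis on CT
#'
#' Bone voxels whose CT intensity exceeds the given percentile of the
#' bone intensity distribution; only the largest connected component is
#' retained (isolated noise voxels above the percentile are dropped).
#'
#' @param ct CT `cf_volume`.
#' @param bone bone [label_mask()].
#' @param percentile percentile of the bone intensity distribution.
#' @return A `sclerosis` [label_mask()].
#' @export
highlight_sclerosis <- function(ct, bone, percentile = 90) {
  stopifnot(inherits(ct, "cf_volume"), inherits(bone, "cf_mask"))
  if (!any(bone$data)) stop("bone mask is empty")
  vals <- ct$data[bone$data == 1L]
  thr <- stats::quantile(vals, percentile / 100, names = FALSE)
  m <- bone$data == 1L & ct$data > thr
  out <- array(0L, dim(ct$data))
  if (any(m)) {
    lab <- connected_components(array(as.integer(m), dim(ct$data)), 26)
    sizes <- tabulate(lab[lab > 0])
    if (length(sizes)) out[lab == which.max(sizes)] <- 1L
  }
  structure(list(data = out, spacing = bone$spacing, origin = bone$origin,
                 axes = bone$axes, label = "sclerosis"),
            class = "cf_mask")
}

#' Is segmented subchondral bone underneath a finding?
#'
#' Projects both the finding's footprint and the SSB fragment radially
#' toward the cap centre (the anatomical frame origin) and tests whether
#' the projected footprints intersect, mirroring the visual
#' transparency-based assessment of the fused scene.
#'
#' @param finding a [finding()] with footprint points.
#' @param ssb `ssb` [label_mask()].
#' @param frame a [anatomical_frame()] centred on the cap.
#' @param bin_mm projection raster resolution.
#' @return Logical flag.
#' @export
ssb_underneath <- function(finding, ssb, frame, bin_mm = 0.8) {
  stopifnot(inherits(finding, "cf_finding"), inherits(ssb, "cf_mask"))
  if (!any(ssb$data)) return(FALSE)
  fpts <- finding_points(finding)
  if (is.null(fpts) || nrow(fpts) == 0) return(FALSE)
  spts <- voxel_grid_world(ssb, ssb$data == 1L)
  proj <- function(p) {
    rel <- sweep(as.matrix(p), 2, frame$origin)
    r <- sqrt(rowSums(rel^2))
    d <- rel / pmax(r, 1e-9)
    cbind(round(as.numeric(d %*% frame$ml) * 10 / bin_mm),
          round(as.numeric(d %*% frame$pd) * 10 / bin_mm))
  }
  kf <- unique(paste(proj(fpts)[, 1], proj(fpts)[, 2]))
  ks <- unique(paste(proj(spts)[, 1], proj(spts)[, 2]))
  any(kf %in% ks)
}

finding_points <- function(f) {
  if (!is.null(f$points)) return(as.matrix(f$points))
  if (!is.null(f$voxels)) return(as.matrix(f$voxels))
  NULL
}
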