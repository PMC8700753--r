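#' Landmark (N-point) rigid registration
#'
#' Least-squares rigid alignment of ordered corresponding landmark sets
#' (Kabsch / absolute orientation): the returned transform is restricted
#' to proper rotations plus translation (no scaling, and reflections are
#' excluded so a mirrored solution cannot silently flip anatomy), and
#' minimizes the sum of squared distances `sum(|T(src_i) - dst_i|^2)`.
#' Correspondence is by order/name, as when points are picked manually
#' on screen; four well-spread points on different planes are the
#' typical protocol.
#'
#' @param src,dst [landmark_set()]s (or n x 3 matrices) with matching
#'   order; at least 3 non-collinear points.
#' @return List with `transform` (a `cf_transform`) and `rmsd` (mm).
#' @export
npoint_register <- function(src, dst) {
  ps <- if (inherits(src, "cf_landmarks")) src$points else as.matrix(src)
  pd <- if (inherits(dst, "cf_landmarks")) dst$points else as.matrix(dst)
  if (nrow(ps) != nrow(pd))
    stop("landmark count mismatch: ", nrow(ps), " vs ", nrow(pd))
  if (nrow(ps) < 3) stop("at least 3 landmark pairs required")
  if (!is.null(rownames(ps)) && !is.null(rownames(pd)) &&
      !identical(rownames(ps), rownames(pd)))
    stop("landmark names do not match between the two sets")
  if (landmarks_collinear(ps) || landmarks_collinear(pd))
    stop("landmarks are collinear; the rotation is not determined")
  tr <- kabsch(ps, pd)
  res <- apply_transform(tr, ps) - pd
  list(transform = tr, rmsd = sqrt(mean(rowSums(res^2))))
}

kabsch <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  H <- crossprod(sweep(src, 2, cs), sweep(dst, 2, cd))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, cd - as.numeric(R %*% cs))
}

#' Refine a rigid alignment by iterative closest point
#'
#' Point-to-point ICP between mesh vertex clouds: nearest-neighbour
#' correspondences on a uniform spatial grid, rigid (Kabsch) update,
#' repeated until the relative change of the rmsd falls below `rel_tol`
#' or `max_iter` is reached. The rmsd trace is non-increasing. The
#' moving cloud is uniformly subsampled for speed; no trimming is
#' applied by default (intended for fully overlapping surfaces;
#' `trim_frac` discards the worst correspondences for partial overlap).
#'
#' @param moving,fixed `cf_mesh` objects (vertices used).
#' @param init initial `cf_transform` (e.g. from [npoint_register()]).
#' @param max_iter maximum iterations.
#' @param rel_tol relative rmsd-change convergence tolerance.
#' @param subsample maximum number of moving vertices used.
#' @param trim_frac fraction of worst correspondences to discard (0 =
#'   none).
#' @return List with `transform` (`cf_transform`), `rmsd` (final, mm)
#'   and `trace` (rmsd per iteration).
#' @export
icp_refine <- function(moving, fixed, init = rigid_transform(),
                       max_iter = 50, rel_tol = 1e-6, subsample = 2000,
                       trim_frac = 0) {
  stopifnot(inherits(moving, "cf_mesh"), inherits(fixed, "cf_mesh"),
            inherits(init, "cf_transform"))
  if (nrow(moving$vertices) == 0 || nrow(fixed$vertices) == 0)
    stop("ICP requires non-empty meshes")
  if (!all(is.finite(moving$vertices)) || !all(is.finite(fixed$vertices)))
    stop("non-finite vertices")
  P <- moving$vertices
  if (nrow(P) > subsample)
    P <- P[round(seq(1, nrow(P), length.out = subsample)), , drop = FALSE]
  Q <- fixed$vertices
  bb <- apply(Q, 2, range)
  cell <- max(max(bb[2, ] - bb[1, ]) / 40, 1e-6)
  Tcur <- init
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    Pm <- apply_transform(Tcur, P)
    nn <- cf_nearest_neighbour(Pm, Q, cell)
    tgt <- Q[nn, , drop = FALSE]
    d2 <- rowSums((Pm - tgt)^2)
    use <- seq_along(d2)
    if (trim_frac > 0)
      use <- order(d2)[seq_len(max(3, floor(length(d2) *
                                            (1 - trim_frac))))]
    rmsd <- sqrt(mean(d2[use]))
    trace <- c(trace, rmsd)
    Tcur <- kabsch(P[use, , drop = FALSE], tgt[use, , drop = FALSE])
    if (is.finite(prev) &&
        abs(prev - rmsd) <= rel_tol * max(prev, 1e-12)) break
    prev <- rmsd
  }
  list(transform = Tcur, rmsd = trace[length(trace)], trace = trace)
}

#' Assemble the MRI-CT fusion scene (MCFI)
#'
#' Applies the MRI-to-CT transform to the MRI-derived models (the MRI
#' humerus and the articular cartilage, which is rigidly linked to it so
#' their relative pose is preserved), hides the MRI humerus, leaves the
#' CT humerus untouched, and overlays the segmented subchondral bone in
#' red. The result is the fused scene the lesion evaluation and surgical
#' simulation operate on.
#'
#' @param ct_humerus CT bone `cf_mesh` (required).
#' @param mri_humerus MRI bone `cf_mesh`.
#' @param cartilage cartilage `cf_mesh` (MRI frame).
#' @param ssb optional SSB `cf_mesh`.
#' @param transform `cf_transform` mapping the MRI frame to the CT
#'   frame.
#' @param ssb_frame frame the SSB mesh is supplied in: `"CT"` (the
#'   usual case: it was segmented from CT and is left untouched) or
#'   `"MRI"` (transformed together with the linked MRI models).
#' @return An object of class `cf_scene`.
#' @export
build_mcfi <- function(ct_humerus, mri_humerus, cartilage, ssb = NULL,
                       transform = rigid_transform(),
                       ssb_frame = c("CT", "MRI")) {
  ssb_frame <- match.arg(ssb_frame)
  if (missing(ct_humerus) || is.null(ct_humerus))
    stop("a CT humerus model is required")
  stopifnot(inherits(ct_humerus, "cf_mesh"), inherits(transform,
            "cf_transform"))
  mri_h <- transform_mesh(mri_humerus, transform)
  mri_h$label <- "humerus_mri"
  mri_h$visible <- FALSE
  cart <- transform_mesh(cartilage, transform)
  models <- list(humerus_ct = ct_humerus, humerus_mri = mri_h,
                 cartilage = cart)
  if (!is.null(ssb)) {
    sm <- if (ssb_frame == "MRI") transform_mesh(ssb, transform) else ssb
    sm$label <- "ssb"
    sm$color <- c(1, 0, 0)
    models$ssb <- sm
  }
  structure(list(models = models, transform_mri_to_ct = transform),
            class = "cf_scene")
}

#' @export
print.cf_scene <- function(x, ...) {
  cat("<cf_scene> MCFI with models:\n")
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %-12s %6d faces, alpha %.2f%s\n", nm, nrow(m$faces),
                m$transparency, if (m$visible) "" else " (hidden)"))
  }
  invisible(x)
}

#' Adjust the transparency of one scene model
#'
#' Used to look through the articular cartilage at the subchondral bone
#' beneath it; only the named model's alpha changes.
#'
#' @param scene a `cf_scene`.
#' @param label model name in the scene.
#' @param alpha transparency in [0, 1] (0 = invisible, 1 = opaque).
#' @return The modified scene.
#' @export
set_transparency <- function(scene, label, alpha) {
  stopifnot(inherits(scene, "cf_scene"))
  if (!label %in% names(scene$models))
    stop("no model named '", label, "' in scene")
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be in [0, 1]")
  scene$models[[label]]$transparency <- alpha
  if (alpha == 0) scene$models[[label]]$visible <- FALSE
  scene
}
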