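#' Configuration for the synthetic capitellum phantom
#'
#' The phantom is a geometric stand-in for a traction-MRI / CT pair of an
#' OCD elbow: a spherical capitellar cap with a cartilage shell, a
#' proximal shaft and two epicondyle-like surface bosses (which break the
#' rotational symmetry so shape-based registration is well posed), imaged
#' in two modalities whose world frames are related by a known rigid
#' transform. The lesion is parameterized by its polar position on the cap
#' and angular extent; switches add a fissure slab perpendicular to the
#' articular surface, a cartilage defect, a surface protrusion or
#' flattening, a subchondral fragment separated from the parent bone by a
#' low-intensity cleft (with an optional bridging rod as a negative
#' control for the three-plane separation criterion), and a sclerotic
#' rim. Anatomical realism is a non-goal; exact geometric ground truth is
#' the goal.
#'
#' The analytic footprint is an ellipse in the anteroposterior projection
#' with semi-axes `R_s * sin(extent/2)` (the chord subtended by the
#' angular extent on the outer surface of radius `R_s`), so the true
#' vertical/horizontal diameters are `2 R_s sin(extent/2)` in closed
#' form.
#'
#' @param grid_shape integer triple of voxels per axis (both volumes).
#' @param spacing_mri,spacing_ct isotropic voxel spacing in mm.
#' @param bone_radius capitellar bone radius, mm.
#' @param cartilage_thickness cartilage shell thickness, mm.
#' @param cap_half_angle_deg polar half-angle of the articular cap.
#' @param lesion_center_angles degrees `c(theta, phi)`: polar angle from
#'   the cap apex and azimuth from the mediolateral axis.
#' @param lesion_angular_extent degrees `c(vertical, horizontal)` angular
#'   extents governing the footprint size.
#' @param fissure_enabled add an articular cartilage fissure slab.
#' @param fissure_orientation `"normal"` (penetrating, a true ACF) or
#'   `"tangential"` (a sub-surface slab that is *not* an ACF; negative
#'   control).
#' @param defect_enabled remove the cartilage over the footprint (ACD).
#' @param protrusion_height_mm,flattening_depth_mm surface deformity
#'   amplitudes (0 disables).
#' @param ssb_cleft_planes `"all"` (fragment fully separated in every
#'   plane), `"bridge"` (a bone rod keeps it connected: not an SSB), or
#'   `"none"` (no fragment).
#' @param sclerosis_enabled add a high-intensity sclerotic rim on CT.
#' @param true_transform `cf_transform` mapping the MRI frame to the CT
#'   frame.
#' @param landmark_count number of shared landmarks (>= 4).
#' @param noise_sd additive Gaussian intensity noise (both volumes).
#' @param seed integer RNG seed; the phantom is bit-reproducible for a
#'   fixed seed and config.
#' @param traction_applied metadata flag recording that the MRI is
#'   modelled as acquired under axial traction (widened joint space is
#'   implicit in the cartilage outline being visible).
#' @return An object of class `cf_phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(80L, 80L, 80L),
                           spacing_mri = 0.4, spacing_ct = 0.5,
                           bone_radius = 11, cartilage_thickness = 2.2,
                           cap_half_angle_deg = 60,
                           lesion_center_angles = c(15, 90),
                           lesion_angular_extent = c(60, 50),
                           fissure_enabled = TRUE,
                           fissure_orientation = c("normal", "tangential"),
                           defect_enabled = FALSE,
                           protrusion_height_mm = 1.2,
                           flattening_depth_mm = 0,
                           ssb_cleft_planes = c("all", "bridge", "none"),
                           sclerosis_enabled = TRUE,
                           true_transform = rigid_transform(
                             rotation_about_axis(c(0.3, 0.8, 0.52), 12),
                             c(6, -4, 9)),
                           landmark_count = 4L,
                           noise_sd = 5,
                           seed = 1L,
                           traction_applied = TRUE) {
  fissure_orientation <- match.arg(fissure_orientation)
  ssb_cleft_planes <- match.arg(ssb_cleft_planes)
  spacing_mri <- rep(spacing_mri, length.out = 3)
  spacing_ct <- rep(spacing_ct, length.out = 3)
  if (any(c(spacing_mri, spacing_ct) <= 0)) stop("spacing must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (landmark_count < 3) stop("landmark_count must be >= 3")
  if (bone_radius <= 0 || cartilage_thickness <= 0)
    stop("bone_radius and cartilage_thickness must be positive")
  if (protrusion_height_mm > 0 && flattening_depth_mm > 0)
    stop("choose protrusion or flattening, not both")
  cfg <- structure(list(
    grid_shape = as.integer(rep(grid_shape, length.out = 3)),
    spacing_mri = spacing_mri, spacing_ct = spacing_ct,
    bone_radius = bone_radius,
    cartilage_thickness = cartilage_thickness,
    cap_half_angle_deg = cap_half_angle_deg,
    lesion_center_angles = lesion_center_angles,
    lesion_angular_extent = lesion_angular_extent,
    fissure_enabled = isTRUE(fissure_enabled),
    fissure_orientation = fissure_orientation,
    defect_enabled = isTRUE(defect_enabled),
    protrusion_height_mm = protrusion_height_mm,
    flattening_depth_mm = flattening_depth_mm,
    ssb_cleft_planes = ssb_cleft_planes,
    sclerosis_enabled = isTRUE(sclerosis_enabled),
    true_transform = true_transform,
    landmark_count = as.integer(landmark_count),
    noise_sd = noise_sd, seed = as.integer(seed),
    traction_applied = isTRUE(traction_applied)),
    class = "cf_phantom_config")
  validate_phantom_config(cfg)
  cfg
}

# synthetic intensity classes; config constants, not HU-calibrated
phantom_intensities <- function() {
  list(mri = c(background = 0, bone = 80, cartilage = 200, low = 0),
       ct = c(background = 0, bone = 1000, sclerosis = 1600,
              cartilage = 30))
}

phantom_geometry <- function(config) {
  R_b <- config$bone_radius
  R_s <- R_b + config$cartilage_thickness
  th_c <- config$lesion_center_angles[1] * pi / 180
  ph_c <- config$lesion_center_angles[2] * pi / 180
  centre_uv <- R_s * sin(th_c) * c(cos(ph_c), sin(ph_c))
  semi <- R_s * sin(config$lesion_angular_extent * pi / 360)
  # semi[1]: vertical (proximodistal, v); semi[2]: horizontal (ml, u)
  list(R_b = R_b, R_s = R_s,
       cap_cos = cos(config$cap_half_angle_deg * pi / 180),
       centre_uv = centre_uv,
       semi_v = semi[1], semi_h = semi[2],
       shaft_r = 0.5 * R_b, shaft_y0 = 0.88 * R_b, shaft_y1 = 1.4 * R_b,
       boss1_c = R_b * c(0.95, 0.2, -0.25) /
         sqrt(sum(c(0.95, 0.2, -0.25)^2)), boss1_r = 2.5,
       boss2_c = R_b * c(-0.85, 0.45, -0.28) /
         sqrt(sum(c(-0.85, 0.45, -0.28)^2)), boss2_r = 2.0,
       frag_depth = 3, cleft_th = 1.2, rim_th = 1.6,
       frag_scale = 0.6, cleft_scale = 0.78, bridge_r = 0.8,
       fissure_half = 0.25)
}

validate_phantom_config <- function(config) {
  g <- phantom_geometry(config)
  half_mri <- config$spacing_mri * (config$grid_shape - 1) / 2
  reach <- g$R_s + max(config$protrusion_height_mm, 0) + 1
  if (reach > half_mri[1] || reach > half_mri[3] || reach > half_mri[2])
    stop("grid too small to hold bone_radius plus cartilage: ",
         "need at least ", sprintf("%.1f", 2 * reach), " mm of field of view")
  rim <- sqrt(sum(g$centre_uv^2)) + max(g$semi_v, g$semi_h)
  if (rim > g$R_s * sqrt(1 - g$cap_cos^2) - 0.5)
    stop("lesion extent exceeds the articular cap ",
         sprintf("(footprint reaches %.1f mm from the apex, cap radius %.1f mm)",
                 rim, g$R_s * sqrt(1 - g$cap_cos^2)))
  invisible(config)
}

in_ellipse_uv <- function(u, v, g, scale = 1) {
  ((u - g$centre_uv[1]) / (g$semi_h * scale))^2 +
    ((v - g$centre_uv[2]) / (g$semi_v * scale))^2 <= 1
}

# Evaluate the phantom intensity at anatomy-frame points P (n x 3 mm).
phantom_intensity <- function(P, config, modality) {
  g <- phantom_geometry(config)
  iv <- phantom_intensities()
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  r <- sqrt(x^2 + y^2 + z^2)
  # cap coordinates: u mediolateral, v proximodistal (AP projection)
  u <- x; v <- y
  in_cap_dir <- ifelse(r > 0, z / pmax(r, 1e-12), 1) >= g$cap_cos
  in_fp <- in_ellipse_uv(u, v, g) & z > 0

  sphere <- r <= g$R_b
  shaft <- sqrt(x^2 + z^2) <= g$shaft_r & y >= g$shaft_y0 & y <= g$shaft_y1
  boss1 <- (x - g$boss1_c[1])^2 + (y - g$boss1_c[2])^2 +
    (z - g$boss1_c[3])^2 <= g$boss1_r^2
  boss2 <- (x - g$boss2_c[1])^2 + (y - g$boss2_c[2])^2 +
    (z - g$boss2_c[3])^2 <= g$boss2_r^2

  have_frag <- config$ssb_cleft_planes != "none"
  frag <- cleft <- scler <- rep(FALSE, length(x))
  if (have_frag) {
    in_frag_fp <- in_ellipse_uv(u, v, g, g$frag_scale) & z > 0
    in_cleft_fp <- in_ellipse_uv(u, v, g, g$cleft_scale) & z > 0
    frag <- sphere & in_frag_fp & r > g$R_b - g$frag_depth
    cleft <- sphere & in_cleft_fp & r > g$R_b - g$frag_depth - g$cleft_th &
      !frag
    if (config$ssb_cleft_planes == "bridge") {
      rod <- (u - g$centre_uv[1])^2 + (v - g$centre_uv[2])^2 <= g$bridge_r^2
      cleft <- cleft & !rod
    }
    if (config$sclerosis_enabled) {
      floor_r <- g$R_b - g$frag_depth - g$cleft_th
      scler <- sphere & in_cleft_fp & r <= floor_r &
        r > floor_r - g$rim_th
    }
  }
  bone <- (sphere & !cleft) | shaft | boss1 | boss2

  # cartilage shell over the cap
  R_out <- rep(g$R_s, length(x))
  if (config$protrusion_height_mm > 0)
    R_out[in_fp] <- g$R_s + config$protrusion_height_mm
  if (config$flattening_depth_mm > 0)
    R_out[in_fp] <- g$R_s - config$flattening_depth_mm
  cart <- in_cap_dir & r > g$R_b & r <= R_out & !bone
  if (config$defect_enabled) cart[in_fp] <- FALSE

  fiss <- rep(FALSE, length(x))
  if (config$fissure_enabled) {
    if (config$fissure_orientation == "normal") {
      # slab containing the local surface normal: kills cartilage signal
      # across the full thickness along the proximodistal mid-line
      fiss <- cart & in_fp & abs(v - g$centre_uv[2]) <= g$fissure_half
    } else {
      t <- config$cartilage_thickness
      fiss <- cart & in_fp & r > g$R_b + 0.3 * t & r <= g$R_b + 0.5 * t
    }
  }

  if (modality == "MRI") {
    out <- rep(iv$mri[["background"]], length(x))
    out[bone] <- iv$mri[["bone"]]
    out[cart] <- iv$mri[["cartilage"]]
    out[fiss] <- iv$mri[["low"]]
  } else {
    out <- rep(iv$ct[["background"]], length(x))
    out[bone] <- iv$ct[["bone"]]
    out[scler] <- iv$ct[["sclerosis"]]
    out[cart & !fiss] <- iv$ct[["cartilage"]]
  }
  out
}

phantom_membership <- function(P, config, what) {
  # boolean masks for truth construction, same geometry as intensity
  g <- phantom_geometry(config)
  x <- P[, 1]; y <- P[, 2]; z <- P[, 3]
  r <- sqrt(x^2 + y^2 + z^2)
  u <- x; v <- y
  switch(what,
    fragment = {
      if (config$ssb_cleft_planes == "none") rep(FALSE, length(x))
      else r <= g$R_b & r > g$R_b - g$frag_depth &
        in_ellipse_uv(u, v, g, g$frag_scale) & z > 0
    },
    sclerosis = {
      if (config$ssb_cleft_planes == "none" || !config$sclerosis_enabled)
        rep(FALSE, length(x))
      else {
        floor_r <- g$R_b - g$frag_depth - g$cleft_th
        r <= floor_r & r > floor_r - g$rim_th &
          in_ellipse_uv(u, v, g, g$cleft_scale) & z > 0
      }
    },
    stop("unknown membership: ", what))
}

phantom_grid <- function(config, modality, origin_shift = c(0, 0, 0)) {
  sp <- if (modality == "MRI") config$spacing_mri else config$spacing_ct
  sh <- config$grid_shape
  origin <- -sp * (sh - 1) / 2 + origin_shift
  list(spacing = sp, shape = sh, origin = origin)
}

phantom_landmarks <- function(config) {
  g <- phantom_geometry(config)
  p1 <- g$boss1_c + g$boss1_r * g$boss1_c / sqrt(sum(g$boss1_c^2))
  p2 <- g$boss2_c + g$boss2_r * g$boss2_c / sqrt(sum(g$boss2_c^2))
  p3 <- c(g$shaft_r, 0.9 * g$shaft_y1, 0)
  p4 <- c(0, 0, g$R_b)
  pts <- rbind(p1, p2, p3, p4)
  nms <- c("epicondyle_major", "epicondyle_minor", "shaft", "cap_apex")
  extra <- config$landmark_count - 4L
  if (extra > 0) {
    ang <- 2 * pi * seq_len(extra) / (extra + 1)
    pts <- rbind(pts, cbind(g$shaft_r * cos(ang), 0.7 * g$shaft_y1,
                            g$shaft_r * sin(ang)))
    nms <- c(nms, paste0("shaft_", seq_len(extra)))
  } else if (extra < 0) {
    pts <- pts[seq_len(config$landmark_count), , drop = FALSE]
    nms <- nms[seq_len(config$landmark_count)]
  }
  rownames(pts) <- NULL
  landmark_set(pts, names = nms, frame = "MRI")
}

#' Generate a paired synthetic MRI/CT phantom case
#'
#' Rasterizes the analytic phantom into an MRI-like and a CT-like volume
#' whose world frames are related by `config$true_transform`, derives the
#' shared landmarks in both frames, and records the full geometric ground
#' truth (transform, lesion footprint and diameters, findings, SSB and
#' sclerosis masks, anatomical frame). Deterministic for a fixed seed.
#'
#' @param config a [phantom_config()].
#' @return An object of class `cf_phantom` with elements `mri`, `ct`,
#'   `landmarks_mri`, `landmarks_ct`, `truth`, `config`.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "cf_phantom_config"))
  validate_phantom_config(config)
  g <- phantom_geometry(config)
  set.seed(config$seed)

  gm <- phantom_grid(config, "MRI")
  mri_vol <- image_volume(array(0, gm$shape), spacing = gm$spacing,
                          origin = gm$origin, modality = "MRI")
  Pm <- voxel_grid_world(mri_vol)
  mri_dat <- phantom_intensity(Pm, config, "MRI")
  if (config$noise_sd > 0)
    mri_dat <- mri_dat + rnorm(length(mri_dat), 0, config$noise_sd)
  mri_vol$data <- array(mri_dat, gm$shape)

  Tt <- config$true_transform
  centre_ct <- apply_transform(Tt, c(0, 0, 0))
  gc <- phantom_grid(config, "CT")
  ct_vol <- image_volume(array(0, gc$shape), spacing = gc$spacing,
                         origin = gc$origin + centre_ct, modality = "CT")
  Pc <- voxel_grid_world(ct_vol)
  Pc_anat <- apply_transform(invert_transform(Tt), Pc)
  ct_dat <- phantom_intensity(Pc_anat, config, "CT")
  if (config$noise_sd > 0)
    ct_dat <- ct_dat + rnorm(length(ct_dat), 0, config$noise_sd)
  ct_vol$data <- array(ct_dat, gc$shape)

  lm_mri <- phantom_landmarks(config)
  lm_ct <- landmark_set(apply_transform(Tt, lm_mri$points),
                        names = rownames(lm_mri$points), frame = "CT")

  truth <- phantom_truth(config, ct_vol, Pc_anat)
  structure(list(mri = mri_vol, ct = ct_vol,
                 landmarks_mri = lm_mri, landmarks_ct = lm_ct,
                 truth = truth, config = config),
            class = "cf_phantom")
}

#' @export
print.cf_phantom <- function(x, ...) {
  cat("<cf_phantom>\n  ")
  print(x$mri)
  cat("  ")
  print(x$ct)
  cat(sprintf("  %d landmarks; findings: %s; SSB %spresent\n",
              nrow(x$landmarks_mri$points),
              if (length(x$truth$true_findings))
                paste(vapply(x$truth$true_findings, `[[`, "", "kind"),
                      collapse = ", ") else "none",
              if (x$truth$ssb_present) "" else "not "))
  invisible(x)
}

# footprint surface samples (MRI/anatomy frame, mm)
phantom_footprint_points <- function(config, step = 0.25) {
  g <- phantom_geometry(config)
  us <- seq(g$centre_uv[1] - g$semi_h, g$centre_uv[1] + g$semi_h, by = step)
  vs <- seq(g$centre_uv[2] - g$semi_v, g$centre_uv[2] + g$semi_v, by = step)
  uv <- expand.grid(u = us, v = vs)
  keep <- in_ellipse_uv(uv$u, uv$v, g)
  # exact extremes of the analytic ellipse so extents are closed-form
  uv <- rbind(uv[keep, ],
              data.frame(u = g$centre_uv[1] + c(-g$semi_h, g$semi_h, 0, 0),
                         v = g$centre_uv[2] + c(0, 0, -g$semi_v, g$semi_v)))
  w <- sqrt(pmax(g$R_s^2 - uv$u^2 - uv$v^2, 0))
  cbind(uv$u, uv$v, w)
}

phantom_truth <- function(config, ct_vol, Pc_anat) {
  g <- phantom_geometry(config)
  fp <- phantom_footprint_points(config)
  frame <- anatomical_frame(origin = c(0, 0, 0), ap = c(0, 0, 1),
                            pd = c(0, 1, 0), ml = c(1, 0, 0),
                            side = "right")
  has_size <- config$defect_enabled || config$protrusion_height_mm > 0 ||
    config$flattening_depth_mm > 0
  area_of <- function(pts) {
    uv <- project_ap(frame, pts)
    sort(unique(quadrant_area(uv[, 1], uv[, 2])))
  }
  ssb_present <- config$ssb_cleft_planes == "all"
  findings <- list()
  if (config$fissure_enabled && config$fissure_orientation == "normal") {
    sel <- abs(fp[, 2] - g$centre_uv[2]) <= max(g$fissure_half, 0.3)
    findings <- c(findings, list(
      finding("ACF", points = fp[sel, , drop = FALSE],
              areas = area_of(fp[sel, , drop = FALSE]),
              ssb_underneath = ssb_present)))
  }
  if (config$defect_enabled)
    findings <- c(findings, list(
      finding("ACD", points = fp, areas = area_of(fp))))
  if (config$protrusion_height_mm > 0)
    findings <- c(findings, list(
      finding("ASD", points = fp, areas = area_of(fp),
              asd_subtype = "protrusion", ssb_underneath = ssb_present)))
  if (config$flattening_depth_mm > 0)
    findings <- c(findings, list(
      finding("ASD", points = fp, areas = area_of(fp),
              asd_subtype = "flattening", ssb_underneath = ssb_present)))

  scl <- phantom_membership(Pc_anat, config, "sclerosis")
  scler_mask <- label_mask(array(as.integer(scl), dim(ct_vol$data)),
                           ct_vol, "sclerosis")
  frag <- phantom_membership(Pc_anat, config, "fragment")
  frag_mask <- label_mask(array(as.integer(frag), dim(ct_vol$data)),
                          ct_vol, "ssb")
  structure(list(
    true_transform = config$true_transform,
    lesion_footprint = fp,
    true_vertical_diameter = if (has_size) 2 * g$semi_v else NA_real_,
    true_horizontal_diameter = if (has_size) 2 * g$semi_h else NA_real_,
    true_findings = findings,
    ssb_present = ssb_present,
    fragment_mask = frag_mask,
    sclerosis_mask = scler_mask,
    anatomical_frame = frame),
    class = "cf_phantom_truth")
}

#' Ground-truth lesion report for a phantom case
#'
#' Applies the same codified stability and ICRS rules the analysis stage
#' uses, but to the phantom's true findings, yielding the report any
#' correct pipeline run should recover.
#'
#' @param case a `cf_phantom` from [generate_phantom()].
#' @return A [lesion_report()].
#' @export
truth_report <- function(case) {
  stopifnot(inherits(case, "cf_phantom"))
  tr <- case$truth
  stability <- classify_stability(tr$true_findings)
  icrs <- predict_icrs(tr$true_findings)
  lesion_report(findings = tr$true_findings,
                ssb_present = tr$ssb_present,
                vertical_diameter_mm = tr$true_vertical_diameter,
                horizontal_diameter_mm = tr$true_horizontal_diameter,
                stability = stability, icrs_class = icrs)
}
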