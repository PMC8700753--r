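#' Costal osteochondral autograft template
#'
#' Rectangular bone block with a cartilage cap layer, modelled on an
#' average-sized rib graft. The default dimensions are package defaults
#' for a plausible average graft (user-adjustable); the graft's local
#' frame has the articular (cartilage) surface at z = 0 and the bone
#' extending to z = -height.
#'
#' @param length_mm,width_mm,height_mm block dimensions (> 0).
#' @param cartilage_cap_thickness_mm cartilage layer thickness.
#' @return An object of class `cf_graft`.
#' @export
make_costal_graft <- function(length_mm = 15, width_mm = 10,
                              height_mm = 8,
                              cartilage_cap_thickness_mm = 2) {
  if (any(c(length_mm, width_mm, height_mm,
            cartilage_cap_thickness_mm) <= 0))
    stop("graft dimensions must be positive")
  hx <- width_mm / 2; hy <- length_mm / 2
  V <- cbind(c(-hx, hx, hx, -hx, -hx, hx, hx, -hx),
             c(-hy, -hy, hy, hy, -hy, -hy, hy, hy),
             c(0, 0, 0, 0, -height_mm, -height_mm, -height_mm,
               -height_mm))
  F <- rbind(c(1, 2, 3), c(1, 3, 4),          # top (z = 0)
             c(5, 7, 6), c(5, 8, 7),          # bottom
             c(1, 6, 2), c(1, 5, 6),
             c(2, 7, 3), c(2, 6, 7),
             c(3, 8, 4), c(3, 7, 8),
             c(4, 5, 1), c(4, 8, 5))
  mesh <- tri_mesh(V, F, label = "graft", color = c(0.2, 0.8, 0.3))
  structure(list(shape = "costal_block",
                 dims = list(length = length_mm, width = width_mm,
                             height = height_mm,
                             cartilage_cap = cartilage_cap_thickness_mm),
                 pose = rigid_transform(), mesh = mesh),
            class = "cf_graft")
}

#' Cylindrical (OATS-style) osteochondral plug
#'
#' @param diameter_mm plug diameter; when `catalog` is non-NULL the
#'   diameter must belong to it (default catalog: 5 and 7 mm).
#' @param length_mm plug length (> 0).
#' @param catalog allowed diameters, or NULL to accept any.
#' @param n_segments circumferential facet count.
#' @return An object of class `cf_graft`.
#' @export
make_cylindrical_graft <- function(diameter_mm, length_mm = 12,
                                   catalog = c(5, 7), n_segments = 64) {
  if (diameter_mm <= 0 || length_mm <= 0)
    stop("graft dimensions must be positive")
  if (!is.null(catalog) && !diameter_mm %in% catalog)
    stop("diameter ", diameter_mm,
         " mm is not in the graft catalog (", paste(catalog,
         collapse = ", "), ")")
  r <- diameter_mm / 2
  ang <- 2 * pi * (seq_len(n_segments) - 1) / n_segments
  ring_top <- cbind(r * cos(ang), r * sin(ang), 0)
  ring_bot <- cbind(r * cos(ang), r * sin(ang), -length_mm)
  V <- rbind(ring_top, ring_bot, c(0, 0, 0), c(0, 0, -length_mm))
  ctop <- 2L * n_segments + 1L
  cbot <- 2L * n_segments + 2L
  nxt <- c(seq_len(n_segments - 1) + 1L, 1L)
  F <- rbind(
    cbind(seq_len(n_segments), nxt, ctop),                       # top fan
    cbind(n_segments + nxt, n_segments + seq_len(n_segments), cbot),
    cbind(seq_len(n_segments), n_segments + seq_len(n_segments),
          nxt),
    cbind(nxt, n_segments + seq_len(n_segments), n_segments + nxt))
  mesh <- tri_mesh(V, F, label = "graft", color = c(0.2, 0.8, 0.3))
  structure(list(shape = "cylinder",
                 dims = list(diameter = diameter_mm, length = length_mm),
                 pose = rigid_transform(), mesh = mesh),
            class = "cf_graft")
}

#' @export
print.cf_graft <- function(x, ...) {
  cat(sprintf("<cf_graft> %s (%s)\n", x$shape,
              paste(names(x$dims), unlist(x$dims), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

# analytic solid membership in the graft's local frame
graft_contains <- function(graft, pose, points) {
  local <- apply_transform(invert_transform(pose), points)
  if (graft$shape == "costal_block") {
    d <- graft$dims
    abs(local[, 1]) <= d$width / 2 & abs(local[, 2]) <= d$length / 2 &
      local[, 3] <= 0 & local[, 3] >= -d$height
  } else {
    d <- graft$dims
    local[, 1]^2 + local[, 2]^2 <= (d$diameter / 2)^2 &
      local[, 3] <= 0 & local[, 3] >= -d$length
  }
}

#' Simulate lesion resection on the fused scene
#'
#' Separates the lesion footprint from the cartilage model into an
#' independent resection mesh (hidden, so the scene shows the lesion
#' removed) and records the footprint and anatomical frame on the scene
#' for subsequent graft placement.
#'
#' @param scene a `cf_scene`.
#' @param footprint n x 3 mm matrix (or `cf_finding`) of the resection
#'   area.
#' @param frame a [anatomical_frame()] (CT/world frame of the scene).
#' @return The modified scene, with models `cartilage` (remainder) and
#'   `resection` (hidden).
#' @export
simulate_resection <- function(scene, footprint, frame) {
  stopifnot(inherits(scene, "cf_scene"))
  if (inherits(footprint, "cf_finding"))
    footprint <- finding_points(footprint)
  footprint <- as.matrix(footprint)
  if (nrow(footprint) == 0) stop("empty footprint")
  parts <- separate_region(scene$models$cartilage, footprint, frame)
  parts$resection$visible <- FALSE
  scene$models$cartilage <- parts$remainder
  scene$models$resection <- parts$resection
  scene$resection_footprint <- footprint
  scene$frame <- frame
  scene
}

#' Place osteochondral graft(s) and quantify the reconstruction
#'
#' Computes placement quality metrics on the fused scene:
#' `coverage_fraction` (share of the resected footprint, in the AP
#' projection, covered by the graft(s)), `step_off_mm` (signed maximum
#' deviation of the graft articular surface from the reference cap
#' sphere), `seat_depth_mm` (deepest penetration of the graft into the
#' host bone) and `collision_volume_mm3` (graft-bone overlap outside
#' the footprint, i.e. beyond the intended seat). Metrics are computed
#' on rasters at `resolution`.
#'
#' @param scene a `cf_scene` after [simulate_resection()] (or with
#'   `footprint`/`frame` supplied).
#' @param graft a `cf_graft` or list of them.
#' @param pose a `cf_transform` or list matching `graft`.
#' @param footprint,frame override the scene's stored resection.
#' @param resolution raster resolution in mm.
#' @return An object of class `cf_placement` with the four metrics.
#' @export
place_graft <- function(scene, graft, pose, footprint = NULL,
                        frame = NULL, resolution = 0.2) {
  stopifnot(inherits(scene, "cf_scene"))
  grafts <- if (inherits(graft, "cf_graft")) list(graft) else graft
  poses <- if (inherits(pose, "cf_transform")) list(pose) else pose
  stopifnot(length(grafts) == length(poses))
  if (is.null(footprint)) footprint <- scene$resection_footprint
  if (is.null(frame)) frame <- scene$frame
  if (is.null(footprint) || is.null(frame))
    stop("no resection footprint on the scene; run simulate_resection() ",
         "or pass footprint and frame")
  fuv <- project_ap(frame, footprint)
  hull <- grDevices::chull(fuv[, 1], fuv[, 2])
  hx <- fuv[hull, 1]; hy <- fuv[hull, 2]
  us <- seq(min(hx), max(hx), by = resolution)
  vs <- seq(min(hy), max(hy), by = resolution)
  gr <- expand.grid(u = us, v = vs)
  in_fp <- point_in_polygon(gr$u, gr$v, hx, hy)
  n_fp <- sum(in_fp)
  if (n_fp == 0) stop("footprint is degenerate at this resolution")

  # coverage: union of the grafts' projected silhouettes (convex shapes:
  # silhouette = convex hull of projected vertices)
  covered <- rep(FALSE, n_fp)
  outside_box <- TRUE
  scene_bb <- apply(scene$models$humerus_ct$vertices, 2, range)
  for (i in seq_along(grafts)) {
    gv <- apply_transform(poses[[i]], grafts[[i]]$mesh$vertices)
    if (any(gv[, 1] >= scene_bb[1, 1] & gv[, 1] <= scene_bb[2, 1] &
            gv[, 2] >= scene_bb[1, 2] & gv[, 2] <= scene_bb[2, 2] &
            gv[, 3] >= scene_bb[1, 3] & gv[, 3] <= scene_bb[2, 3]))
      outside_box <- FALSE
    guv <- project_ap(frame, gv)
    gh <- grDevices::chull(guv[, 1], guv[, 2])
    covered <- covered | point_in_polygon(gr$u[in_fp], gr$v[in_fp],
                                          guv[gh, 1], guv[gh, 2])
  }
  if (outside_box)
    warning("graft pose places the graft fully outside the scene ",
            "bounding box; coverage is 0")
  coverage <- sum(covered) / n_fp

  # reference cap sphere from the cartilage + resection surface
  cap_pts <- rbind(scene$models$cartilage$vertices,
                   if (!is.null(scene$models$resection))
                     scene$models$resection$vertices)
  sph <- fit_sphere(cap_pts)
  host <- scene$models$humerus_ct$vertices
  huv <- project_ap(frame, host)
  near <- point_in_polygon(huv[, 1], huv[, 2],
                           mean(hx) + (hx - mean(hx)) * 1.3,
                           mean(hy) + (hy - mean(hy)) * 1.3)
  bone_sph <- if (sum(near) > 20)
    fit_sphere(host[near, , drop = FALSE]) else sph

  step_off <- 0
  seat <- 0
  collision <- 0
  for (i in seq_along(grafts)) {
    g <- grafts[[i]]; p <- poses[[i]]
    gv <- apply_transform(p, g$mesh$vertices)
    top_local <- g$mesh$vertices[, 3] > -1e-9
    top <- gv[top_local, , drop = FALSE]
    tuv <- project_ap(frame, top)
    in_t <- point_in_polygon(tuv[, 1], tuv[, 2], hx, hy)
    if (any(in_t)) {
      dev <- sqrt(rowSums(sweep(top[in_t, , drop = FALSE], 2,
                                sph$centre)^2)) - sph$radius
      cand <- dev[which.max(abs(dev))]
      if (abs(cand) > abs(step_off)) step_off <- cand
    }
    rb <- bone_sph$radius -
      sqrt(rowSums(sweep(gv, 2, bone_sph$centre)^2))
    seat <- max(seat, rb, 0)
    # collision: graft solid inside bone, projecting outside footprint
    bb <- apply(gv, 2, range)
    xs <- seq(bb[1, 1], bb[2, 1], by = resolution * 2)
    ys <- seq(bb[1, 2], bb[2, 2], by = resolution * 2)
    zs <- seq(bb[1, 3], bb[2, 3], by = resolution * 2)
    pts <- as.matrix(expand.grid(xs, ys, zs))
    inside_g <- graft_contains(g, p, pts)
    if (any(inside_g)) {
      pin <- pts[inside_g, , drop = FALSE]
      in_bone <- sqrt(rowSums(sweep(pin, 2, bone_sph$centre)^2)) <=
        bone_sph$radius
      puv <- project_ap(frame, pin)
      out_fp <- !point_in_polygon(puv[, 1], puv[, 2], hx, hy)
      collision <- collision +
        sum(in_bone & out_fp) * (resolution * 2)^3
    }
  }
  structure(list(coverage_fraction = coverage, step_off_mm = step_off,
                 seat_depth_mm = seat,
                 collision_volume_mm3 = collision),
            class = "cf_placement")
}

#' @export
print.cf_placement <- function(x, ...) {
  cat(sprintf(
    "<cf_placement> coverage %.1f%%, step-off %+.2f mm, seat %.2f mm, collision %.1f mm^3\n",
    100 * x$coverage_fraction, x$step_off_mm, x$seat_depth_mm,
    x$collision_volume_mm3))
  invisible(x)
}

#' Plan a drilling trajectory
#'
#' Builds a drill plan from an entry point on the bone surface to a
#' target inside the bone. The plan records whether the segment crosses
#' the articular cartilage model (iatrogenic damage: a posteroanterior
#' plan with a cartilage breach is flagged invalid) and whether it
#' penetrates the highlighted sclerotic region (which drilling should
#' traverse to promote bleeding and healing).
#'
#' @param scene a `cf_scene`; if `scene$sclerosis_mask` is set it is
#'   used for the sclerosis test.
#' @param entry,target mm points (world/CT frame).
#' @param approach `"posteroanterior"` or `"anteroposterior"`.
#' @param drill_diameter_mm optional physical drill diameter; when > 0
#'   the cartilage test uses a capsule of that radius (sampled rays).
#' @return An object of class `cf_drillplan`.
#' @export
plan_drilling <- function(scene, entry, target,
                          approach = c("posteroanterior",
                                       "anteroposterior"),
                          drill_diameter_mm = 0) {
  approach <- match.arg(approach)
  stopifnot(inherits(scene, "cf_scene"))
  entry <- as.numeric(entry); target <- as.numeric(target)
  bone <- scene$models$humerus_ct
  if (!point_in_mesh(target, bone))
    stop("drill target lies outside the bone")
  dvec <- target - entry
  depth <- sqrt(sum(dvec^2))
  if (depth <= 0) stop("entry and target coincide")
  dir <- dvec / depth
  cart <- scene$models$cartilage
  breach <- segment_hits_mesh(entry, target, cart)
  if (!breach && drill_diameter_mm > 0) {
    # capsule test: parallel rays offset by the drill radius
    perp <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- perp - sum(perp * dir) * dir
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(dir[2] * e1[3] - dir[3] * e1[2],
            dir[3] * e1[1] - dir[1] * e1[3],
            dir[1] * e1[2] - dir[2] * e1[1])
    r <- drill_diameter_mm / 2
    for (a in seq(0, 2 * pi, length.out = 9)[-9]) {
      off <- r * (cos(a) * e1 + sin(a) * e2)
      if (segment_hits_mesh(entry + off, target + off, cart)) {
        breach <- TRUE
        break
      }
    }
  }
  scler <- FALSE
  if (!is.null(scene$sclerosis_mask)) {
    msk <- scene$sclerosis_mask
    ts <- seq(0, 1, by = min(0.25 / depth, 0.5))
    pts <- outer(ts, dvec) + matrix(entry, length(ts), 3, byrow = TRUE)
    ijk <- round(world_to_voxel(msk, pts))
    d <- dim(msk$data)
    ok <- ijk[, 1] >= 0 & ijk[, 2] >= 0 & ijk[, 3] >= 0 &
      ijk[, 1] < d[1] & ijk[, 2] < d[2] & ijk[, 3] < d[3]
    if (any(ok))
      scler <- any(msk$data[ijk[ok, , drop = FALSE] + 1L] == 1L)
  }
  invalid <- approach == "posteroanterior" && breach
  structure(list(entry = entry, target = target, direction = dir,
                 depth_mm = depth, approach = approach,
                 cartilage_breach = breach,
                 sclerosis_penetrated = scler, invalid = invalid),
            class = "cf_drillplan")
}

segment_hits_mesh <- function(p0, p1, mesh) {
  if (is.null(mesh) || nrow(mesh$faces) == 0) return(FALSE)
  cf_segment_mesh_hits(as.numeric(p0), as.numeric(p1), mesh$vertices,
                       mesh$faces) > 0
}

point_in_mesh <- function(p, mesh) {
  # ray-parity test against a closed mesh
  bb <- apply(mesh$vertices, 2, range)
  far <- bb[2, ] + c(13.1, 7.7, 19.3)  # irrational-ish offsets avoid
                                       # edge-grazing degeneracies
  hits <- cf_segment_mesh_hits(as.numeric(p), as.numeric(far),
                               mesh$vertices, mesh$faces)
  hits %% 2 == 1
}

#' @export
print.cf_drillplan <- function(x, ...) {
  cat(sprintf(
    "<cf_drillplan> %s, depth %.1f mm, cartilage breach: %s, sclerosis: %s%s\n",
    x$approach, x$depth_mm, x$cartilage_breach, x$sclerosis_penetrated,
    if (x$invalid) " [INVALID: posteroanterior plan breaches cartilage]"
    else ""))
  invisible(x)
}
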