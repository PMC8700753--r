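#' Fit the capitellar ellipse in the anteroposterior view
#'
#' The articular surface of the capitellum is treated as elliptical in
#' the AP view: the outer cartilage boundary is projected onto the
#' (mediolateral, proximodistal) plane and a direct least-squares conic
#' (ellipse-constrained) fit is applied to its convex hull.
#'
#' @param cartilage a cartilage `cf_mesh` (or n x 3 point matrix).
#' @param frame a [anatomical_frame()].
#' @return An object of class `cf_ellipse` with `center` (u, v), `a`
#'   (mediolateral semi-axis), `b` (proximodistal semi-axis) and
#'   `orientation` (radians).
#' @export
fit_capitellar_ellipse <- function(cartilage, frame) {
  pts <- if (inherits(cartilage, "cf_mesh")) cartilage$vertices
         else as.matrix(cartilage)
  if (nrow(pts) < 5) stop("too few points for an ellipse fit")
  uv <- project_ap(frame, pts)
  hull <- grDevices::chull(uv[, 1], uv[, 2])
  if (length(hull) < 5) {
    # densify: hull of a coarse mesh can be short; fall back to extremes
    hull <- unique(c(hull, order(uv[, 1])[c(1, nrow(uv))],
                     order(uv[, 2])[c(1, nrow(uv))]))
  }
  h <- uv[hull, , drop = FALSE]
  fit_ellipse_uv(h[, 1], h[, 2])
}

# Direct least-squares ellipse fit (Halir-Flusser partitioning of the
# Fitzgibbon ellipse-constrained conic fit; stable also for exact fits)
fit_ellipse_uv <- function(x, y) {
  if (length(x) < 5) stop("degenerate projection: fewer than 5 points")
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate projection: ", conditionMessage(e)))
  M0 <- S1 + S2 %*% Tm
  M <- rbind(M0[3, ] / 2, -M0[2, ], M0[1, ] / 2)
  ev <- eigen(M)
  lam <- Re(ev$values)
  vecs <- Re(ev$vectors)
  cond <- 4 * vecs[1, ] * vecs[3, ] - vecs[2, ]^2
  ok <- which(cond > 0 & is.finite(lam))
  if (length(ok) == 0) stop("degenerate projection: no ellipse solution")
  a1 <- vecs[, ok[1]]
  a6 <- c(a1, as.numeric(Tm %*% a1))
  A <- a6[1]; B <- a6[2]; Cc <- a6[3]; Dd <- a6[4]; E <- a6[5]; Ff <- a6[6]
  M2 <- matrix(c(A, B / 2, B / 2, Cc), 2, 2)
  bvec <- c(Dd, E)
  centre <- as.numeric(-solve(M2, bvec) / 2)
  const <- Ff - 0.25 * sum(bvec * solve(M2, bvec))
  eg <- eigen(M2, symmetric = TRUE)
  axes_len <- sqrt(-const / eg$values)
  if (any(!is.finite(axes_len)) || any(axes_len <= 0))
    stop("degenerate projection: conic is not an ellipse")
  # label semi-axes by alignment with the u (mediolateral) axis
  align_u <- abs(eg$vectors[1, ])
  iu <- which.max(align_u); iv <- setdiff(1:2, iu)
  orientation <- atan2(eg$vectors[2, iu], eg$vectors[1, iu])
  structure(list(center = centre + c(mx, my),
                 a = axes_len[iu], b = axes_len[iv],
                 orientation = orientation),
            class = "cf_ellipse")
}

#' @export
print.cf_ellipse <- function(x, ...) {
  cat(sprintf(
    "<cf_ellipse> centre (%.2f, %.2f), semi-axes a=%.2f (ML) b=%.2f (PD) mm\n",
    x$center[1], x$center[2], x$a, x$b))
  invisible(x)
}

ellipse_value <- function(ellipse, u, v) {
  du <- u - ellipse$center[1]; dv <- v - ellipse$center[2]
  co <- cos(ellipse$orientation); si <- sin(ellipse$orientation)
  ru <- du * co + dv * si
  rv <- -du * si + dv * co
  (ru / ellipse$a)^2 + (rv / ellipse$b)^2
}

# quadrant numbering, clockwise from anteromedial in the AP view:
# 1 medial-proximal, 2 lateral-proximal, 3 lateral-distal,
# 4 medial-distal; boundary points take the lower-numbered adjacent area
quadrant_area <- function(du, dv) {
  q <- ifelse(dv >= 0, ifelse(du >= 0, 1L, 2L),
              ifelse(du >= 0, 4L, 3L))
  q[du == 0 & dv < 0] <- 3L
  q[dv == 0 & du < 0] <- 2L
  q
}

#' Assign a point to one of the four capitellar areas
#'
#' The AP view of the capitellum is divided into four areas, numbered
#' clockwise starting anteromedial, by the proximodistal and
#' mediolateral axes through the ellipse centre. Boundary points go to
#' the lower-numbered adjacent area; the exact centre is area 1.
#'
#' @param point length-3 mm point (world frame).
#' @param ellipse a `cf_ellipse` from [fit_capitellar_ellipse()].
#' @param frame a [anatomical_frame()].
#' @param tol relative tolerance on the ellipse membership test.
#' @return Integer area in 1:4 (errors if the point projects outside
#'   the ellipse).
#' @export
assign_area <- function(point, ellipse, frame, tol = 1e-9) {
  uv <- project_ap(frame, point)
  val <- ellipse_value(ellipse, uv[, 1], uv[, 2])
  if (any(val > 1 + tol)) {
    dist <- (sqrt(val[val > 1 + tol][1]) - 1) *
      min(ellipse$a, ellipse$b)
    stop(sprintf("point projects outside the capitellar ellipse (about %.2f mm beyond the boundary)",
                 dist))
  }
  as.integer(quadrant_area(uv[, 1] - ellipse$center[1],
                           uv[, 2] - ellipse$center[2]))
}

#' Localize a finding into capitellar areas
#'
#' Applies the quadrant assignment over the finding's projected
#' footprint and records the set of touched areas. Footprint points
#' marginally outside the fitted ellipse (a finding can reach the cap
#' rim) are tolerated up to `rim_tol` and excluded beyond it.
#'
#' @param finding a [finding()] with footprint points.
#' @param ellipse a `cf_ellipse`.
#' @param frame a [anatomical_frame()].
#' @param rim_tol relative ellipse-value tolerance for rim points.
#' @return The finding with `areas` filled.
#' @export
localize_finding <- function(finding, ellipse, frame, rim_tol = 0.2) {
  stopifnot(inherits(finding, "cf_finding"))
  pts <- finding_points(finding)
  if (is.null(pts) || nrow(pts) == 0)
    stop("finding has no footprint to localize")
  uv <- project_ap(frame, pts)
  val <- ellipse_value(ellipse, uv[, 1], uv[, 2])
  keep <- val <= 1 + rim_tol
  if (!any(keep)) keep <- rep(TRUE, nrow(uv))
  areas <- quadrant_area(uv[keep, 1] - ellipse$center[1],
                         uv[keep, 2] - ellipse$center[2])
  finding$areas <- sort(unique(as.integer(areas)))
  finding
}

#' Measure vertical and horizontal lesion diameters
#'
#' Straight-line extents of the AP-projected lesion footprint: vertical
#' along the proximodistal axis, horizontal along the mediolateral
#' axis, both in mm. An empty footprint yields absent (`NA`) values,
#' mirroring the clinical situation where no defect or deformity leaves
#' anything to measure.
#'
#' @param footprint n x 3 mm matrix (or `cf_finding`), possibly empty.
#' @param frame a [anatomical_frame()].
#' @param voxel_correction_mm when the footprint points are voxel
#'   centres, the centre-to-centre extent under-covers the region by
#'   about one voxel (half a voxel on each side); pass the voxel
#'   spacing to compensate. Zero (default) for analytic point sets.
#' @return Named numeric `c(vertical, horizontal)` in mm (NA if empty).
#' @export
measure_diameters <- function(footprint, frame, voxel_correction_mm = 0) {
  if (inherits(footprint, "cf_finding"))
    footprint <- finding_points(footprint)
  if (is.null(footprint) || nrow(as.matrix(footprint)) == 0)
    return(c(vertical = NA_real_, horizontal = NA_real_))
  uv <- project_ap(frame, as.matrix(footprint))
  ext <- c(vertical = diff(range(uv[, 2])),
           horizontal = diff(range(uv[, 1])))
  ifelse(ext > 0, ext + voxel_correction_mm, ext)
}

#' Classify lesion stability
#'
#' A lesion is unstable when a fissure or surface deformity has the
#' segmented subchondral bone underneath it, or when the cartilage is
#' frankly defective; otherwise it is stable.
#'
#' @param findings list of [finding()]s with `ssb_underneath` flags set.
#' @return `"stable"` or `"unstable"`.
#' @export
classify_stability <- function(findings) {
  kinds <- vapply(findings, `[[`, "", "kind")
  ssb <- vapply(findings, `[[`, TRUE, "ssb_underneath")
  if (any(kinds == "ACD")) return("unstable")
  if (any(kinds %in% c("ACF", "ASD") & ssb)) return("unstable")
  "stable"
}

#' Predict the ICRS class from findings
#'
#' Codified precedence rule: a cartilage defect means class IV; a
#' fissure or surface deformity with subchondral bone segmented beneath
#' it means class III (unstable but cartilage continuous); a fissure or
#' deformity without separated bone underneath means class II; no
#' findings means class I. The findings-only variant (`use_ssb =
#' FALSE`) is for tabulated records where the SSB relationship is not
#' recorded: there any surface deformity counts as class III and a
#' fissure alone as class II. Class III/IV always coincides with an
#' unstable call of [classify_stability()] when `use_ssb = TRUE`.
#'
#' @param findings list of [finding()]s.
#' @param use_ssb use the per-finding `ssb_underneath` flags.
#' @return `"I"`, `"II"`, `"III"` or `"IV"`.
#' @export
predict_icrs <- function(findings, use_ssb = TRUE) {
  kinds <- vapply(findings, `[[`, "", "kind")
  ssb <- vapply(findings, `[[`, TRUE, "ssb_underneath")
  if (any(kinds == "ACD")) return("IV")
  if (use_ssb) {
    if (any(kinds %in% c("ACF", "ASD") & ssb)) return("III")
    if (any(kinds %in% c("ACF", "ASD"))) return("II")
  } else {
    if (any(kinds == "ASD")) return("III")
    if (any(kinds == "ACF")) return("II")
  }
  "I"
}

#' Recommend a surgical procedure from the lesion report
#'
#' Articular surface reconstruction (costal osteochondral autograft) is
#' indicated for an unstable lesion whose maximum diameter exceeds 10
#' mm; drilling for a small class IV lesion or for a stable lesion
#' refractory to conservative therapy; free-body removal is appended
#' when articular free bodies are present.
#'
#' @param report a [lesion_report()].
#' @param refractory_to_conservative did conservative therapy fail?
#' @param free_bodies are articular free bodies present?
#' @return Character vector of procedures (possibly `"none"`).
#' @export
recommend_procedure <- function(report, refractory_to_conservative = FALSE,
                                free_bodies = FALSE) {
  stopifnot(inherits(report, "cf_report"))
  vd <- report$vertical_diameter_mm
  hd <- report$horizontal_diameter_mm
  maxd <- suppressWarnings(max(vd, hd, na.rm = TRUE))
  unstable <- report$stability == "unstable"
  if (unstable && !is.finite(maxd))
    stop("unstable lesion without measured diameters: measure the lesion first")
  out <- character(0)
  if (unstable && maxd > 10) {
    out <- "reconstruction"
  } else if ((report$icrs_class == "IV" && is.finite(maxd) && maxd <= 10) ||
             (!unstable && refractory_to_conservative)) {
    out <- "drilling"
  }
  if (free_bodies) out <- c(out, "free_body_removal")
  if (length(out) == 0) out <- "none"
  out
}
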