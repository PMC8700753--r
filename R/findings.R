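#' Lesion finding primitive
#'
#' One finding of the kind the fusion-image evaluation records: an
#' articular cartilage fissure (ACF: a low-intensity line within the
#' cartilage penetrating or perpendicular to the articular surface), an
#' articular cartilage defect (ACD: cartilage absent), or an articular
#' surface deformity (ASD: an irregular cartilage outline, recorded as
#' protrusion or flattening). Kinds are mutually exclusive per finding;
#' `asd_subtype` is present iff the kind is ASD.
#'
#' @param kind `"ACF"`, `"ACD"` or `"ASD"`.
#' @param voxels optional integer matrix of 0-based voxel indices or
#'   n x 3 mm point matrix of the finding's footprint.
#' @param points optional n x 3 mm coordinates of the footprint (world).
#' @param areas integer subset of 1:4 (filled by [localize_finding()]).
#' @param asd_subtype `"protrusion"` or `"flattening"` (ASD only).
#' @param ssb_underneath flag: segmented subchondral bone lies radially
#'   beneath this finding.
#' @return An object of class `cf_finding`.
#' @export
finding <- function(kind = c("ACF", "ACD", "ASD"), voxels = NULL,
                    points = NULL, areas = integer(),
                    asd_subtype = NULL, ssb_underneath = FALSE) {
  kind <- match.arg(kind)
  if (kind == "ASD") {
    if (is.null(asd_subtype) ||
        !asd_subtype %in% c("protrusion", "flattening"))
      stop("ASD findings need asd_subtype 'protrusion' or 'flattening'")
  } else if (!is.null(asd_subtype)) {
    stop("asd_subtype is only valid for ASD findings")
  }
  areas <- sort(unique(as.integer(areas)))
  if (length(areas) && (min(areas) < 1L || max(areas) > 4L))
    stop("areas must be a subset of 1:4")
  structure(list(kind = kind, voxels = voxels, points = points,
                 areas = areas, asd_subtype = asd_subtype,
                 ssb_underneath = isTRUE(ssb_underneath)),
            class = "cf_finding")
}

#' @export
print.cf_finding <- function(x, ...) {
  cat(sprintf("<cf_finding> %s%s%s%s\n", x$kind,
              if (!is.null(x$asd_subtype)) paste0(" (", x$asd_subtype, ")")
              else "",
              if (length(x$areas))
                paste0(", areas {", paste(x$areas, collapse = ","), "}")
              else "",
              if (x$ssb_underneath) ", SSB underneath" else ""))
  invisible(x)
}

#' Structured lesion report
#'
#' Aggregates the per-case evaluation: the findings with their quadrant
#' localization, whether a segmented subchondral bone fragment is present,
#' the measured vertical (proximodistal) and horizontal (mediolateral)
#' diameters, the stability call, the predicted ICRS class and the
#' recommended procedure. Diameters are `NA` when there is no measurable
#' footprint. Class III/IV implies an unstable call.
#'
#' @param findings list of [finding()] objects.
#' @param ssb_present flag.
#' @param vertical_diameter_mm,horizontal_diameter_mm mm or `NA`.
#' @param stability `"stable"` or `"unstable"`.
#' @param icrs_class `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param recommended_procedure `"reconstruction"`, `"drilling"`,
#'   `"free_body_removal"` or `"none"`.
#' @return An object of class `cf_report`.
#' @export
lesion_report <- function(findings = list(), ssb_present = FALSE,
                          vertical_diameter_mm = NA_real_,
                          horizontal_diameter_mm = NA_real_,
                          stability = c("stable", "unstable"),
                          icrs_class = c("I", "II", "III", "IV"),
                          recommended_procedure = c("none",
                            "reconstruction", "drilling",
                            "free_body_removal")) {
  stability <- match.arg(stability)
  icrs_class <- match.arg(icrs_class)
  recommended_procedure <- match.arg(recommended_procedure)
  stopifnot(all(vapply(findings, inherits, TRUE, "cf_finding")))
  if (icrs_class %in% c("III", "IV") && stability != "unstable")
    stop("ICRS class III/IV requires an unstable lesion")
  structure(list(findings = findings, ssb_present = isTRUE(ssb_present),
                 vertical_diameter_mm = vertical_diameter_mm,
                 horizontal_diameter_mm = horizontal_diameter_mm,
                 stability = stability, icrs_class = icrs_class,
                 recommended_procedure = recommended_procedure),
            class = "cf_report")
}

#' @export
print.cf_report <- function(x, ...) {
  kinds <- vapply(x$findings, `[[`, "", "kind")
  cat("<cf_report>\n")
  cat(sprintf("  findings: %s\n",
              if (length(kinds)) paste(kinds, collapse = ", ") else "none"))
  cat(sprintf("  SSB present: %s\n", x$ssb_present))
  cat(sprintf("  diameters (V x H): %s x %s mm\n",
              format(x$vertical_diameter_mm),
              format(x$horizontal_diameter_mm)))
  cat(sprintf("  stability: %s, ICRS class %s, procedure: %s\n",
              x$stability, x$icrs_class, x$recommended_procedure))
  invisible(x)
}

#' Anatomical reference frame of the capitellum
#'
#' Right-handed orthonormal frame spanned by the anteroposterior (AP),
#' proximodistal (PD) and mediolateral (ML) directions, anchored at the
#' capitellar centre. The AP view used for quadrant localization and
#' diameter measurement projects onto the (ML, PD) plane. `ml` points
#' medially, `pd` proximally, `ap` anteriorly; for a left-side elbow the
#' constructor mirrors the supplied ML axis so that the anteromedial
#' quadrant stays area 1.
#'
#' @param origin capitellar centre, mm.
#' @param ap,pd,ml unit direction vectors (orthonormal, right-handed).
#' @param side `"right"` or `"left"`.
#' @return An object of class `cf_frame`.
#' @export
anatomical_frame <- function(origin = c(0, 0, 0), ap = c(0, 0, 1),
                             pd = c(0, 1, 0), ml = c(1, 0, 0),
                             side = c("right", "left")) {
  side <- match.arg(side)
  B <- cbind(ml, pd, ap)
  if (max(abs(crossprod(B) - diag(3))) > 1e-6)
    stop("frame axes must be orthonormal")
  structure(list(origin = as.numeric(origin), ap = as.numeric(ap),
                 pd = as.numeric(pd), ml = as.numeric(ml), side = side),
            class = "cf_frame")
}

#' @export
print.cf_frame <- function(x, ...) {
  cat(sprintf("<cf_frame> %s side, origin (%.2f, %.2f, %.2f) mm\n",
              x$side, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Project points into the frame's anteroposterior view
#'
#' @param frame a `cf_frame`.
#' @param points n x 3 mm matrix.
#' @return n x 2 matrix with columns `u` (mediolateral) and `v`
#'   (proximodistal).
#' @export
project_ap <- function(frame, points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3)
       else as.matrix(points)
  rel <- sweep(p, 2, frame$origin, `-`)
  cbind(u = as.numeric(rel %*% frame$ml),
        v = as.numeric(rel %*% frame$pd))
}

# anteroposterior (depth) coordinate of points in a frame
project_axis <- function(frame, points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3)
       else as.matrix(points)
  as.numeric(sweep(p, 2, frame$origin) %*% frame$ap)
}

#' Rigidly transform an anatomical frame
#' @param frame a `cf_frame`.
#' @param transform a `cf_transform`.
#' @return The transformed frame.
#' @export
transform_frame <- function(frame, transform) {
  anatomical_frame(origin = apply_transform(transform, frame$origin),
                   ap = as.numeric(transform$rotation %*% frame$ap),
                   pd = as.numeric(transform$rotation %*% frame$pd),
                   ml = as.numeric(transform$rotation %*% frame$ml),
                   side = frame$side)
}
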