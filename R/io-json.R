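#' Read and write landmark sets as JSON
#'
#' The schema is `{"frame": "MRI", "points": [{"name", "x", "y", "z"},
#' ...]}`; files listing `frame` per point are also accepted on read.
#'
#' @param set a `cf_landmarks`.
#' @param path file path.
#' @return `read_landmarks` returns a `cf_landmarks`; `write_landmarks`
#'   returns the path invisibly.
#' @export
write_landmarks <- function(set, path) {
  stopifnot(inherits(set, "cf_landmarks"))
  pts <- lapply(seq_len(nrow(set$points)), function(i)
    list(name = rownames(set$points)[i],
         x = set$points[i, 1], y = set$points[i, 2], z = set$points[i, 3]))
  jsonlite::write_json(list(frame = set$frame, points = pts), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- obj$points
  if (is.null(pts)) pts <- obj   # bare array of point objects
  pts <- as.data.frame(pts)
  if (nrow(pts) < 3)
    stop("at least 3 landmarks required, found ", nrow(pts))
  frame <- if (!is.null(obj$frame)) obj$frame
    else if ("frame" %in% names(pts)) pts$frame[1] else "MRI"
  landmark_set(cbind(pts$x, pts$y, pts$z), names = pts$name, frame = frame)
}

#' Serialize a lesion report as versioned JSON
#'
#' Absent diameters (the situation where no cartilage defect or surface
#' deformity leaves anything to measure) serialize as JSON nulls.
#'
#' @param report a `cf_report` from [lesion_report()].
#' @param path file path.
#' @return `read_report` returns a `cf_report`; `write_report` returns
#'   the path invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cf_report"))
  nn <- function(x) if (length(x) == 0 || is.na(x)) NULL else x
  obj <- list(
    schema = "capfuse-lesion-report",
    schema_version = "1.0",
    findings = lapply(report$findings, function(f)
      list(kind = f$kind,
           areas = as.integer(f$areas),
           asd_subtype = if (is.null(f$asd_subtype)) NULL else f$asd_subtype,
           ssb_underneath = isTRUE(f$ssb_underneath))),
    ssb_present = report$ssb_present,
    vertical_diameter_mm = nn(report$vertical_diameter_mm),
    horizontal_diameter_mm = nn(report$horizontal_diameter_mm),
    stability = report$stability,
    icrs_class = report$icrs_class,
    recommended_procedure = report$recommended_procedure)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$schema, "capfuse-lesion-report"))
    stop("not a capfuse lesion report: ", path)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  findings <- lapply(obj$findings, function(f)
    finding(kind = f$kind, areas = unlist(f$areas),
            asd_subtype = if (is.null(f$asd_subtype)) NULL
                          else f$asd_subtype,
            ssb_underneath = isTRUE(f$ssb_underneath)))
  lesion_report(findings = findings,
                ssb_present = isTRUE(obj$ssb_present),
                vertical_diameter_mm = num_or_na(obj$vertical_diameter_mm),
                horizontal_diameter_mm =
                  num_or_na(obj$horizontal_diameter_mm),
                stability = obj$stability,
                icrs_class = obj$icrs_class,
                recommended_procedure = obj$recommended_procedure)
}
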