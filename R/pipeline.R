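#' Default per-stage parameters for a case evaluation
#'
#' Intensity windows match the phantom's synthetic intensity classes by
#' default and should be adjusted per scanner for real data, exactly as
#' operator-set thresholds would be.
#'
#' @param mri_bone,mri_cartilage,ct_bone intensity windows.
#' @param min_component_mm3 minimum segmented component volume.
#' @param icp_subsample,icp_max_iter,icp_rel_tol ICP controls.
#' @param h_tol,angle_tol,span_frac,thickness_min,defect_area_min
#'   detector thresholds (mm / degrees / fraction).
#' @param sclerosis_percentile percentile for sclerosis highlighting.
#' @return Named list of parameters.
#' @export
case_params <- function(mri_bone = c(40, 140),
                        mri_cartilage = c(150, 1e6),
                        ct_bone = c(500, 1e6),
                        min_component_mm3 = 30,
                        icp_subsample = 1500, icp_max_iter = 50,
                        icp_rel_tol = 1e-6,
                        h_tol = 0.5, angle_tol = 30, span_frac = 0.8,
                        thickness_min = 0.5, defect_area_min = 5,
                        sclerosis_percentile = 90) {
  as.list(environment())
}

#' Evaluate one MRI/CT case end to end
#'
#' Runs the full evaluation chain: threshold segmentation of bone and
#' cartilage, iso-surface reconstruction, landmark registration refined
#' by ICP, fusion-scene assembly with the SSB overlay, finding
#' detection, quadrant localization, diameter measurement, and the
#' stability/ICRS rules, producing a [lesion_report()].
#'
#' @param mri,ct `cf_volume`s.
#' @param landmarks_mri,landmarks_ct corresponding [landmark_set()]s.
#' @param frame [anatomical_frame()] in the MRI frame.
#' @param params a [case_params()] list.
#' @return An object of class `cf_case_eval` with `report`, `scene`,
#'   `transform`, `registration` (rmsd trace), `ellipse`, `findings`
#'   and the masks.
#' @export
evaluate_case <- function(mri, ct, landmarks_mri, landmarks_ct, frame,
                          params = case_params()) {
  p <- params
  mri_bone <- segment_by_threshold(mri,
    threshold_spec(p$mri_bone[1], p$mri_bone[2],
                   min_volume_mm3 = p$min_component_mm3), "humerus")
  cartilage <- segment_by_threshold(mri,
    threshold_spec(p$mri_cartilage[1], p$mri_cartilage[2],
                   min_volume_mm3 = p$min_component_mm3), "cartilage")
  ct_bone <- segment_by_threshold(ct,
    threshold_spec(p$ct_bone[1], p$ct_bone[2],
                   min_volume_mm3 = p$min_component_mm3), "humerus")

  mesh_mri_bone <- extract_surface(mri_bone)
  mesh_mri_bone$label <- "humerus_mri"
  mesh_cart <- extract_surface(cartilage)
  mesh_ct_bone <- extract_surface(ct_bone)

  np <- npoint_register(landmarks_mri, landmarks_ct)
  icp <- icp_refine(mesh_mri_bone, mesh_ct_bone, np$transform,
                    max_iter = p$icp_max_iter, rel_tol = p$icp_rel_tol,
                    subsample = p$icp_subsample)
  transform <- icp$transform

  ssb_mask <- detect_ssb(ct_bone)
  ssb_mesh <- if (any(ssb_mask$data)) extract_surface(ssb_mask) else NULL
  scler <- highlight_sclerosis(ct, ct_bone, p$sclerosis_percentile)

  scene <- build_mcfi(mesh_ct_bone, mesh_mri_bone, mesh_cart,
                      ssb = ssb_mesh, transform = transform,
                      ssb_frame = "CT")
  scene$sclerosis_mask <- scler
  scene$frame <- transform_frame(frame, transform)

  acf <- detect_fissures(cartilage, mri, frame,
                         angle_tol = p$angle_tol,
                         span_frac = p$span_frac)
  asd <- detect_surface_deformity(cartilage, frame, h_tol = p$h_tol,
                                  thickness_min = p$thickness_min)
  acd <- detect_cartilage_defect(cartilage, frame,
                                 thickness_min = p$thickness_min,
                                 area_min = p$defect_area_min)
  findings <- c(acf, asd, acd)

  frame_ct <- transform_frame(frame, transform)
  findings <- lapply(findings, function(f) {
    if (f$kind %in% c("ACF", "ASD") && any(ssb_mask$data)) {
      f_ct <- f
      f_ct$points <- apply_transform(transform, finding_points(f))
      f$ssb_underneath <- ssb_underneath(f_ct, ssb_mask, frame_ct)
    }
    f
  })

  ellipse <- fit_capitellar_ellipse(mesh_cart, frame)
  findings <- lapply(findings, localize_finding, ellipse = ellipse,
                     frame = frame)

  kinds <- vapply(findings, `[[`, "", "kind")
  fp <- do.call(rbind, lapply(findings[kinds %in% c("ASD", "ACD")],
                              finding_points))
  di <- if (is.null(fp)) c(vertical = NA_real_, horizontal = NA_real_)
        else measure_diameters(fp, frame,
                               voxel_correction_mm = mean(mri$spacing))

  stability <- classify_stability(findings)
  icrs <- predict_icrs(findings)
  report <- lesion_report(findings = findings,
                          ssb_present = any(ssb_mask$data),
                          vertical_diameter_mm = di[["vertical"]],
                          horizontal_diameter_mm = di[["horizontal"]],
                          stability = stability, icrs_class = icrs)
  if (!(stability == "unstable" && !is.finite(di[["vertical"]])))
    report$recommended_procedure <- recommend_procedure(report)[1]
  structure(list(report = report, scene = scene, transform = transform,
                 registration = list(npoint_rmsd = np$rmsd,
                                     icp_trace = icp$trace),
                 ellipse = ellipse, findings = findings,
                 masks = list(mri_bone = mri_bone, cartilage = cartilage,
                              ct_bone = ct_bone, ssb = ssb_mask,
                              sclerosis = scler)),
            class = "cf_case_eval")
}

#' @export
print.cf_case_eval <- function(x, ...) {
  cat("<cf_case_eval>\n")
  cat(sprintf("  registration: landmark rmsd %.3f mm, ICP final rmsd %.3f mm (%d iterations)\n",
              x$registration$npoint_rmsd,
              tail(x$registration$icp_trace, 1),
              length(x$registration$icp_trace)))
  print(x$report)
  invisible(x)
}

#' Run the full pipeline from a configuration
#'
#' Drives the stage chain phantom -> segment -> reconstruct -> register
#' -> fuse -> analyze and writes every stage product (volumes,
#' landmarks, transform, meshes, report) under `out_dir`. Stage outputs
#' already present are reused when `resume` is TRUE. Deterministic for
#' a fixed seed.
#'
#' @param config named list (or path to a YAML file) with optional
#'   entries `out_dir`, `seed`, `resume`, `phantom` (arguments to
#'   [phantom_config()]) and `params` (arguments to [case_params()]).
#' @return Invisibly, a list with `report`, `paths` and `seed`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% tempfile("capfuse_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  resume <- isTRUE(config$resume)
  paths <- list(
    mri = file.path(out_dir, "mri.nii.gz"),
    ct = file.path(out_dir, "ct.nii.gz"),
    lm_mri = file.path(out_dir, "landmarks_mri.json"),
    lm_ct = file.path(out_dir, "landmarks_ct.json"),
    transform = file.path(out_dir, "transform.json"),
    cartilage_mesh = file.path(out_dir, "cartilage.ply"),
    ct_bone_mesh = file.path(out_dir, "humerus_ct.stl"),
    report = file.path(out_dir, "report.json"),
    log = file.path(out_dir, "pipeline_log.json"))

  pc_args <- config$phantom %||% list()
  pc_args$seed <- seed
  pc <- do.call(phantom_config, pc_args)
  log <- list(seed = seed, stages = list())

  stage_done <- function(stage, ...) {
    log$stages[[stage]] <<- list(time = format(Sys.time()), ...)
  }

  if (resume && all(file.exists(paths$mri, paths$ct, paths$lm_mri,
                                paths$lm_ct))) {
    mri <- read_volume(paths$mri, modality = "MRI")
    ct <- read_volume(paths$ct, modality = "CT")
    lm_mri <- read_landmarks(paths$lm_mri)
    lm_ct <- read_landmarks(paths$lm_ct)
    frame <- anatomical_frame()
    stage_done("phantom", cached = TRUE)
  } else {
    ph <- generate_phantom(pc)
    mri <- ph$mri; ct <- ph$ct
    lm_mri <- ph$landmarks_mri; lm_ct <- ph$landmarks_ct
    frame <- ph$truth$anatomical_frame
    write_volume(mri, paths$mri)
    write_volume(ct, paths$ct)
    write_landmarks(lm_mri, paths$lm_mri)
    write_landmarks(lm_ct, paths$lm_ct)
    stage_done("phantom", cached = FALSE, seed = seed)
  }

  if (is.null(lm_mri) || !file.exists(paths$lm_mri))
    stop("pipeline stage 'register' failed: missing landmarks file ",
         paths$lm_mri)

  prm <- do.call(case_params, config$params %||% list())
  ev <- evaluate_case(mri, ct, lm_mri, lm_ct, frame, prm)
  stage_done("segment")
  stage_done("reconstruct")
  write_transform(ev$transform, paths$transform)
  stage_done("register",
             icp_iterations = length(ev$registration$icp_trace))
  write_mesh(ev$scene$models$cartilage, paths$cartilage_mesh)
  write_mesh(ev$scene$models$humerus_ct, paths$ct_bone_mesh)
  stage_done("fuse")
  write_report(ev$report, paths$report)
  stage_done("analyze", icrs = ev$report$icrs_class)

  jsonlite::write_json(log, paths$log, auto_unbox = TRUE, digits = NA)
  invisible(list(report = ev$report, evaluation = ev, paths = paths,
                 seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
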