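# shared fused scene with resected lesion, built once
.sim_cache <- new.env(parent = emptyenv())

sim_scene <- function() {
  if (is.null(.sim_cache$scene)) {
    ph <- default_phantom()
    ev <- evaluate_case(ph$mri, ph$ct, ph$landmarks_mri,
                        ph$landmarks_ct, default_frame())
    fp_ct <- apply_transform(ev$transform, ph$truth$lesion_footprint)
    .sim_cache$scene <- simulate_resection(ev$scene, fp_ct,
                                           ev$scene$frame)
    .sim_cache$ev <- ev
    .sim_cache$ph <- ph
  }
  .sim_cache
}

cap_pose <- function(frame, uv = c(0, 3.4), R = 13.2) {
  centre <- frame$origin + frame$ml * uv[1] + frame$pd * uv[2] +
    frame$ap * sqrt(R^2 - sum(uv^2))
  rigid_transform(cbind(frame$ml, frame$pd, frame$ap), centre)
}

test_that("graft templates have the right analytic volumes", {
  gc <- make_costal_graft(15, 10, 8, 2)
  expect_lt(abs(mesh_volume(gc$mesh) / (15 * 10 * 8) - 1), 0.02)
  g5 <- make_cylindrical_graft(5, 12)
  expect_lt(abs(mesh_volume(g5$mesh) / (pi * 2.5^2 * 12) - 1), 0.02)
  g7 <- make_cylindrical_graft(7, 12)
  expect_lt(abs(mesh_volume(g7$mesh) / (pi * 3.5^2 * 12) - 1), 0.02)
  expect_error(make_costal_graft(0, 10, 8), "positive")
  expect_error(make_cylindrical_graft(6), "catalog")
  expect_s3_class(make_cylindrical_graft(6, catalog = NULL), "cf_graft")
})

test_that("resection hides the lesion and can be toggled back", {
  sc <- sim_scene()$scene
  expect_false(sc$models$resection$visible)
  expect_gt(nrow(sc$models$resection$faces), 0)
  restored <- sc
  restored$models$resection$visible <- TRUE
  vis <- vapply(restored$models, `[[`, TRUE, "visible")
  expect_true(vis[["resection"]])
  # resection captured at least 95% of the faces over the true footprint
  ph <- sim_scene()$ph
  ev <- sim_scene()$ev
  cart_full <- extract_surface(segment_phantom_cartilage(ph))
  fp <- ph$truth$lesion_footprint
  uv_fp <- capfuse:::project_ap(default_frame(), fp)
  hull <- grDevices::chull(uv_fp[, 1], uv_fp[, 2])
  cent <- (cart_full$vertices[cart_full$faces[, 1], ] +
           cart_full$vertices[cart_full$faces[, 2], ] +
           cart_full$vertices[cart_full$faces[, 3], ]) / 3
  uv_c <- capfuse:::project_ap(default_frame(), cent)
  n_true <- sum(capfuse:::point_in_polygon(uv_c[, 1], uv_c[, 2],
                                           uv_fp[hull, 1],
                                           uv_fp[hull, 2]))
  expect_gte(nrow(sc$models$resection$faces) / n_true, 0.95)
  expect_error(simulate_resection(sc, matrix(numeric(0), 0, 3),
                                  sc$frame), "empty footprint")
})

test_that("graft coverage matches the voxel-counting oracle", {
  sc <- sim_scene()$scene
  fr <- sc$frame
  g7 <- make_cylindrical_graft(7)
  pose <- cap_pose(fr)
  pr <- place_graft(sc, g7, pose)
  orac <- coverage_oracle(sc$resection_footprint, fr, list(g7),
                          list(pose))
  expect_lt(abs(pr$coverage_fraction - orac), 0.02)

  # two cylinders side by side (a two-graft reconstruction plan)
  g5 <- make_cylindrical_graft(5)
  pose2 <- cap_pose(fr, uv = c(0, 8.2))
  pr2 <- place_graft(sc, list(g7, g5), list(pose, pose2))
  orac2 <- coverage_oracle(sc$resection_footprint, fr, list(g7, g5),
                           list(pose, pose2))
  expect_lt(abs(pr2$coverage_fraction - orac2), 0.02)
  # coverage grows monotonically with added grafts
  expect_gte(pr2$coverage_fraction, pr$coverage_fraction - 1e-9)

  # a graft translated fully off the footprint covers nothing
  off_pose <- rigid_transform(pose$rotation,
                              pose$translation + 60 * fr$ml)
  expect_warning(pr0 <- place_graft(sc, g7, off_pose), "outside")
  expect_equal(pr0$coverage_fraction, 0)

  # a block congruent with the footprint covers it completely
  big <- make_costal_graft(24, 24, 8, 2)
  prf <- place_graft(sc, big, cap_pose(fr, uv = c(0, 3.4), R = 14.5))
  expect_gte(prf$coverage_fraction, 0.98)
})

test_that("coverage agrees with the oracle across random poses", {
  sc <- sim_scene()$scene
  fr <- sc$frame
  set.seed(17)
  g <- make_cylindrical_graft(7)
  for (i in 1:12) {
    uv <- runif(2, -4, 4) + c(0, 3.4)
    tilt <- rotation_about_axis(rnorm(3), runif(1, 0, 15))
    base <- cap_pose(fr, uv = uv, R = runif(1, 12.5, 14.5))
    pose <- rigid_transform(base$rotation %*% tilt, base$translation)
    pr <- place_graft(sc, g, pose)
    orac <- coverage_oracle(sc$resection_footprint, fr, list(g),
                            list(pose))
    expect_lt(abs(pr$coverage_fraction - orac), 0.02)
  }
})

test_that("placement metrics are invariant under whole-scene motion", {
  sc <- sim_scene()$scene
  fr <- sc$frame
  g <- make_cylindrical_graft(7)
  pose <- cap_pose(fr)
  pr1 <- place_graft(sc, g, pose)
  move <- rigid_transform(rotation_about_axis(c(2, -1, 1), 25),
                          c(12, -7, 30))
  sc2 <- sc
  for (nm in names(sc2$models))
    sc2$models[[nm]] <- transform_mesh(sc2$models[[nm]], move)
  sc2$resection_footprint <- apply_transform(move,
                                             sc$resection_footprint)
  sc2$frame <- transform_frame(fr, move)
  pr2 <- place_graft(sc2, g, compose_transforms(move, pose))
  expect_equal(pr2$coverage_fraction, pr1$coverage_fraction,
               tolerance = 0.01)
  expect_equal(pr2$step_off_mm, pr1$step_off_mm, tolerance = 0.05)
  expect_equal(pr2$seat_depth_mm, pr1$seat_depth_mm, tolerance = 0.05)
})

test_that("drill plans detect cartilage breach and sclerosis transit", {
  sc <- sim_scene()$ev$scene
  fr <- sc$frame
  target <- fr$origin + fr$ap * 4 + fr$pd * 1
  entry_post <- fr$origin - fr$ap * 11.5 + fr$pd * 1
  pa <- plan_drilling(sc, entry_post, target, "posteroanterior")
  expect_false(pa$cartilage_breach)
  expect_false(pa$invalid)
  expect_true(pa$sclerosis_penetrated)
  expect_equal(sqrt(sum(pa$direction^2)), 1, tolerance = 1e-9)
  expect_equal(pa$depth_mm, sqrt(sum((target - entry_post)^2)),
               tolerance = 1e-9)

  ap <- plan_drilling(sc, fr$origin + fr$ap * 16, target,
                      "anteroposterior")
  expect_true(ap$cartilage_breach)
  expect_false(ap$invalid)

  pa_bad <- plan_drilling(sc, fr$origin + fr$ap * 16, target,
                          "posteroanterior")
  expect_true(pa_bad$invalid)

  outside <- fr$origin + fr$ap * 40
  expect_error(plan_drilling(sc, entry_post, outside, "posteroanterior"),
               "outside the bone")
})
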