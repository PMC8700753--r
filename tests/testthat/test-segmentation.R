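test_that("threshold segmentation recovers the phantom cartilage", {
  ph <- noiseless_phantom()
  cart <- segment_phantom_cartilage(ph)
  # truth mask: voxels whose centre lies in the analytic cartilage shell
  P <- voxel_grid_world(ph$mri)
  truth_int <- capfuse:::phantom_intensity(P, ph$config, "MRI")
  truth <- label_mask(array(as.integer(truth_int == 200),
                            dim(ph$mri$data)), ph$mri, "cartilage")
  expect_gte(mask_dice(cart, truth), 0.95)
})

test_that("threshold edge cases: empty windows and min-volume filtering", {
  ph <- noiseless_phantom()
  expect_warning(
    m <- segment_by_threshold(ph$mri, threshold_spec(5000, 6000)),
    "empty mask")
  expect_equal(sum(m$data), 0)
  expect_warning(
    m2 <- segment_by_threshold(ph$mri,
      threshold_spec(150, 1e6, min_volume_mm3 = 1e9)),
    "empty mask")
  expect_equal(sum(m2$data), 0)
})

test_that("fissure detector finds penetrating slabs and rejects others", {
  ph <- default_phantom()
  fr <- default_frame()
  cart <- segment_phantom_cartilage(ph)
  acf <- detect_fissures(cart, ph$mri, fr)
  expect_length(acf, 1)
  expect_identical(acf[[1]]$kind, "ACF")

  tang <- generate_phantom(phantom_config(
    fissure_orientation = "tangential", protrusion_height_mm = 0,
    seed = 31))
  cart_t <- segment_phantom_cartilage(tang)
  expect_length(detect_fissures(cart_t, tang$mri, fr), 0)

  cart_c <- segment_phantom_cartilage(clean_phantom())
  expect_length(detect_fissures(cart_c, clean_phantom()$mri, fr), 0)
})

test_that("surface deformity detector separates protrusion/flattening", {
  fr <- default_frame()
  asd_p <- detect_surface_deformity(
    segment_phantom_cartilage(default_phantom()), fr)
  expect_length(asd_p, 1)
  expect_identical(asd_p[[1]]$asd_subtype, "protrusion")

  flat <- generate_phantom(phantom_config(
    flattening_depth_mm = 1.5, protrusion_height_mm = 0,
    fissure_enabled = FALSE, seed = 32))
  asd_f <- detect_surface_deformity(segment_phantom_cartilage(flat), fr)
  expect_length(asd_f, 1)
  expect_identical(asd_f[[1]]$asd_subtype, "flattening")

  expect_length(detect_surface_deformity(
    segment_phantom_cartilage(clean_phantom()), fr), 0)
})

test_that("cartilage defect detector finds craters, not intact caps", {
  fr <- default_frame()
  acd <- detect_cartilage_defect(
    segment_phantom_cartilage(defect_phantom()), fr)
  expect_length(acd, 1)
  expect_identical(acd[[1]]$kind, "ACD")
  expect_length(detect_cartilage_defect(
    segment_phantom_cartilage(clean_phantom()), fr), 0)
})

test_that("SSB requires discontinuity in all three planes", {
  bone_full <- segment_phantom_ct_bone(default_phantom())
  ssb <- detect_ssb(bone_full)
  truth <- default_phantom()$truth$fragment_mask
  expect_gte(sum(ssb$data & truth$data) / sum(truth$data), 0.9)

  # a bone bridge in one plane keeps the fragment attached: no SSB
  bone_bridge <- segment_phantom_ct_bone(bridge_phantom())
  expect_equal(sum(detect_ssb(bone_bridge)$data), 0)

  bone_clean <- segment_phantom_ct_bone(clean_phantom())
  expect_equal(sum(detect_ssb(bone_clean)$data), 0)
})

test_that("SSB detection is invariant to axis permutation", {
  ph <- default_phantom()
  bone <- segment_phantom_ct_bone(ph)
  ssb0 <- detect_ssb(bone)
  perm <- c(3, 1, 2)
  vol_p <- image_volume(aperm(ph$ct$data, perm),
                        spacing = ph$ct$spacing[perm],
                        modality = "CT")
  bone_p <- label_mask(aperm(bone$data, perm), vol_p, "humerus")
  ssb_p <- detect_ssb(bone_p)
  expect_identical(aperm(ssb0$data, perm), ssb_p$data)
})

test_that("sclerosis highlighting overlaps the true rim", {
  ph <- default_phantom()
  bone <- segment_phantom_ct_bone(ph)
  scl <- highlight_sclerosis(ph$ct, bone, 90)
  truth <- ph$truth$sclerosis_mask
  expect_gte(sum(scl$data & truth$data) / sum(truth$data), 0.8)
  expect_equal(sum(highlight_sclerosis(ph$ct, bone, 100)$data), 0)
  # a CT without a sclerotic class yields no coherent component overlap
  ph0 <- clean_phantom()
  bone0 <- segment_phantom_ct_bone(ph0)
  scl0 <- highlight_sclerosis(ph0$ct, bone0, 90)
  expect_lt(sum(scl0$data) / sum(bone0$data), 0.05)
})

test_that("radial projection decides whether SSB lies under a finding", {
  ph <- default_phantom()
  fr <- default_frame()
  bone <- segment_phantom_ct_bone(ph)
  ssb <- detect_ssb(bone)
  # express mask and finding in the same (CT) frame
  fr_ct <- transform_frame(fr, ph$config$true_transform)
  over <- finding("ACF", points = apply_transform(
    ph$config$true_transform, ph$truth$lesion_footprint))
  expect_true(ssb_underneath(over, ssb, fr_ct))
  # a finding patch far from the fragment's radial shadow
  R_s <- 13.2
  far_uv <- cbind(runif(30, -7.5, -6.5), runif(30, -7.5, -6.5))
  far <- cbind(far_uv, sqrt(R_s^2 - rowSums(far_uv^2)))
  away <- finding("ACF", points = apply_transform(
    ph$config$true_transform, far))
  expect_false(ssb_underneath(away, ssb, fr_ct))
  empty <- label_mask(array(0L, dim(ph$ct$data)), ph$ct, "ssb")
  expect_false(ssb_underneath(over, empty, fr_ct))
})

test_that("detectors are deterministic and match truth on noiseless data", {
  ph <- noiseless_phantom()
  fr <- default_frame()
  cart <- segment_phantom_cartilage(ph)
  a1 <- detect_fissures(cart, ph$mri, fr)
  a2 <- detect_fissures(cart, ph$mri, fr)
  expect_identical(a1, a2)
  kinds_truth <- sort(vapply(ph$truth$true_findings, `[[`, "", "kind"))
  asd <- detect_surface_deformity(cart, fr)
  acd <- detect_cartilage_defect(cart, fr)
  kinds_det <- sort(vapply(c(a1, asd, acd), `[[`, "", "kind"))
  expect_identical(kinds_det, kinds_truth)
})
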