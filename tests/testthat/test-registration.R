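test_that("landmark registration is exact on noiseless correspondences", {
  set.seed(5)
  src <- matrix(rnorm(12, sd = 10), 4, 3)
  reg_id <- npoint_register(src, src)
  expect_lt(max(abs(reg_id$transform$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(reg_id$transform$translation)), 1e-9)
  expect_lt(reg_id$rmsd, 1e-12)

  truth <- rigid_transform(rotation_about_axis(rnorm(3), 17), c(3, -2, 5))
  dst <- apply_transform(truth, src)
  reg <- npoint_register(src, dst)
  # forward-transform oracle: apply the candidate to src, compare to dst
  expect_lt(max(abs(apply_transform(reg$transform, src) - dst)), 1e-9)
  # composition with the inverse is identity
  comp <- compose_transforms(invert_transform(truth), reg$transform)
  expect_lt(max(abs(comp$rotation - diag(3))), 1e-9)
})

test_that("landmark registration rejects invalid inputs distinctly", {
  a <- matrix(rnorm(12), 4, 3)
  expect_error(npoint_register(a, a[1:3, ]), "count mismatch")
  expect_error(npoint_register(a[1:2, ], a[1:2, ]), "at least 3")
  line <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(npoint_register(line, line), "collinear")
})

test_that("ICP is a fixed point on aligned meshes and refines small offsets", {
  ph <- default_phantom()
  mesh <- extract_surface(segment_phantom_ct_bone(ph))
  res0 <- icp_refine(mesh, mesh, rigid_transform(), max_iter = 10)
  expect_lt(max(abs(res0$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(res0$transform$translation)), 1e-6)
  expect_lte(length(res0$trace), 3)

  init <- rigid_transform(rotation_about_axis(c(1, 1, 0), 2), c(1, 0, -0.5))
  res <- icp_refine(mesh, mesh, init)
  expect_lt(rotation_angle_deg(res$transform$rotation), 0.1)
  expect_lt(sqrt(sum(res$transform$translation^2)), 0.05)
  # rmsd trace is monotone non-increasing
  expect_true(all(diff(res$trace) <= 1e-9))
})

test_that("non-finite vertices are rejected by ICP", {
  bad <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                  rbind(c(1, 2, 3)))
  bad$vertices[1, 1] <- NaN
  good <- make_cylindrical_graft(5)$mesh
  expect_error(icp_refine(bad, good), "non-finite")
})

test_that("fusion preserves the rigid cartilage-humerus link", {
  ph <- default_phantom()
  mri_bone <- extract_surface(segment_phantom_cartilage(ph))
  mri_bone$label <- "humerus_mri"
  cart <- extract_surface(segment_phantom_cartilage(ph))
  ct_bone <- extract_surface(segment_phantom_ct_bone(ph))
  tr <- ph$config$true_transform
  set.seed(8)
  pick_c <- sample(nrow(cart$vertices), 50)
  pick_h <- sample(nrow(mri_bone$vertices), 50)
  before <- sqrt(rowSums((cart$vertices[pick_c, ] -
                          mri_bone$vertices[pick_h, ])^2))
  scene <- build_mcfi(ct_bone, mri_bone, cart, transform = tr)
  after <- sqrt(rowSums((scene$models$cartilage$vertices[pick_c, ] -
                         scene$models$humerus_mri$vertices[pick_h, ])^2))
  expect_lt(max(abs(before - after)), 1e-9)
  # identity transform leaves the cartilage untouched
  scene_id <- build_mcfi(ct_bone, mri_bone, cart,
                         transform = rigid_transform())
  expect_equal(scene_id$models$cartilage$vertices, cart$vertices)
  # MRI humerus hidden, SSB red, CT humerus required
  ssb <- make_cylindrical_graft(5)$mesh
  scene_s <- build_mcfi(ct_bone, mri_bone, cart, ssb = ssb,
                        transform = tr)
  expect_false(scene_s$models$humerus_mri$visible)
  expect_equal(scene_s$models$ssb$color, c(1, 0, 0))
  expect_error(build_mcfi(NULL, mri_bone, cart, transform = tr),
               "CT humerus")
})

test_that("transparency control edits exactly one model", {
  ph <- default_phantom()
  mesh <- extract_surface(segment_phantom_ct_bone(ph))
  cart <- extract_surface(segment_phantom_cartilage(ph))
  mri <- mesh; mri$label <- "humerus_mri"
  ssb <- make_cylindrical_graft(5)$mesh
  scene <- build_mcfi(mesh, mri, cart, ssb = ssb,
                      transform = rigid_transform())
  s2 <- set_transparency(scene, "cartilage", 0.3)
  expect_equal(s2$models$cartilage$transparency, 0.3)
  expect_equal(s2$models$ssb$transparency, 1)
  s3 <- set_transparency(scene, "cartilage", 0)
  expect_false(s3$models$cartilage$visible)
  expect_error(set_transparency(scene, "cartilage", 1.5), "alpha")
  expect_error(set_transparency(scene, "nope", 0.5), "no model")
})
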