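make_sphere_mask <- function(R = 10, spacing = 0.5, pad = 2) {
  n <- ceiling(2 * (R + pad) / spacing)
  vol <- image_volume(array(0, c(n, n, n)), spacing = rep(spacing, 3),
                      origin = rep(-(n - 1) * spacing / 2, 3),
                      modality = "CT")
  P <- voxel_grid_world(vol)
  label_mask(array(as.integer(rowSums(P^2) <= R^2), dim(vol$data)),
             vol, "humerus")
}

test_that("iso-surface of a voxelized sphere matches analytic area", {
  m <- make_sphere_mask(10, 0.5)
  mesh <- extract_surface(m)
  expect_lt(abs(mesh_area(mesh) / (4 * pi * 100) - 1), 0.05)
  expect_lt(abs(mesh_volume(mesh) / (4 / 3 * pi * 1000) - 1), 0.05)
  expect_true(capfuse:::mesh_is_closed(mesh))
})

test_that("a single-voxel mask produces a closed positive-volume mesh", {
  vol <- image_volume(array(0, c(9, 9, 9)), modality = "CT")
  arr <- array(0L, c(9, 9, 9))
  arr[5, 5, 5] <- 1L
  mesh <- extract_surface(label_mask(arr, vol, "humerus"))
  expect_true(capfuse:::mesh_is_closed(mesh))
  expect_gt(mesh_volume(mesh), 0)
  empty <- label_mask(array(0L, c(9, 9, 9)), vol, "humerus")
  expect_error(extract_surface(empty), "empty mask")
})

test_that("Taubin smoothing preserves volume", {
  m <- make_sphere_mask(8, 0.5)
  mesh <- extract_surface(m)
  expect_identical(smooth_mesh(mesh, 0), mesh)
  sm <- smooth_mesh(mesh, 20)
  expect_lt(abs(mesh_volume(sm) / mesh_volume(mesh) - 1), 0.01)
  expect_error(smooth_mesh(mesh, -1), "iterations")
})

test_that("separate_region partitions faces conservatively", {
  ph <- default_phantom()
  fr <- default_frame()
  cart <- extract_surface(segment_phantom_cartilage(ph))
  fp <- ph$truth$lesion_footprint
  parts <- separate_region(cart, fp, fr)
  expect_equal(nrow(parts$resection$faces) + nrow(parts$remainder$faces),
               nrow(cart$faces))
  expect_equal(mesh_area(parts$resection) + mesh_area(parts$remainder),
               mesh_area(cart), tolerance = 1e-6)

  # footprint covering the whole mesh: remainder is empty
  big <- cbind(c(-50, 50, 50, -50), c(-50, -50, 50, 50), c(13, 13, 13, 13))
  all_in <- separate_region(cart, big, fr)
  expect_equal(nrow(all_in$remainder$faces), 0L)
  expect_error(separate_region(cart, matrix(numeric(0), 0, 3), fr),
               "empty footprint")
})

test_that("resection area matches the analytic footprint patch area", {
  # the resected piece of the cartilage shell contains the outer and
  # inner surface patches over the footprint; compare against the
  # numerically integrated spherical patch areas (independent oracle)
  ph <- clean_phantom()
  fr <- default_frame()
  cart <- extract_surface(segment_phantom_cartilage(ph))
  g <- capfuse:::phantom_geometry(ph$config)
  parts <- separate_region(cart, ph$truth$lesion_footprint, fr)
  expected <- spherical_patch_area(g$R_s, g$centre_uv,
                                   c(g$semi_h, g$semi_v)) +
    spherical_patch_area(g$R_b, g$centre_uv, c(g$semi_h, g$semi_v))
  expect_lt(abs(mesh_area(parts$resection) / expected - 1), 0.1)
})

test_that("surface extraction recovers footprint diameters within a voxel", {
  ph <- defect_phantom()
  fr <- default_frame()
  cart <- segment_phantom_cartilage(ph)
  acd <- detect_cartilage_defect(cart, fr)
  expect_length(acd, 1)
  d <- measure_diameters(acd[[1]], fr,
                         voxel_correction_mm = mean(ph$mri$spacing))
  expect_lt(abs(d[["vertical"]] - ph$truth$true_vertical_diameter), 1)
  expect_lt(abs(d[["horizontal"]] - ph$truth$true_horizontal_diameter), 1)
})
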