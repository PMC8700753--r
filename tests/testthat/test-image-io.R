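test_that("NIfTI and NRRD volume writers round-trip data and geometry", {
  set.seed(1)
  v <- image_volume(array(rnorm(3 * 4 * 5), c(3, 4, 5)),
                    spacing = c(0.4, 0.5, 0.6), origin = c(1, -2, 3),
                    modality = "MRI")
  for (ext in c(".nii.gz", ".nrrd")) {
    f <- tempfile(fileext = ext)
    write_volume(v, f)
    v2 <- read_volume(f, modality = "MRI")
    expect_equal(v2$data, v$data, tolerance = 1e-6)
    expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)
    expect_equal(v2$origin, v$origin, tolerance = 1e-6)
    expect_equal(v2$axes, v$axes, tolerance = 1e-6)
  }
  expect_error(read_volume(tempfile(fileext = ".nrrd")), "no such file")
})

test_that("integer mask volumes round-trip bit-exactly through NRRD", {
  m <- array(as.integer(runif(4 * 4 * 4) > 0.5), c(4, 4, 4))
  v <- image_volume(m, spacing = c(1, 1, 1), modality = "CT")
  f <- tempfile(fileext = ".nrrd")
  write_volume(v, f)
  expect_identical(read_volume(f)$data == 1, v$data == 1)
})

test_that("DICOM series reading recovers geometry and pixel data", {
  dir <- tempfile()
  dir.create(dir)
  set.seed(2)
  arr <- array(sample.int(900, 16 * 12 * 6, replace = TRUE), c(16, 12, 6))
  for (k in seq_len(6))
    capfuse:::write_dicom_slice(file.path(dir, sprintf("s%02d.dcm", k)),
                                arr[, , k],
                                position_lps = c(-4, -3, (k - 1) * 0.5),
                                spacing_rc = c(0.7, 0.6))
  v <- read_dicom_series(dir, "CT")
  expect_equal(dim(v$data), c(16L, 12L, 6L))
  # slice pitch of 0.5 mm becomes the through-plane spacing
  expect_equal(v$spacing[3], 0.5, tolerance = 1e-9)
  expect_equal(v$spacing[1:2], c(0.6, 0.7), tolerance = 1e-9)
  expect_equal(max(abs(v$data - arr)), 0)
  # LPS position (-4, -3, 0) converts to RAS (4, 3, 0)
  expect_equal(v$origin, c(4, 3, 0), tolerance = 1e-9)
})

test_that("a directory mixing DICOM series is rejected listing the UIDs", {
  dir <- tempfile()
  dir.create(dir)
  px <- matrix(1L, 8, 8)
  capfuse:::write_dicom_slice(file.path(dir, "a.dcm"), px, c(0, 0, 0),
                              c(1, 1), series_uid = "1.2.3")
  capfuse:::write_dicom_slice(file.path(dir, "b.dcm"), px, c(0, 0, 1),
                              c(1, 1), series_uid = "4.5.6")
  expect_error(read_dicom_series(dir), "1\\.2\\.3.*4\\.5\\.6")
})

test_that("landmark JSON round-trips and enforces the 3-point minimum", {
  lm <- landmark_set(rbind(c(1, 0, 0), c(0, 2, 0), c(0, 0, 3),
                           c(1, 1, 1)),
                     names = c("a", "b", "c", "d"), frame = "CT")
  f <- tempfile(fileext = ".json")
  write_landmarks(lm, f)
  lm2 <- read_landmarks(f)
  expect_equal(unname(lm2$points), unname(lm$points), tolerance = 1e-12)
  expect_identical(rownames(lm2$points), rownames(lm$points))
  expect_identical(lm2$frame, "CT")
  # a 4-point set (the usual protocol) is accepted as-is
  expect_equal(nrow(lm2$points), 4L)
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(list(frame = "MRI", points = list(
    list(name = "a", x = 1, y = 0, z = 0),
    list(name = "b", x = 0, y = 1, z = 0))), f2, auto_unbox = TRUE)
  expect_error(read_landmarks(f2), "at least 3")
  expect_error(landmark_set(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "collinear")
})

test_that("lesion reports serialize with nulls for absent diameters", {
  rep1 <- lesion_report(
    findings = list(finding("ACF", areas = c(1, 2),
                            ssb_underneath = TRUE),
                    finding("ASD", areas = 2:3,
                            asd_subtype = "protrusion",
                            ssb_underneath = TRUE)),
    ssb_present = TRUE, vertical_diameter_mm = 14.8,
    horizontal_diameter_mm = 13.1, stability = "unstable",
    icrs_class = "III")
  f <- tempfile(fileext = ".json")
  write_report(rep1, f)
  back <- read_report(f)
  expect_identical(back$icrs_class, "III")
  expect_identical(back$stability, "unstable")
  expect_equal(back$vertical_diameter_mm, 14.8)
  expect_identical(vapply(back$findings, `[[`, "", "kind"),
                   c("ACF", "ASD"))
  expect_identical(back$findings[[2]]$asd_subtype, "protrusion")

  # no measurable lesion: diameters serialize as null and read back NA
  rep2 <- lesion_report(findings = list(finding("ACF", areas = 1)),
                        stability = "stable", icrs_class = "II")
  f2 <- tempfile(fileext = ".json")
  write_report(rep2, f2)
  txt <- paste(readLines(f2), collapse = "")
  expect_match(txt, "\"vertical_diameter_mm\":null")
  expect_true(is.na(read_report(f2)$vertical_diameter_mm))
  expect_error(lesion_report(icrs_class = "V"), "arg")
})

test_that("mesh STL/PLY export round-trips and keeps the SSB color", {
  g <- make_cylindrical_graft(5)
  fs <- tempfile(fileext = ".stl")
  write_mesh(g$mesh, fs)
  m2 <- read_mesh(fs)
  expect_equal(nrow(m2$vertices), nrow(g$mesh$vertices))
  expect_equal(nrow(m2$faces), nrow(g$mesh$faces))
  expect_equal(abs(mesh_volume(m2)), abs(mesh_volume(g$mesh)),
               tolerance = 1e-5)

  ssb <- g$mesh
  ssb$label <- "ssb"
  ssb$color <- c(1, 0, 0)
  fp <- tempfile(fileext = ".ply")
  write_mesh(ssb, fp)
  m3 <- read_mesh(fp)
  expect_equal(m3$color, c(1, 0, 0))
  expect_identical(m3$label, "ssb")

  # unit cube: 8 vertices, 12 faces
  cb <- make_costal_graft(1, 1, 1, 0.2)
  fc <- tempfile(fileext = ".stl")
  write_mesh(cb$mesh, fc)
  cube <- read_mesh(fc)
  expect_equal(nrow(cube$vertices), 8L)
  expect_equal(nrow(cube$faces), 12L)

  empty <- tri_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(write_mesh(empty, tempfile(fileext = ".stl")), "empty")

  open_mesh <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        rbind(c(1, 2, 3)))
  expect_message(write_mesh(open_mesh, tempfile(fileext = ".ply")),
                 "not 2-manifold")
})
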