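test_that("capitellar ellipse fit recovers a projected circle", {
  th <- seq(0, 2 * pi, length.out = 181)[-1]
  pts <- cbind(10 * cos(th), 10 * sin(th), runif(180, 4, 6))
  el <- fit_capitellar_ellipse(pts, default_frame())
  expect_lt(abs(el$a / 10 - 1), 0.01)
  expect_lt(abs(el$b / 10 - 1), 0.01)
  expect_lt(max(abs(el$center)), 0.1)
  expect_error(fit_capitellar_ellipse(matrix(numeric(0), 0, 3),
                                      default_frame()), "few points")
})

test_that("phantom cap ellipse centre lands within a voxel of truth", {
  ph <- default_phantom()
  cart <- extract_surface(segment_phantom_cartilage(ph))
  el <- fit_capitellar_ellipse(cart, default_frame())
  expect_lt(max(abs(el$center)), max(ph$mri$spacing))
})

test_that("area assignment partitions the ellipse with the tie rule", {
  el <- structure(list(center = c(0, 0), a = 10, b = 8, orientation = 0),
                  class = "cf_ellipse")
  fr <- default_frame()
  # quadrants: 1 medial-proximal, 2 lateral-proximal, 3 lateral-distal,
  # 4 medial-distal (clockwise from anteromedial)
  expect_equal(assign_area(c(3, 4, 0), el, fr), 1L)
  expect_equal(assign_area(c(-3, 4, 0), el, fr), 2L)
  expect_equal(assign_area(c(-3, -4, 0), el, fr), 3L)
  expect_equal(assign_area(c(3, -4, 0), el, fr), 4L)
  # boundaries go to the lower-numbered adjacent area; centre is area 1
  expect_equal(assign_area(c(0, 0, 0), el, fr), 1L)
  expect_equal(assign_area(c(0, 5, 0), el, fr), 1L)
  expect_equal(assign_area(c(-5, 0, 0), el, fr), 2L)
  expect_equal(assign_area(c(0, -5, 0), el, fr), 3L)
  expect_equal(assign_area(c(5, 0, 0), el, fr), 1L)
  expect_error(assign_area(c(30, 0, 0), el, fr), "outside")

  # dense grid: every interior point maps to exactly one area and all
  # four areas are hit
  g <- expand.grid(u = seq(-9.5, 9.5, 0.5), v = seq(-7.5, 7.5, 0.5))
  g <- g[(g$u / 10)^2 + (g$v / 8)^2 <= 1, ]
  areas <- vapply(seq_len(nrow(g)), function(i)
    assign_area(c(g$u[i], g$v[i], 0), el, fr), integer(1))
  expect_true(all(areas %in% 1:4))
  expect_setequal(unique(areas), 1:4)
})

test_that("left-right mirroring keeps anteromedial as area 1", {
  el <- structure(list(center = c(0, 0), a = 10, b = 10, orientation = 0),
                  class = "cf_ellipse")
  right <- default_frame()
  left <- anatomical_frame(ml = c(-1, 0, 0), ap = c(0, 0, -1),
                           side = "left")
  p_med_right <- c(3, 4, 0)    # medial for the right side (+x medial)
  p_med_left <- c(-3, 4, 0)    # medial for the left side (-x medial)
  expect_equal(assign_area(p_med_right, el, right), 1L)
  expect_equal(assign_area(p_med_left, el, left), 1L)
})

test_that("finding localization fills quadrant sets", {
  ph <- default_phantom()
  fr <- default_frame()
  cartm <- extract_surface(segment_phantom_cartilage(ph))
  el <- fit_capitellar_ellipse(cartm, fr)
  # the phantom fissure crosses the proximodistal axis: two areas
  acf <- detect_fissures(segment_phantom_cartilage(ph), ph$mri, fr)[[1]]
  acf <- localize_finding(acf, el, fr)
  expect_identical(acf$areas, ph$truth$true_findings[[1]]$areas)
  # a point-like finding maps to a single area
  pt <- finding("ACF", points = matrix(c(3, 4, 11), 1))
  expect_length(localize_finding(pt, el, fr)$areas, 1)
  # a full-cap footprint touches all four areas
  full <- finding("ACD", points = ph$truth$lesion_footprint)
  full$points <- rbind(full$points, full$points %*% diag(c(-1, -1, 1)))
  expect_identical(localize_finding(full, el, fr)$areas, 1:4)
})

test_that("diameters are AP-plane extents with absent-value semantics", {
  fr <- default_frame()
  ph <- default_phantom()
  d <- measure_diameters(ph$truth$lesion_footprint, fr)
  expect_equal(d[["vertical"]], ph$truth$true_vertical_diameter,
               tolerance = 1e-6)
  expect_equal(d[["horizontal"]], ph$truth$true_horizontal_diameter,
               tolerance = 1e-6)
  single <- measure_diameters(matrix(c(1, 2, 3), 1), fr)
  expect_equal(unname(single), c(0, 0))
  none <- measure_diameters(matrix(numeric(0), 0, 3), fr)
  expect_true(all(is.na(none)))
})

test_that("stability rule follows the SSB-underneath definition", {
  acf_ssb <- finding("ACF", areas = 1, ssb_underneath = TRUE)
  acf_free <- finding("ACF", areas = 1, ssb_underneath = FALSE)
  asd_ssb <- finding("ASD", areas = 2:3, asd_subtype = "protrusion",
                     ssb_underneath = TRUE)
  acd <- finding("ACD", areas = 2:3)
  expect_identical(classify_stability(list(acf_ssb, asd_ssb)), "unstable")
  expect_identical(classify_stability(list(acf_free)), "stable")
  expect_identical(classify_stability(list(acd)), "unstable")
  expect_identical(classify_stability(list()), "stable")
})

test_that("ICRS rule reproduces the tabulated class patterns", {
  # defect in areas 2,3 with nothing else: class IV
  expect_identical(predict_icrs(list(finding("ACD", areas = 2:3)),
                                use_ssb = FALSE), "IV")
  # fissures in all areas plus protrusion in 2,3: class III
  expect_identical(predict_icrs(list(
    finding("ACF", areas = 1:4),
    finding("ASD", areas = 2:3, asd_subtype = "protrusion")),
    use_ssb = FALSE), "III")
  # a single area-1 fissure alone: class II
  expect_identical(predict_icrs(list(finding("ACF", areas = 1)),
                                use_ssb = FALSE), "II")
  expect_identical(predict_icrs(list(), use_ssb = FALSE), "I")
})

test_that("stability and ICRS class are consistent on random findings", {
  set.seed(9)
  for (i in 1:200) {
    fs <- list()
    if (runif(1) < 0.5)
      fs <- c(fs, list(finding("ACF", areas = sample(4, 2),
                               ssb_underneath = runif(1) < 0.5)))
    if (runif(1) < 0.5)
      fs <- c(fs, list(finding("ASD", areas = sample(4, 2),
                               asd_subtype = sample(c("protrusion",
                                                      "flattening"), 1),
                               ssb_underneath = runif(1) < 0.5)))
    if (runif(1) < 0.3)
      fs <- c(fs, list(finding("ACD", areas = sample(4, 1))))
    cls <- predict_icrs(fs)
    stab <- classify_stability(fs)
    expect_identical(cls %in% c("III", "IV"), stab == "unstable")
  }
})

test_that("procedure recommendation follows the size/stability rules", {
  rec <- lesion_report(findings = list(finding("ACD", areas = 2:3)),
                       ssb_present = TRUE,
                       vertical_diameter_mm = 14.8,
                       horizontal_diameter_mm = 13.1,
                       stability = "unstable", icrs_class = "IV")
  expect_identical(recommend_procedure(rec), "reconstruction")

  small4 <- lesion_report(findings = list(finding("ACD", areas = 2)),
                          vertical_diameter_mm = 8,
                          horizontal_diameter_mm = 9,
                          stability = "unstable", icrs_class = "IV")
  expect_identical(recommend_procedure(small4), "drilling")

  stable_ref <- lesion_report(findings = list(finding("ACF", areas = 1)),
                              stability = "stable", icrs_class = "II")
  expect_identical(
    recommend_procedure(stable_ref, refractory_to_conservative = TRUE),
    "drilling")
  expect_identical(recommend_procedure(stable_ref), "none")
  expect_identical(
    recommend_procedure(stable_ref, free_bodies = TRUE),
    "free_body_removal")

  no_d <- lesion_report(findings = list(finding("ACD", areas = 1)),
                        stability = "unstable", icrs_class = "IV")
  expect_error(recommend_procedure(no_d), "measure")
})
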