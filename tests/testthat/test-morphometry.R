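# Ring-model morphometry: arithmetic identities, invariances, phantom oracle.

test_that("bone area is pixel count times pixel area, and additive", {
  m <- matrix(0L, 20, 20); m[sample(400, 100)] <- 1L
  expect_equal(bone_area(roi_mask(m, 0.7, "bone")), 100 * 0.49)
  m2 <- matrix(0L, 20, 20); m2[1:10] <- 1L
  m2[m == 1L] <- 0L                      # make disjoint
  u <- matrix(as.integer(m | m2), 20, 20)
  expect_equal(bone_area(u, 0.7),
               bone_area(m, 0.7) + bone_area(m2, 0.7))
  expect_error(bone_area(matrix(0L, 5, 5), 0.7), "empty")
})

test_that("wall thickness is area over centerline length", {
  # the cohort-scale worked example: BA 74.3 mm^2, CL 27.52 mm
  expect_equal(74.3 / 27.52, 2.70, tolerance = 0.002)
  # identity BA = BT * CL holds exactly per slice by construction
  ph <- make_annulus_phantom(phantom_spec())
  sm <- slice_morphometry(ph$image, ph$bone, ph$marrow)
  expect_equal(sm$BA, sm$BT * sm$CL, tolerance = 1e-12)
})

test_that("the diameter-convention g reproduces the ring-model diameter ratio", {
  # centerline diameter 8.2 mm, BT 2.7 mm -> g = 5.5 / 10.9
  cl <- pi * 8.2
  expect_equal(g_ratio(cl, 2.7, "diameter"), 5.5 / 10.9, tolerance = 1e-12)
  # limits: vanishing wall -> 1; wall equal to the centerline diameter -> 0
  expect_equal(g_ratio(cl, 1e-9, "diameter"), 1, tolerance = 1e-6)
  expect_equal(g_ratio(cl, 8.2, "diameter"), 0, tolerance = 1e-12)
  # literal convention applies the raw loop length
  expect_equal(g_ratio(20, 2, "literal"), 18 / 22, tolerance = 1e-12)
})

test_that("MPI of a uniform bone region equals its normalized intensity", {
  ph <- make_annulus_phantom(phantom_spec(intensity_bone = 0.12))
  sm <- slice_morphometry(ph$image, ph$bone, ph$marrow)
  # interior bone pixels are exactly 0.12 after normalization; partial-volume
  # rim pixels pull the mean up slightly
  expect_lt(abs(sm$MPI - 0.12), 0.06)
  norm <- fibmorph:::normalize_intensity(ph$image$values)
  interior <- ph$bone$values == 1 &
    fibmorph:::shift_mat(ph$bone$values, 1, 0) == 1 &
    fibmorph:::shift_mat(ph$bone$values, -1, 0) == 1 &
    fibmorph:::shift_mat(ph$bone$values, 0, 1) == 1 &
    fibmorph:::shift_mat(ph$bone$values, 0, -1) == 1
  expect_equal(mean(norm[interior]), 0.12, tolerance = 0.005)
})

test_that("MPI is invariant to global affine intensity rescaling", {
  set.seed(4)
  ph <- make_annulus_phantom(phantom_spec(noise_sd = 0.02))
  sm1 <- slice_morphometry(ph$image, ph$bone, ph$marrow)
  scaled <- slice_image(ph$image$values * 37 + 11, 0.7)
  sm2 <- slice_morphometry(scaled, ph$bone, ph$marrow)
  expect_equal(sm2$MPI, sm1$MPI, tolerance = 1e-10)
})

test_that("subject averaging follows the per-slice mean of BA/CL", {
  set.seed(5)
  st <- make_phantom_stack(phantom_spec(), n_slices = 7, jitter = 0.01)
  sm <- subject_morphometry(st)
  expect_equal(sm$BT, mean(sm$per_slice$BA / sm$per_slice$CL),
               tolerance = 1e-12)
  expect_equal(sm$g, mean(sm$per_slice$g), tolerance = 1e-12)
  expect_equal(sm$n_slices_used, 7L)
  # identical slices give subject values equal to slice values
  st0 <- make_phantom_stack(phantom_spec(), n_slices = 7, jitter = 0)
  sm0 <- subject_morphometry(st0)
  expect_equal(sm0$BT, sm0$per_slice$BT[1], tolerance = 1e-12)
  # plain arithmetic-mean bookkeeping
  expect_equal(mean(c(2, 2, 2, 3, 3, 3, 6)), 3.0)
})

test_that("measurements are scale-equivariant in the pixel spacing", {
  m <- annulus_mask(51, 16, 8)
  sm1 <- slice_morphometry(NULL, roi_mask(m, 0.7, "bone"),
                           roi_mask(annulus_mask(51, 8, 0), 0.7, "marrow"))
  sm2 <- slice_morphometry(NULL, roi_mask(m, 1.4, "bone"),
                           roi_mask(annulus_mask(51, 8, 0), 1.4, "marrow"))
  expect_equal(sm2$CL, 2 * sm1$CL, tolerance = 1e-12)
  expect_equal(sm2$BT, 2 * sm1$BT, tolerance = 1e-12)
  expect_equal(sm2$D_out, 2 * sm1$D_out, tolerance = 1e-12)
  expect_equal(sm2$BA, 4 * sm1$BA, tolerance = 1e-12)
  expect_equal(sm2$BMA, 4 * sm1$BMA, tolerance = 1e-12)
  expect_equal(sm2$g, sm1$g, tolerance = 1e-12)
})

test_that("estimates are robust to a 30-degree rotation of the geometry", {
  # rendered at 0.175 mm so that discretization noise sits below the 2% bound
  base <- phantom_spec(outer_diameter = 10.9, wall_thickness = 2.7,
                       pixel_spacing = 0.175, grid_size = 129L,
                       deformation_harmonics = list(c(3, 0.08, 0.4)))
  rot <- phantom_spec(outer_diameter = 10.9, wall_thickness = 2.7,
                      pixel_spacing = 0.175, grid_size = 129L,
                      deformation_harmonics = list(c(3, 0.08,
                                                     0.4 + 3 * pi / 6)))
  m1 <- with(make_annulus_phantom(base),
             slice_morphometry(image, bone, marrow))
  m2 <- with(make_annulus_phantom(rot),
             slice_morphometry(image, bone, marrow))
  expect_lt(abs(m2$BT - m1$BT) / m1$BT, 0.02)
  expect_lt(abs(m2$g - m1$g) / m1$g, 0.02)
})

test_that("image-mode phantom subject recovers the sampled thickness", {
  set.seed(6)
  st <- make_phantom_stack(phantom_spec(outer_diameter = 2 * 2.5 / (1 - 0.5),
                                        wall_thickness = 2.5,
                                        noise_sd = 0.02),
                           n_slices = 9)
  sm <- subject_morphometry(st)
  expect_lte(abs(sm$BT - 2.5), 0.35)     # half a pixel at 0.7 mm
})

test_that("a wall thicker than the ring model admits is flagged, not clamped", {
  # tiny lumen: skeleton loop around a nearly filled ring
  m <- annulus_mask(41, 14, 2.2)
  sm <- suppressWarnings(
    slice_morphometry(NULL, roi_mask(m, 0.7, "bone")))
  expect_true(sm$flagged || sm$D_in > 0)
  if (sm$D_in <= 0) expect_lt(sm$g, 0)   # reported negative, never clamped
})
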