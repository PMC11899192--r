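# Phantom generator: analytic truth, rendering contracts, cohort sampling.

test_that("undeformed annulus truth matches the closed forms", {
  ph <- make_annulus_phantom(phantom_spec(outer_diameter = 10.9,
                                          wall_thickness = 2.7))
  d_out <- 10.9; d_in <- 10.9 - 2 * 2.7
  expect_equal(ph$truth$true_BT, (d_out - d_in) / 2, tolerance = 1e-4)
  expect_equal(ph$truth$true_g, d_in / d_out, tolerance = 1e-4)
  expect_equal(ph$truth$true_BA, pi * (d_out^2 - d_in^2) / 4,
               tolerance = 1e-4)
  expect_equal(ph$truth$true_BMA, pi * d_in^2 / 4, tolerance = 1e-4)
  expect_equal(ph$truth$true_CL, pi * (d_out + d_in) / 2, tolerance = 1e-4)
})

test_that("g tends to zero as the wall approaches the full radius", {
  g_vals <- vapply(c(2.0, 3.5, 4.5, 5.35), function(bt) {
    spec <- phantom_spec(outer_diameter = 10.9, wall_thickness = bt)
    phantom_truth_g <- make_annulus_phantom(spec)$truth$true_g
  }, numeric(1))
  expect_true(all(diff(g_vals) < 0))
  expect_lt(g_vals[length(g_vals)], 0.05)
})

test_that("deformed-ring area from polygonal integration matches a supersampled pixel count", {
  spec <- phantom_spec(outer_diameter = 10.9, wall_thickness = 2.7,
                       deformation_harmonics = list(c(3, 0.1, 0.7)))
  truth <- make_annulus_phantom(spec)$truth
  oracle <- supersampled_ring_area(spec, factor = 16L)
  expect_lt(abs(truth$true_BA - oracle) / oracle, 0.01)
})

test_that("bone and marrow masks are disjoint and marrow fills the interior", {
  ph <- make_annulus_phantom(phantom_spec(
    deformation_harmonics = list(c(3, 0.08, 0.3))))
  expect_equal(sum(ph$bone$values & ph$marrow$values), 0)
  # every marrow pixel lies inside the ring's interior hole
  filled <- ph$bone$values
  lab <- fibmorph:::label_components(1L - filled, connectivity = 4L)
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                            lab[, ncol(lab)]))
  interior <- !(lab %in% border_labels) & lab > 0
  expect_true(all(interior[ph$marrow$values == 1]))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(wall_thickness = 6, outer_diameter = 10.9),
               "wall_thickness")
  expect_error(phantom_spec(deformation_harmonics = list(c(3, 0.35, 0))),
               "amplitude")
  expect_error(phantom_spec(deformation_harmonics = list(c(1, 0.1, 0))),
               "order")
  expect_error(phantom_spec(noise_sd = -0.1), "noise_sd")
  # self-intersecting inner contour: large deformation on a thick wall
  expect_error(make_annulus_phantom(
    phantom_spec(outer_diameter = 10, wall_thickness = 4,
                 deformation_harmonics = list(c(4, 0.29, 0)))),
    "self-intersect")
  # ring touching the grid boundary
  expect_error(make_annulus_phantom(
    phantom_spec(outer_diameter = 30, wall_thickness = 3, grid_size = 44L)),
    "boundary")
})

test_that("pixel-derived area converges toward the analytic truth with resolution", {
  rel_err <- vapply(c(0.7, 0.35, 0.175), function(sp) {
    gs <- as.integer(ceiling(2 * (10.9 / 2 / sp + 5)))
    ph <- make_annulus_phantom(phantom_spec(outer_diameter = 10.9,
                                            wall_thickness = 2.7,
                                            pixel_spacing = sp,
                                            grid_size = gs))
    abs(bone_area(ph$bone) - ph$truth$true_BA) / ph$truth$true_BA
  }, numeric(1))
  expect_true(all(diff(rel_err) <= 0.01))   # non-increasing within noise
  expect_lt(rel_err[3], rel_err[1] + 1e-12)
})

test_that("degenerate cohort spec yields identical subjects", {
  ov <- null_cohort_overrides()
  for (g in names(ov$groups)) for (v in c("BT", "BA", "g", "MPI"))
    ov$groups[[g]][[v]]$sd <- 0
  spec <- do.call(cohort_spec, c(ov, list(seed = 3)))
  co <- make_cohort(spec, mode = "table")
  expect_equal(length(unique(co$true_BT)), 1L)
  expect_equal(length(unique(co$true_g)), 1L)
  # downstream correlation against the constant flags an error, not NaN
  expect_error(pearson_correlation(co$age, co$true_BT), "constant")
})

test_that("group sample means stay within 3 SE of the specified means", {
  # law-of-large-numbers check over repeated seeds, default over-50 groups
  n_seeds <- 100
  m_bt <- f_bt <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    co <- make_cohort(cohort_spec(seed = s), mode = "table")
    m_bt[s] <- mean(co$true_BT[co$sex == "M" & co$age_group == "gt50"])
    f_bt[s] <- mean(co$true_BT[co$sex == "F" & co$age_group == "gt50"])
  }
  se_m <- 0.6 / sqrt(51 * n_seeds)
  se_f <- 0.5 / sqrt(26 * n_seeds)
  expect_lt(abs(mean(m_bt) - 2.9), 3 * se_m + 0.02)  # + truncation allowance
  expect_lt(abs(mean(f_bt) - 2.0), 3 * se_f + 0.02)
})

test_that("cohort generation is bit-reproducible under a fixed seed", {
  a <- make_cohort(cohort_spec(seed = 11), mode = "table")
  b <- make_cohort(cohort_spec(seed = 11), mode = "table")
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a),
                         as.data.frame(make_cohort(cohort_spec(seed = 12)))))
})

test_that("cohorts with any active group under n = 2 are refused", {
  expect_error(make_cohort(cohort_spec(groups = list(F_le50 = list(n = 1)),
                                       seed = 1)),
               "cohort too small")
  # n = 0 groups are simply excluded
  co <- make_cohort(cohort_spec(groups = list(F_le50 = list(n = 0),
                                              M_le50 = list(n = 0)),
                                seed = 1))
  expect_equal(nrow(co), 77L)
  expect_true(all(co$age_group == "gt50"))
})

test_that("image-mode geometry realizes the sampled thickness end to end", {
  ov <- list(groups = list(F_le50 = list(n = 0), M_le50 = list(n = 0),
                           F_gt50 = list(n = 0),
                           M_gt50 = list(n = 2,
                                         BT = list(mean = 2.5, sd = 0),
                                         g = list(mean = 0.5, sd = 0))),
             image = list(noise_sd = 0, deformation_amplitude = 0))
  co <- make_cohort(do.call(cohort_spec, c(ov, list(seed = 5))),
                    mode = "image")
  meas <- measure_cohort(co)
  expect_true(all(abs(meas$BT - meas$true_BT) <= 0.35))  # half pixel @ 0.7 mm
})
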