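# Shared fixtures and independent oracles for the test suite.

# Filled annulus mask from pixel-center distances (no supersampling): the
# straightforward rasterization an oracle would use.
annulus_mask <- function(n, r_out, r_in, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  d <- sqrt(outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, "+"))
  matrix(as.integer(d <= r_out & d >= r_in), n, n)
}

# Diamond ring |dx| + |dy| == r: a one-pixel-wide 8-connected closed curve
# with no removable corner pixels.
diamond_ring <- function(n, r) {
  cx <- (n + 1) %/% 2
  d <- abs(outer(seq_len(n) - cx, rep(1, n))) +
       abs(outer(rep(1, n), seq_len(n) - cx))
  matrix(as.integer(d == r), n, n)
}

# Brute-force area of a deformed ring by dense subpixel counting; the
# independent oracle for the polygonal-integration ground truth.
supersampled_ring_area <- function(spec, factor = 16L) {
  n <- spec$grid_size; s <- factor; sp <- spec$pixel_spacing
  half <- n * sp / 2
  sub <- ((seq_len(n * s) - 0.5) / s) * sp - half
  dx <- matrix(sub, n * s, n * s, byrow = TRUE) - spec$center_offset[1]
  dy <- matrix(sub, n * s, n * s) - spec$center_offset[2]
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  r_out <- spec$outer_diameter / 2
  for (h in spec$deformation_harmonics)
    r_out <- r_out + (spec$outer_diameter / 2) * h[2] * cos(h[1] * th + h[3])
  inside <- r <= r_out & r > r_out - spec$wall_thickness
  sum(inside) * (sp / s)^2
}

# Permutation p-value for the two-sample location test (pooled mean
# difference statistic), the distribution-free oracle for the pooled t.
perm_ttest_p <- function(a, b, n_perm = 1e5, seed = 99) {
  set.seed(seed)
  pooled <- c(a, b)
  n_a <- length(a)
  obs <- abs(mean(a) - mean(b))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), n_a)
    hits <- hits + (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12)
  }
  hits / n_perm
}

# Permutation p-value for the Pearson correlation.
perm_cor_p <- function(x, y, n_perm = 1e5, seed = 99) {
  set.seed(seed)
  obs <- abs(cor(x, y))
  hits <- 0L
  for (i in seq_len(n_perm))
    hits <- hits + (abs(cor(x, sample(y))) >= obs - 1e-12)
  hits / n_perm
}

# Wrap a bare matrix + spacing into the mask/image pair used by
# slice_morphometry.
as_slice <- function(mask_mat, spacing, image_mat = NULL) {
  list(bone = roi_mask(mask_mat, spacing, "bone"),
       image = if (!is.null(image_mat)) slice_image(image_mat, spacing))
}

# Small table-mode cohort spec override: equal means, no slopes.
null_cohort_overrides <- function() {
  eq <- list(BT = list(mean = 2.5, sd = 0.5), BA = list(mean = 70, sd = 15),
             g = list(mean = 0.45, sd = 0.12), MPI = list(mean = 0.13, sd = 0.04))
  list(groups = list(F_le50 = eq, M_le50 = eq, F_gt50 = eq, M_gt50 = eq),
       age_slopes = list(bt = list(F = 0, M = 0), mpi = list(F = 0, M = 0)))
}
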