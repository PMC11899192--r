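# Synthetic cohort simulation.
#
# Subjects are drawn from four sex x age-group cells with configurable group
# means/SDs for BT, BA, g and MPI, linear age effects on BT and MPI about
# the group age midpoint, and covariates (BMI, MFI class, SFT). Table mode
# samples morphometry directly; image mode additionally renders a phantom
# stack per subject whose ring geometry realizes the sampled BT and g, so
# the full image-based measurement chain can be exercised end to end.

#' Cohort simulation parameters
#'
#' Returns the packaged defaults (see
#' `system.file("extdata", "cohort_defaults.yaml", package = "fibmorph")`),
#' with any element overridable. The default group sizes, means, SDs and age
#' ranges emulate published group statistics of an adult 7T fibular
#' morphometry cohort (107 subjects split at age 50); they describe the
#' conditions being simulated, not values the pipeline must reproduce.
#'
#' @param ... named overrides, merged recursively into the defaults (e.g.
#'   `groups = list(F_gt50 = list(n = 10))`,
#'   `age_slopes = list(bt = list(F = 0))`).
#' @param seed integer seed stored in the spec; [make_cohort()] seeds from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(..., seed = 1L) {
  defaults <- yaml::read_yaml(system.file("extdata", "cohort_defaults.yaml",
                                          package = "fibmorph"))
  spec <- modify_list_deep(defaults, list(...))
  spec$seed <- as.integer(seed)
  for (gname in names(spec$groups)) {
    g <- spec$groups[[gname]]
    for (v in c("BT", "BA", "g", "MPI"))
      if (g[[v]]$sd < 0)
        stop("group ", gname, ": ", v, " sd must be >= 0", call. = FALSE)
    p <- unlist(g$mfi_probs)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("group ", gname, ": mfi_probs must be non-negative and sum to 1",
           call. = FALSE)
    if (g$age_max < g$age_min)
      stop("group ", gname, ": bad age range", call. = FALSE)
  }
  structure(spec, class = "cohort_spec")
}

modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

# Sample one group's subjects. Age effects are applied about the group age
# midpoint; the residual SD is shrunk so the realized group SD stays close
# to the specified one (floored at 20% of it).
sample_group <- function(g, gname, slopes, bmi, sft, image_mode, image_cfg) {
  n <- g$n
  sex <- g$sex
  age <- stats::runif(n, g$age_min, g$age_max)
  age_mid <- (g$age_min + g$age_max) / 2
  var_age <- (g$age_max - g$age_min)^2 / 12

  draw <- function(par, slope = 0) {
    resid_sd <- if (par$sd == 0) 0
                else sqrt(max(par$sd^2 - slope^2 * var_age, (0.2 * par$sd)^2))
    par$mean + slope * (age - age_mid) + stats::rnorm(n, 0, resid_sd)
  }
  ok <- rep(FALSE, n)
  BT <- BA <- gr <- MPI <- numeric(n)
  for (it in 1:200) {
    bad <- which(!ok)
    if (length(bad) == 0L) break
    BT[bad] <- draw(g$BT, slopes$bt[[sex]])[bad]
    BA[bad] <- draw(g$BA)[bad]
    gr[bad] <- draw(g$g)[bad]
    MPI[bad] <- draw(g$MPI, slopes$mpi[[sex]])[bad]
    ok <- BT > 0 & BA > 0 & MPI > 0 & gr > 0 & gr < 1
    if (image_mode) {
      d_out <- 2 * BT / (1 - gr)
      max_d <- image_cfg$grid_size * image_cfg$pixel_spacing / 2 - 3
      ok <- ok & d_out <= max_d & gr * d_out >= 2 * image_cfg$pixel_spacing
    }
    if (all(par_sd_zero <- c(g$BT$sd, g$BA$sd, g$g$sd, g$MPI$sd) == 0) &&
        any(!ok))
      stop("degenerate cohort spec produces invalid fixed values",
           call. = FALSE)
  }
  if (!all(ok))
    stop("could not sample valid morphometry for group ", gname,
         " after 200 rounds (means/SDs imply out-of-range values)",
         call. = FALSE)
  mfi <- sample(names(g$mfi_probs), n, replace = TRUE,
                prob = unlist(g$mfi_probs))
  d_out <- 2 * BT / (1 - gr)
  data.frame(sex = sex, age = age,
             bmi = pmax(stats::rnorm(n, bmi[[sex]]$mean, bmi[[sex]]$sd), 12),
             mfi_class = mfi,
             sft = pmax(stats::rnorm(n, sft$mean, sft$sd), 0.5),
             true_BT = BT, true_BA = BA, true_g = gr, true_MPI = MPI,
             true_BMA = pi * (gr * d_out)^2 / 4,
             age_group = if (g$age_max <= 50) "le50" else "gt50",
             stringsAsFactors = FALSE)
}

#' Simulate a cohort
#'
#' @param spec a [cohort_spec()].
#' @param mode `"table"` samples morphometry values directly (fast);
#'   `"image"` additionally renders a phantom slice stack per subject whose
#'   geometry realizes the sampled wall thickness and g-ratio.
#' @return object of class `fib_cohort`: a data.frame with columns
#'   `subject_id`, `sex`, `age`, `bmi`, `mfi_class`, `sft`, `true_BT`,
#'   `true_BA`, `true_g`, `true_MPI`, `true_BMA`, `age_group`. In image mode
#'   the attribute `"stacks"` holds one [subject_stack()] per subject.
#'   Deterministic given `spec$seed`.
#' @export
make_cohort <- function(spec, mode = c("table", "image")) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  ns <- vapply(spec$groups, function(g) as.integer(g$n), integer(1))
  spec$groups <- spec$groups[ns > 0L]    # n = 0 disables a group
  ns <- ns[ns > 0L]
  if (length(ns) == 0L || any(ns < 2L))
    stop("cohort too small: every active group needs n >= 2 (got ",
         paste(ns, collapse = ", "), ")", call. = FALSE)
  set.seed(spec$seed)
  img <- spec$image
  rows <- lapply(names(spec$groups), function(gname)
    sample_group(spec$groups[[gname]], gname, spec$age_slopes, spec$bmi,
                 spec$sft, mode == "image", img))
  tab <- do.call(rbind, rows)
  tab <- cbind(subject_id = sprintf("S%03d", seq_len(nrow(tab))), tab)
  rownames(tab) <- NULL
  class(tab) <- c("fib_cohort", "data.frame")

  if (mode == "image") {
    stacks <- vector("list", nrow(tab))
    for (i in seq_len(nrow(tab))) {
      d_out <- 2 * tab$true_BT[i] / (1 - tab$true_g[i])
      ph <- phantom_spec(
        outer_diameter = d_out,
        wall_thickness = tab$true_BT[i],
        deformation_harmonics = if (img$deformation_amplitude > 0)
          list(c(3, img$deformation_amplitude, stats::runif(1, 0, 2 * pi)))
          else list(),
        intensity_bone = min(max(tab$true_MPI[i], 0.02), 0.6),
        noise_sd = img$noise_sd,
        pixel_spacing = img$pixel_spacing,
        grid_size = img$grid_size,
        supersample_factor = img$supersample_factor)
      stacks[[i]] <- make_phantom_stack(
        ph, n_slices = img$n_slices, jitter = img$jitter,
        subject_id = tab$subject_id[i],
        covariates = as.list(tab[i, c("age", "sex", "bmi", "mfi_class",
                                      "sft")]))
    }
    names(stacks) <- tab$subject_id
    attr(tab, "stacks") <- stacks
  }
  attr(tab, "seed") <- spec$seed
  attr(tab, "mode") <- mode
  tab
}

#' @export
print.fib_cohort <- function(x, ...) {
  cat("<fib_cohort> ", nrow(x), " subjects (",
      sum(x$sex == "F"), "F/", sum(x$sex == "M"), "M), mode ",
      attr(x, "mode") %||% "table", ", seed ", attr(x, "seed"), "\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Measure every subject of an image-mode cohort
#'
#' Runs [subject_morphometry()] on each rendered stack and joins the
#' measurements to the cohort table.
#'
#' @param cohort an image-mode [make_cohort()] result.
#' @param ... passed to [subject_morphometry()].
#' @return data.frame: cohort columns plus measured `BT`, `BA`, `CL`, `g`,
#'   `MPI`, `BMA`, `n_flagged`.
#' @export
measure_cohort <- function(cohort, ...) {
  stacks <- attr(cohort, "stacks")
  if (is.null(stacks))
    stop("cohort was generated in table mode; re-run make_cohort(mode = \"image\")",
         call. = FALSE)
  meas <- do.call(rbind, lapply(stacks, function(st)
    as.data.frame(subject_morphometry(st, ...))))
  merge(as.data.frame(cohort), meas, by = "subject_id", sort = FALSE)
}
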