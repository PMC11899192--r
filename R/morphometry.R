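# Ring-model morphometry of the cortical bone cross-section.
#
# Per slice: BA (bone area) is the foreground pixel count times the pixel
# area; CL is the physical length of the medial-axis centerline loop; wall
# thickness is BT = BA / CL; under a circular-ring approximation the
# centerline diameter is CL / pi, the outer diameter D_out = CL/pi + BT, the
# inner diameter D_in = CL/pi - BT, and the g-ratio is D_in / D_out. The MPI
# (mean pixel intensity over the bone mask, after robust slice normalization)
# indexes mineral-density loss, and BMA is the marrow mask area. Subject
# values average the central seven slices; BT is the mean of per-slice BA/CL.

#' Cross-sectional area of a binary mask
#'
#' Foreground pixel count times the pixel area.
#'
#' @param mask a [roi_mask()] or binary matrix.
#' @param pixel_spacing spacing in mm; taken from the mask when omitted.
#' @return area in mm^2.
#' @export
bone_area <- function(mask, pixel_spacing = NULL) {
  if (inherits(mask, "roi_mask")) {
    if (is.null(pixel_spacing)) pixel_spacing <- mask$pixel_spacing
    m <- mask$values
  } else m <- mask
  if (is.null(pixel_spacing)) stop("pixel spacing required", call. = FALSE)
  pixel_spacing <- normalize_spacing(pixel_spacing)
  n_fg <- sum(m > 0)
  if (n_fg == 0L) stop("empty mask has no area", call. = FALSE)
  n_fg * pixel_spacing[1] * pixel_spacing[2]
}

# Robust min-max slice normalization: (I - p_low) / (p_high - p_low) clipped
# to [0, 1], with a near-extreme upper reference (99.9th percentile) so the
# brightest tissue (marrow) anchors 1 even when it covers ~1% of the slice.
# Invariant to global affine intensity rescaling, which makes MPI comparable
# across scanner gain/offset settings.
normalize_intensity <- function(values, lower = 0.005, upper = 0.999) {
  q <- stats::quantile(values, c(lower, upper), names = FALSE, type = 7)
  if (q[2] <= q[1]) stop("degenerate intensity range: cannot normalize",
                         call. = FALSE)
  pmin(pmax((values - q[1]) / (q[2] - q[1]), 0), 1)
}

#' g-ratio from centerline length and wall thickness
#'
#' Under the default `"diameter"` convention the ring's centerline diameter
#' is `CL / pi` and `g = (CL/pi - BT) / (CL/pi + BT)`, which equals the
#' inner-to-outer diameter ratio `D_in / D_out` of a circular ring. The
#' `"literal"` convention computes `(CL - BT) / (CL + BT)` on the raw loop
#' length; it is retained for comparison but is not diameter-consistent
#' (for a typical fibula it gives ~0.8 where the diameter ratio is ~0.5).
#'
#' @param CL centerline loop length, mm.
#' @param BT wall thickness, mm.
#' @param convention `"diameter"` (default) or `"literal"`.
#' @return dimensionless g-ratio. Under the diameter convention a wall
#'   thicker than the ring model admits yields a negative value, returned
#'   as-is (flagged downstream), never clamped.
#' @export
g_ratio <- function(CL, BT, convention = c("diameter", "literal")) {
  convention <- match.arg(convention)
  if (convention == "diameter") {
    d <- CL / pi
    (d - BT) / (d + BT)
  } else {
    (CL - BT) / (CL + BT)
  }
}

#' Morphometry of a single slice
#'
#' @param image a [slice_image()] (used for MPI; may be `NULL` to skip MPI).
#' @param bone bone [roi_mask()].
#' @param marrow marrow [roi_mask()] (may be `NULL` to skip BMA).
#' @param g_convention see [g_ratio()].
#' @param min_size small-component cleanup threshold for skeletonization.
#' @return one-row data.frame: `slice_index`, `BA`, `CL`, `BT`,
#'   `centerline_diameter`, `D_out`, `D_in`, `g`, `MPI`, `BMA`, `is_closed`,
#'   `flagged` (TRUE for an open ring or non-positive `D_in`).
#' @export
slice_morphometry <- function(image, bone, marrow = NULL,
                              g_convention = c("diameter", "literal"),
                              min_size = 5L) {
  g_convention <- match.arg(g_convention)
  sp <- require_isotropic(bone$pixel_spacing)
  BA <- bone_area(bone)
  skel <- skeletonize_mask(bone, min_size = min_size)
  loop <- extract_centerline_loop(skel)
  CL <- loop$length_mm
  if (!is.finite(CL) || CL <= 0)
    stop("degenerate centerline (zero length) in slice ", bone$slice_index,
         call. = FALSE)
  BT <- BA / CL
  d_mid <- CL / pi
  g <- g_ratio(CL, BT, g_convention)
  MPI <- NA_real_
  if (!is.null(image)) {
    norm <- normalize_intensity(image$values)
    MPI <- mean(norm[bone$values > 0])
  }
  BMA <- if (!is.null(marrow)) sum(marrow$values > 0) * sp * sp else NA_real_
  data.frame(slice_index = bone$slice_index,
             BA = BA, CL = CL, BT = BT,
             centerline_diameter = d_mid,
             D_out = d_mid + BT, D_in = d_mid - BT,
             g = g, MPI = MPI, BMA = BMA,
             is_closed = loop$is_closed,
             flagged = !loop$is_closed || (d_mid - BT) <= 0)
}

#' Morphometry of a subject stack
#'
#' Selects the `central_slices` central slices, measures each, and averages:
#' wall thickness is the arithmetic mean of per-slice `BA/CL`; `BA`, `CL`,
#' `MPI`, `BMA` are per-slice means; `g` is computed per slice and then
#' averaged. Slices whose measurement fails (e.g. fragmented mask) are
#' dropped with a warning; if fewer than `central_slices` usable slices
#' remain the subject errors out.
#'
#' @param stack a [subject_stack()].
#' @param central_slices number of central slices to average (default 7).
#' @param g_convention see [g_ratio()].
#' @param min_size small-component cleanup threshold.
#' @return object of class `subject_morphometry`: list with subject-level
#'   `BT`, `BA`, `CL`, `g`, `MPI`, `BMA`, `D_out`, `D_in`, `n_slices_used`,
#'   `n_flagged`, and `per_slice` (data.frame).
#' @export
subject_morphometry <- function(stack, central_slices = 7L,
                                g_convention = c("diameter", "literal"),
                                min_size = 5L) {
  g_convention <- match.arg(g_convention)
  usable <- list()
  for (s in stack$slices) {
    ok <- tryCatch({ stopifnot(sum(s$bone$values) > 0); TRUE },
                   error = function(e) FALSE)
    if (ok) usable <- c(usable, list(s))
    else warning("subject ", stack$subject_id, ": dropping unusable slice",
                 call. = FALSE)
  }
  if (length(usable) < central_slices)
    stop("subject ", stack$subject_id, ": only ", length(usable),
         " usable slices, need ", central_slices, call. = FALSE)
  sub <- select_central_slices(
    subject_stack(stack$subject_id, usable, stack$covariates),
    central_slices)
  rows <- vector("list", length(sub$slices))
  kept <- logical(length(sub$slices))
  for (i in seq_along(sub$slices)) {
    s <- sub$slices[[i]]
    res <- tryCatch(
      slice_morphometry(s$image, s$bone, s$marrow,
                        g_convention = g_convention, min_size = min_size),
      error = function(e) {
        warning("subject ", stack$subject_id, ", slice ",
                s$image$slice_index, ": ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (!is.null(res)) { rows[[i]] <- res; kept[i] <- TRUE }
  }
  per_slice <- do.call(rbind, rows[kept])
  if (is.null(per_slice) || nrow(per_slice) < central_slices)
    stop("subject ", stack$subject_id, ": fewer than ", central_slices,
         " slices survived measurement", call. = FALSE)
  structure(
    list(subject_id = stack$subject_id,
         BT = mean(per_slice$BT),          # mean of per-slice BA/CL
         BA = mean(per_slice$BA),
         CL = mean(per_slice$CL),
         g = mean(per_slice$g),
         MPI = mean(per_slice$MPI),
         BMA = mean(per_slice$BMA),
         D_out = mean(per_slice$D_out),
         D_in = mean(per_slice$D_in),
         n_slices_used = nrow(per_slice),
         n_flagged = sum(per_slice$flagged),
         per_slice = per_slice,
         covariates = stack$covariates),
    class = "subject_morphometry")
}

#' @export
print.subject_morphometry <- function(x, ...) {
  cat("<subject_morphometry> ", x$subject_id, "\n", sep = "")
  cat(sprintf("  BT %.2f mm | BA %.1f mm^2 | CL %.1f mm | g %.3f\n",
              x$BT, x$BA, x$CL, x$g))
  cat(sprintf("  MPI %s | BMA %s mm^2 | %d slice(s)%s\n",
              ifelse(is.na(x$MPI), "-", sprintf("%.3f", x$MPI)),
              ifelse(is.na(x$BMA), "-", sprintf("%.1f", x$BMA)),
              x$n_slices_used,
              if (x$n_flagged > 0) sprintf(" [%d flagged]", x$n_flagged)
              else ""))
  invisible(x)
}

#' @export
summary.subject_morphometry <- function(object, ...) {
  print(object)
  cat("  per-slice:\n")
  print(object$per_slice, row.names = FALSE, digits = 4)
  invisible(object)
}

#' Flatten subject morphometry to a one-row data.frame
#' @param x a `subject_morphometry` object.
#' @return one-row data.frame of the subject-level quantities.
#' @export
as.data.frame.subject_morphometry <- function(x, ...) {
  data.frame(subject_id = x$subject_id, BT = x$BT, BA = x$BA, CL = x$CL,
             g = x$g, MPI = x$MPI, BMA = x$BMA, D_out = x$D_out,
             D_in = x$D_in, n_slices_used = x$n_slices_used,
             n_flagged = x$n_flagged)
}
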