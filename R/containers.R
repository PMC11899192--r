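#' Construct a 2D intensity slice
#'
#' A `slice_image` is the measurement substrate of the pipeline: a 2D grid of
#' dimensionless intensities with physical in-plane pixel spacing. The
#' convention throughout the package is row = image y, column = image x,
#' pixel centers at integer grid coordinates (0-based internally where pixel
#' coordinates are reported), all lengths in millimetres.
#'
#' @param values numeric matrix of finite intensities.
#' @param pixel_spacing in-plane spacing in mm; scalar (isotropic) or length-2
#'   `(row, col)` vector.
#' @param slice_index integer position of the slice within its stack.
#' @param slice_thickness slice thickness in mm (metadata only).
#' @param slice_gap inter-slice gap in mm (metadata only).
#' @return object of class `slice_image`.
#' @export
slice_image <- function(values, pixel_spacing, slice_index = 1L,
                        slice_thickness = 4, slice_gap = 2) {
  if (!is.matrix(values) || length(values) == 0L)
    stop("`values` must be a non-empty matrix", call. = FALSE)
  if (!all(is.finite(values)))
    stop("slice intensities must all be finite", call. = FALSE)
  pixel_spacing <- normalize_spacing(pixel_spacing)
  structure(
    list(values = values,
         pixel_spacing = pixel_spacing,
         slice_index = as.integer(slice_index),
         slice_thickness = slice_thickness,
         slice_gap = slice_gap),
    class = "slice_image")
}

#' Construct a binary region-of-interest mask
#'
#' @param values matrix coercible to binary; any value > 0 is foreground, so
#'   masks stored as \{0, 255\} binarize to \{0, 1\}.
#' @param pixel_spacing in-plane spacing in mm, as for [slice_image()].
#' @param label `"bone"` or `"marrow"`.
#' @param slice_index integer slice position.
#' @return object of class `roi_mask`; `values` is an integer 0/1 matrix.
#' @export
roi_mask <- function(values, pixel_spacing, label = c("bone", "marrow"),
                     slice_index = 1L) {
  label <- match.arg(label)
  if (!is.matrix(values) || length(values) == 0L)
    stop("mask `values` must be a non-empty matrix", call. = FALSE)
  if (!all(is.finite(values)))
    stop("mask values must be finite", call. = FALSE)
  bin <- matrix(as.integer(values > 0), nrow(values), ncol(values))
  pixel_spacing <- normalize_spacing(pixel_spacing)
  structure(
    list(values = bin,
         pixel_spacing = pixel_spacing,
         label = label,
         slice_index = as.integer(slice_index)),
    class = "roi_mask")
}

normalize_spacing <- function(pixel_spacing) {
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || !all(is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0))
    stop("pixel spacing must be one or two positive finite values (mm)",
         call. = FALSE)
  as.numeric(pixel_spacing)
}

#' Require isotropic in-plane spacing
#'
#' Wall-thickness and centerline-length math assumes isotropic pixels; the
#' morphometry layer refuses anisotropic grids rather than silently averaging.
#' @param pixel_spacing length-2 spacing vector (mm).
#' @return the scalar spacing, invisibly usable.
#' @keywords internal
require_isotropic <- function(pixel_spacing) {
  if (abs(pixel_spacing[1] - pixel_spacing[2]) >
      1e-9 * max(pixel_spacing))
    stop("morphometry requires isotropic in-plane spacing; got ",
         pixel_spacing[1], " x ", pixel_spacing[2], " mm", call. = FALSE)
  pixel_spacing[1]
}

#' Bundle one subject's slices, masks and covariates
#'
#' @param subject_id character scalar.
#' @param slices list; each element a list with components `image`
#'   ([slice_image()]), `bone` and `marrow` ([roi_mask()]). Slice indices must
#'   be strictly increasing and grids/spacings must agree within a slice.
#' @param covariates named list or one-row data.frame with `age` (years),
#'   `sex` (`"M"`/`"F"`), `bmi` (kg/m^2), `mfi_class`
#'   (`"normal"`/`"mild"`/`"moderate"`), `sft` (mm). May be `NULL` for
#'   phantom work.
#' @return object of class `subject_stack`.
#' @export
subject_stack <- function(subject_id, slices, covariates = NULL) {
  if (length(slices) == 0L) stop("stack has no slices", call. = FALSE)
  idx <- vapply(slices, function(s) s$image$slice_index, integer(1))
  if (any(diff(idx) <= 0))
    stop("slice indices must be strictly increasing", call. = FALSE)
  for (s in slices) {
    dims <- dim(s$image$values)
    for (m in list(s$bone, s$marrow)) {
      if (is.null(m)) next
      if (!identical(dim(m$values), dims))
        stop("image/mask grid shape mismatch in slice ", s$image$slice_index,
             call. = FALSE)
      if (max(abs(m$pixel_spacing - s$image$pixel_spacing)) > 1e-9)
        stop("image/mask spacing mismatch in slice ", s$image$slice_index,
             call. = FALSE)
    }
  }
  if (!is.null(covariates)) covariates <- as.list(covariates)
  structure(list(subject_id = as.character(subject_id),
                 slices = slices, covariates = covariates),
            class = "subject_stack")
}

#' @export
print.subject_stack <- function(x, ...) {
  cat("<subject_stack> ", x$subject_id, ": ", length(x$slices), " slice(s), ",
      paste(dim(x$slices[[1]]$image$values), collapse = " x "),
      " px @ ", x$slices[[1]]$image$pixel_spacing[1], " mm\n", sep = "")
  invisible(x)
}

#' Select the central slices of a stack
#'
#' The acquisition protocol this pipeline mirrors collects nine axial slices
#' and averages measurements over the central seven. Centering is by slice
#' position in the stack; for an even surplus the window is shifted toward
#' the proximal (lower-index) side.
#'
#' @param stack a [subject_stack()].
#' @param count number of central slices to keep (default 7).
#' @return a `subject_stack` containing `count` slices.
#' @export
select_central_slices <- function(stack, count = 7L) {
  n <- length(stack$slices)
  if (n < count)
    stop("insufficient slices: have ", n, ", need ", count, call. = FALSE)
  drop_lo <- floor((n - count) / 2)           # tie toward proximal side
  keep <- seq(drop_lo + 1L, drop_lo + count)
  subject_stack(stack$subject_id, stack$slices[keep], stack$covariates)
}
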