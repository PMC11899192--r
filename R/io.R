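# File I/O: NIfTI volumes for subject stacks, 16-bit TIFF + JSON sidecar for
# single slices, CSV for covariate and cohort tables. Spacing metadata is
# never defaulted silently: a volume or sidecar without usable pixel spacing
# is a metadata error.

#' Write a subject stack as NIfTI volumes
#'
#' Writes `<subject_id>_image.nii.gz`, `<subject_id>_bone.nii.gz` and
#' `<subject_id>_marrow.nii.gz` with in-plane spacing and slice pitch
#' (thickness + gap) in the header.
#'
#' @param stack a [subject_stack()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
write_subject_nifti <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s1 <- stack$slices[[1]]$image
  pitch <- s1$slice_thickness + s1$slice_gap
  pack <- function(get) {
    arrs <- lapply(stack$slices, get)
    array(unlist(arrs), dim = c(dim(arrs[[1]]), length(arrs)))
  }
  paths <- file.path(dir, paste0(stack$subject_id, "_",
                                 c("image", "bone", "marrow"), ".nii.gz"))
  vols <- list(pack(function(s) s$image$values),
               pack(function(s) s$bone$values),
               pack(function(s) s$marrow$values))
  for (k in 1:3) {
    img <- RNifti::asNifti(vols[[k]])
    RNifti::pixdim(img) <- c(s1$pixel_spacing, pitch)
    RNifti::writeNifti(img, paths[k])
  }
  invisible(paths)
}

#' Read a subject stack from NIfTI volumes
#'
#' @param image_path,bone_path,marrow_path NIfTI files of identical shape;
#'   `marrow_path` may be `NULL`.
#' @param covariates optional named list / one-row data.frame of subject
#'   covariates (`age`, `sex`, `bmi`, `mfi_class`, `sft`).
#' @param subject_id defaults to the image file name stem.
#' @param min_slices slices with an empty bone mask are dropped with a
#'   warning; fewer than `min_slices` usable slices is an error (default 7,
#'   the central-slice averaging requirement).
#' @return a [subject_stack()].
#' @export
read_subject_stack <- function(image_path, bone_path, marrow_path = NULL,
                               covariates = NULL, subject_id = NULL,
                               min_slices = 7L) {
  img <- RNifti::readNifti(image_path)
  bone <- RNifti::readNifti(bone_path)
  marrow <- if (!is.null(marrow_path)) RNifti::readNifti(marrow_path)
  if (!identical(dim(img)[1:3], dim(bone)[1:3]) ||
      (!is.null(marrow) && !identical(dim(img)[1:3], dim(marrow)[1:3])))
    stop("alignment error: image and mask volumes differ in shape",
         call. = FALSE)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 2 || any(!is.finite(pd[1:2])) || any(pd[1:2] <= 0))
    stop("metadata error: NIfTI header carries no usable pixel spacing",
         call. = FALSE)
  sp <- pd[1:2]
  pitch <- if (length(pd) >= 3 && is.finite(pd[3]) && pd[3] > 0) pd[3] else NA
  if (is.null(subject_id))
    subject_id <- sub("_image$", "", sub("\\.nii(\\.gz)?$", "",
                                         basename(image_path)))
  n_sl <- if (length(dim(img)) >= 3) dim(img)[3] else 1L
  slice_of <- function(v, i) if (length(dim(v)) >= 3) v[, , i] else v[, ]
  slices <- list()
  for (i in seq_len(n_sl)) {
    bm <- slice_of(bone, i)
    if (sum(bm > 0) == 0L) {
      warning("subject ", subject_id, ": slice ", i,
              " has an empty bone mask; dropped", call. = FALSE)
      next
    }
    slices[[length(slices) + 1L]] <- list(
      image = slice_image(matrix(slice_of(img, i), dim(img)[1], dim(img)[2]),
                          sp, slice_index = i,
                          slice_thickness = if (is.na(pitch)) NA else pitch,
                          slice_gap = 0),
      bone = roi_mask(matrix(bm, dim(img)[1], dim(img)[2]), sp,
                      "bone", slice_index = i),
      marrow = if (!is.null(marrow))
        roi_mask(matrix(slice_of(marrow, i), dim(img)[1], dim(img)[2]), sp,
                 "marrow", slice_index = i))
  }
  if (length(slices) < min_slices)
    stop("subject ", subject_id, " rejected: only ", length(slices),
         " usable slices (need ", min_slices, ")", call. = FALSE)
  subject_stack(subject_id, slices, covariates)
}

#' Write a single phantom slice as 16-bit TIFF + JSON sidecar
#'
#' The intensity image goes to `<prefix>_image.tiff` (16-bit, min-max
#' scaled; the scaling is recorded in the sidecar), the masks to 8-bit PNGs,
#' and pixel spacing plus the analytic ground truth to `<prefix>.json`.
#'
#' @param phantom a [make_annulus_phantom()] result.
#' @param prefix output path prefix.
#' @return invisibly, the sidecar path.
#' @export
write_slice_tiff <- function(phantom, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  v <- phantom$image$values
  rng <- range(v)
  scaled <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  tiff::writeTIFF(scaled, paste0(prefix, "_image.tiff"),
                  bits.per.sample = 16L)
  png::writePNG(phantom$bone$values + 0, paste0(prefix, "_bone.png"))
  png::writePNG(phantom$marrow$values + 0, paste0(prefix, "_marrow.png"))
  sidecar <- list(pixel_spacing = phantom$image$pixel_spacing,
                  intensity_range = rng,
                  slice_index = phantom$image$slice_index,
                  truth = phantom$truth)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(prefix, ".json"))
}

#' Read a single slice written by [write_slice_tiff()]
#'
#' @param prefix the path prefix used at write time.
#' @return list with `image`, `bone`, `marrow`, `truth`.
#' @export
read_slice_tiff <- function(prefix) {
  sidecar_path <- paste0(prefix, ".json")
  if (!file.exists(sidecar_path))
    stop("metadata error: sidecar ", sidecar_path, " not found; ",
         "pixel spacing is required", call. = FALSE)
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(side$pixel_spacing))
    stop("metadata error: sidecar has no pixel_spacing", call. = FALSE)
  v <- tiff::readTIFF(paste0(prefix, "_image.tiff"))
  rng <- side$intensity_range
  v <- v * (rng[2] - rng[1]) + rng[1]
  idx <- side$slice_index %||% 1L
  list(image = slice_image(v, side$pixel_spacing, slice_index = idx),
       bone = roi_mask(round(png::readPNG(paste0(prefix, "_bone.png")) * 255),
                       side$pixel_spacing, "bone", slice_index = idx),
       marrow = roi_mask(round(png::readPNG(paste0(prefix, "_marrow.png")) * 255),
                         side$pixel_spacing, "marrow", slice_index = idx),
       truth = side$truth)
}

#' Read a covariate table
#'
#' @param path CSV with columns exactly `subject_id`, `sex`, `age`, `bmi`,
#'   `mfi_class`, `sft`.
#' @return data.frame.
#' @export
read_covariates <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sex", "age", "bmi", "mfi_class", "sft")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("covariate table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tab
}

#' Write a cohort table as CSV
#'
#' @param cohort a [make_cohort()] table.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
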