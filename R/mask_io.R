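#' Binary voxel mask
#'
#' Container for a binary 3D segmentation mask together with its physical
#' voxel spacing. All fractal and shape features in the package are computed
#' from this object. Voxel coordinates are 0-based array indices; the
#' physical position of a voxel centre is \code{index * spacing}.
#'
#' @param grid 3D array coercible to 0/1 integer values.
#' @param spacing numeric length-3, voxel edge lengths in mm (all > 0).
#' @param subject_id character label attached to downstream feature rows.
#' @param orientation optional orientation string recorded from a NIfTI
#'   header. It is stored verbatim and never used to reorder axes: every
#'   feature computed here is invariant to axis permutation.
#'
#' @return An object of class \code{voxel_mask}: a list with elements
#'   \code{grid} (integer 0/1 array), \code{spacing}, \code{subject_id},
#'   \code{orientation} and \code{flags} (character vector of data-quality
#'   flags such as \code{"empty"} or \code{"anisotropic"}).
#' @export
voxel_mask <- function(grid, spacing = c(1, 1, 1), subject_id = "subject",
                       orientation = NULL) {
  if (length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel edge lengths in mm", call. = FALSE)
  g <- grid
  storage.mode(g) <- "integer"
  if (!all(g == 0L | g == 1L))
    stop("`grid` must contain only 0/1 values; threshold first", call. = FALSE)
  flags <- character(0)
  if (!any(g == 1L)) flags <- c(flags, "empty")
  if (diff(range(spacing)) > 1e-9) flags <- c(flags, "anisotropic")
  structure(
    list(grid = g, spacing = spacing, subject_id = as.character(subject_id),
         orientation = orientation, flags = flags),
    class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<voxel_mask> %s: %d x %d x %d voxels, spacing %s mm, %d foreground%s\n",
              x$subject_id, d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$grid), if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}

is_isotropic <- function(mask, tol = 1e-9) diff(range(mask$spacing)) <= tol

n_foreground <- function(mask) sum(mask$grid == 1L)

stop_if_empty <- function(mask, what) {
  if (n_foreground(mask) == 0L)
    stop(sprintf("%s requires a non-empty mask (subject '%s')", what, mask$subject_id),
         call. = FALSE)
  invisible(mask)
}

#' Read a binary segmentation mask from a NIfTI file
#'
#' Reads a NIfTI-1 volume (as produced by semi-automatic tumour
#' segmentation), binarises it at \code{value > threshold}, and records the
#' voxel spacing from the header. Segmentation masks are label maps, so the
#' default threshold of 0 keeps every labelled voxel; raise it for
#' probabilistic masks. The header orientation code is recorded but axes are
#' never reordered -- box counting is orientation-agnostic.
#'
#' @param path path to a readable \code{.nii} or \code{.nii.gz} file
#'   containing a scalar 3D volume (a 4D volume with a single timepoint is
#'   accepted and collapsed).
#' @param threshold binarisation threshold; foreground is \code{> threshold}.
#' @param subject_id subject label; defaults to the file name without
#'   extensions.
#' @return A \code{\link{voxel_mask}}. An all-background result is flagged
#'   \code{"empty"} (feature extraction, not reading, treats emptiness as an
#'   error).
#' @export
read_mask <- function(path, threshold = 0, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("mask file not found: %s", path), call. = FALSE)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop(sprintf("cannot read '%s' as NIfTI: %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L) {
    if (d[4] != 1L)
      stop(sprintf("'%s' is a 4D volume with %d timepoints; expected a single 3D mask",
                   path, d[4]), call. = FALSE)
    arr <- arr[, , , 1L, drop = TRUE]
    dim(arr) <- d[1:3]
  } else if (length(d) != 3L) {
    stop(sprintf("'%s' has %d dimensions; expected a 3D mask", path, length(d)),
         call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  orientation <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
  if (is.null(subject_id)) subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  g <- array(as.integer(arr > threshold), dim = dim(arr))
  voxel_mask(g, spacing = spacing, subject_id = subject_id,
             orientation = orientation)
}

#' Write a voxel mask to a NIfTI file
#'
#' @param mask a \code{\link{voxel_mask}}.
#' @param path output \code{.nii} or \code{.nii.gz} path.
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  img <- RNifti::asNifti(mask$grid)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a mask onto an isotropic voxel grid
#'
#' Box counting is defined on isotropic voxels, so anisotropic masks (for
#' example segmented on 2-mm slices with sub-millimetre in-plane spacing)
#' must be resampled before feature extraction. Nearest-neighbour
#' interpolation on voxel centres is used so the output stays strictly
#' binary; an already-isotropic mask is returned unchanged.
#'
#' @param mask a \code{\link{voxel_mask}}.
#' @param target_spacing target isotropic edge length in mm, or
#'   \code{"min-axis"} (default) for the smallest input spacing.
#' @return An isotropic \code{\link{voxel_mask}}.
#' @export
resample_isotropic <- function(mask, target_spacing = "min-axis") {
  stopifnot(inherits(mask, "voxel_mask"))
  if (identical(target_spacing, "min-axis")) {
    t <- min(mask$spacing)
  } else {
    t <- as.numeric(target_spacing)
    if (length(t) != 1L || !is.finite(t) || t <= 0)
      stop("`target_spacing` must be a positive spacing in mm or \"min-axis\"",
           call. = FALSE)
  }
  if (is_isotropic(mask) && abs(mask$spacing[1] - t) <= 1e-9) return(mask)
  d <- dim(mask$grid)
  sp <- mask$spacing
  new_d <- pmax(1L, as.integer(round(d * sp / t)))
  # nearest source voxel centre for each target voxel centre (0-based indices)
  src_idx <- lapply(1:3, function(a) {
    i <- pmin(pmax(round((seq_len(new_d[a]) - 1L) * t / sp[a]), 0), d[a] - 1L)
    as.integer(i) + 1L
  })
  g <- mask$grid[src_idx[[1]], src_idx[[2]], src_idx[[3]], drop = FALSE]
  dim(g) <- new_d
  voxel_mask(g, spacing = rep(t, 3), subject_id = mask$subject_id,
             orientation = mask$orientation)
}

#' Write a per-subject feature table as CSV
#'
#' Serialises a list of feature sets (one per subject, optionally joined to
#' subject metadata) as an RFC 4180 CSV with a fixed leading column order:
#' \code{subject_id}, any metadata columns, then \code{fd},
#' \code{lacunarity}, \code{sphericity}, \code{max_diameter_cm},
#' \code{volume_mm3}. Numeric fields round-trip through
#' \code{\link{read_feature_table}} at full double precision.
#'
#' @param features a list of \code{fractal_features} objects (from
#'   \code{\link{extract_features}}) or a data frame already in table form.
#' @param path output CSV path.
#' @param metadata optional data frame with a \code{subject_id} column to
#'   join (group labels, clinical covariates).
#' @return The written data frame, invisibly.
#' @export
write_feature_table <- function(features, path, metadata = NULL) {
  tab <- if (is.data.frame(features)) features else features_as_table(features)
  if (nrow(tab) == 0L) stop("empty feature list: nothing to write", call. = FALSE)
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id in feature table", call. = FALSE)
  if (!is.null(metadata)) {
    if (!"subject_id" %in% names(metadata))
      stop("`metadata` must have a subject_id column", call. = FALSE)
    tab <- merge(metadata, tab, by = "subject_id", sort = FALSE)
  }
  feat_cols <- intersect(c("fd", "lacunarity", "sphericity", "max_diameter_cm",
                           "volume_mm3"), names(tab))
  other <- setdiff(names(tab), c("subject_id", feat_cols))
  tab <- tab[, c("subject_id", other, feat_cols), drop = FALSE]
  write.csv(tab, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(tab)
}

#' Read a feature or cohort table written by this package
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_feature_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

features_as_table <- function(features) {
  if (inherits(features, "fractal_features")) features <- list(features)
  if (!length(features)) return(data.frame(subject_id = character(0)))
  rows <- lapply(features, function(f) {
    data.frame(subject_id = f$subject_id, fd = f$fd, lacunarity = f$lacunarity,
               sphericity = f$sphericity, max_diameter_cm = f$max_diameter_cm,
               volume_mm3 = f$volume_mm3, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
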