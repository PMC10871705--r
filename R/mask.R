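#' Construct a binary lesion mask
#'
#' A `binary_mask` is a 3D voxel grid of 0/1 values together with the
#' metadata needed for volumetry and comparison: per-axis voxel spacing in
#' mm, an anatomical orientation string, and identifying tags (subject,
#' condition, source).
#'
#' Two masks entering a comparison must share grid shape, spacing, and
#' orientation; [cnt_compare()] enforces this.
#'
#' @param grid 3D array; any nonzero voxel is foreground. Values other than
#'   0/1 are binarized with a warning.
#' @param spacing numeric length-3, voxel edge lengths in mm (strictly
#'   positive). Default `c(0.8, 0.8, 0.8)`, an isotropic MNI-template grid
#'   common in lesion studies.
#' @param orientation axis-label string (e.g. `"LAS"`); purely metadata,
#'   carried through and checked for equality between compared masks.
#' @param subject_id,condition,source identifying tags carried into reports
#'   (e.g. condition `"original"`/`"harmonized"`, source `"scanner1"`).
#' @return An object of class `binary_mask`: a list with elements `grid`
#'   (integer 0/1 array), `spacing`, `orientation`, `subject_id`,
#'   `condition`, `source`.
#' @examples
#' m <- binary_mask(array(0L, c(4, 4, 4)))
#' m$grid[2, 2, 2] <- 1L
#' @export
binary_mask <- function(grid, spacing = c(0.8, 0.8, 0.8),
                        orientation = "LAS",
                        subject_id = "subject", condition = "",
                        source = "") {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive voxel edge lengths (mm)",
         call. = FALSE)
  vals <- unique(as.vector(grid))
  if (any(is.na(vals))) stop("mask contains NA voxels", call. = FALSE)
  if (!all(vals %in% c(0, 1))) {
    warning("mask contains values other than {0,1}; binarizing nonzero -> 1")
    grid <- (grid != 0)
  }
  storage.mode(grid) <- "integer"
  structure(
    list(grid = grid, spacing = as.numeric(spacing),
         orientation = orientation, subject_id = subject_id,
         condition = condition, source = source),
    class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask>", x$subject_id,
      if (nzchar(x$condition)) paste0("[", x$condition, "]"), "\n")
  cat("  grid: ", paste(dim(x$grid), collapse = " x "),
      "  spacing (mm): ", paste(format(x$spacing), collapse = " x "),
      "  orientation: ", x$orientation, "\n", sep = "")
  cat("  foreground voxels:", sum(x$grid),
      sprintf("(%.3f mm^3)", sum(x$grid) * prod(x$spacing)), "\n")
  invisible(x)
}

#' Validate that a pair of masks is comparable
#'
#' Checks identical grid shape, spacing and orientation. Called by every
#' pairwise operation; exposed for manifest validation.
#'
#' @param a,b `binary_mask` objects.
#' @return invisibly `TRUE`; otherwise an error of class `cnt_grid_mismatch`.
#' @export
check_same_grid <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!identical(dim(a$grid), dim(b$grid)) ||
      !isTRUE(all.equal(a$spacing, b$spacing)) ||
      !identical(a$orientation, b$orientation)) {
    stop(structure(class = c("cnt_grid_mismatch", "error", "condition"),
                   list(message = paste0(
                     "masks are not on the same grid: [",
                     paste(dim(a$grid), collapse = "x"), " @ ",
                     paste(a$spacing, collapse = "/"), " ", a$orientation,
                     "] vs [",
                     paste(dim(b$grid), collapse = "x"), " @ ",
                     paste(b$spacing, collapse = "/"), " ", b$orientation,
                     "]"),
                     call = sys.call(-1))))
  }
  invisible(TRUE)
}

#' Read a NIfTI file as a binary mask
#'
#' Any nonzero voxel becomes foreground; non-\{0,1\} inputs produce a
#' warning stating the binarization rule. Spacing is taken from the NIfTI
#' pixdim and orientation from the sform/qform axis labels.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @inheritParams binary_mask
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, subject_id = sub("\\.nii(\\.gz)?$", "",
                                             basename(path)),
                      condition = "", source = "") {
  if (!file.exists(path))
    stop("mask file does not exist: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.vector(img), d[1:3])
  } else if (length(d) != 3L) {
    stop("expected a 3D mask, got ", length(d), "D in ", path, call. = FALSE)
  } else img2 <- img
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing or invalid voxel spacing in ", path, call. = FALSE)
  orient <- tryCatch(RNifti::orientation(img), error = function(e) "unknown")
  binary_mask(array(as.array(img2), dim(img2)[1:3]), spacing = spacing,
              orientation = orient, subject_id = subject_id,
              condition = condition, source = source)
}

#' Write a binary mask (or any labeled grid) to NIfTI
#'
#' @param x a `binary_mask`, or a 3D integer array (e.g. a component-id map
#'   or CNT class-code map) plus explicit `spacing`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing, required when `x` is a bare array.
#' @return invisibly, `path`.
#' @export
write_mask <- function(x, path, spacing = NULL) {
  if (inherits(x, "binary_mask")) {
    grid <- x$grid; spacing <- x$spacing
  } else {
    if (is.null(spacing)) stop("`spacing` required for a bare array")
    grid <- x
  }
  img <- RNifti::asNifti(grid, internal = FALSE)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
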