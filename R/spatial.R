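#' Cohort disagreement heat map
#'
#' Per-voxel percentage of contributing masks with foreground at that
#' voxel: 100 means every subject had a marked voxel there. Typically fed
#' with per-subject Disagreement-class maps on a common template grid.
#'
#' @param masks list of [binary_mask()] (or 0/1 arrays) on identical
#'   grids; length >= 1.
#' @param spacing voxel spacing, taken from the first `binary_mask` if
#'   present.
#' @return Object of class `cnt_heatmap`: list `grid` (percentages 0-100),
#'   `spacing`, `n_subjects`, `orientation`.
#' @export
accumulate_heatmap <- function(masks, spacing = NULL) {
  stopifnot(length(masks) >= 1)
  orientation <- "unknown"
  arrs <- lapply(masks, function(m) {
    if (inherits(m, "binary_mask")) m$grid else m
  })
  if (inherits(masks[[1]], "binary_mask")) {
    spacing <- masks[[1]]$spacing
    orientation <- masks[[1]]$orientation
  }
  if (is.null(spacing)) stop("`spacing` required for bare arrays")
  dm <- dim(arrs[[1]])
  for (a in arrs)
    if (!identical(dim(a), dm))
      stop("heat-map inputs are not on identical grids", call. = FALSE)
  acc <- Reduce(`+`, lapply(arrs, function(a) (a != 0) * 1))
  structure(list(grid = 100 * acc / length(arrs), spacing = spacing,
                 n_subjects = length(arrs), orientation = orientation),
            class = "cnt_heatmap")
}

#' @export
print.cnt_heatmap <- function(x, ...) {
  cat("<cnt_heatmap> ", paste(dim(x$grid), collapse = " x "),
      " over ", x$n_subjects, " subject(s); max ",
      sprintf("%.1f%%", max(x$grid)), "\n", sep = "")
  invisible(x)
}

# axial stacking axis: the axis whose anatomical label is S or I; falls
# back to the third array axis when orientation is unknown
axial_axis <- function(orientation) {
  if (is.character(orientation) && nchar(orientation) == 3) {
    ax <- which(strsplit(toupper(orientation), "")[[1]] %in% c("S", "I"))
    if (length(ax) == 1) return(ax)
  }
  3L
}

#' Thin-slab maximum intensity projection
#'
#' Per-pixel maximum over a slab of adjacent slices centered on
#' `center_slice`. The default slab of 11 slices on a 0.8 mm grid spans
#' 8.8 mm. Slabs extending past the volume are clipped with a warning.
#'
#' @param map a `cnt_heatmap` or 3D array.
#' @param center_slice slice index (along the slab axis) anchoring the
#'   slab.
#' @param n_slices slab thickness in slices (odd; default 11).
#' @param axis `"axial"` (resolved from orientation metadata when
#'   available, otherwise the third array axis) or an explicit axis index
#'   1-3.
#' @return 2D matrix of slab maxima.
#' @export
ts_mip <- function(map, center_slice, n_slices = 11, axis = "axial") {
  grid <- if (inherits(map, "cnt_heatmap")) map$grid else map
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  if (identical(axis, "axial")) {
    axis <- axial_axis(if (inherits(map, "cnt_heatmap")) map$orientation
                       else "unknown")
  }
  if (!axis %in% 1:3) stop("invalid projection axis", call. = FALSE)
  nslc <- dim(grid)[axis]
  if (center_slice < 1 || center_slice > nslc)
    stop("center_slice outside the volume", call. = FALSE)
  half <- (n_slices - 1) %/% 2
  lo <- center_slice - half; hi <- center_slice + half
  if (lo < 1 || hi > nslc) {
    warning("slab clipped at volume boundary")
    lo <- max(1, lo); hi <- min(nslc, hi)
  }
  slices <- lapply(lo:hi, function(s) switch(axis,
    grid[s, , ], grid[, s, ], grid[, , s]))
  Reduce(pmax, slices)
}

#' Overlay a projection on a template slice
#'
#' Renders a grayscale template slice with the projection alpha-blended
#' on top wherever it exceeds `threshold`. Deterministic for fixed
#' inputs.
#'
#' @param template_slice 2D numeric matrix (any range; rescaled to
#'   `[0,1]`).
#' @param projection 2D matrix of the same shape (e.g. a [ts_mip()]
#'   result, 0-100).
#' @param threshold projection values <= threshold leave the template
#'   untouched.
#' @param colormap function mapping `[0,1]` to color, as from
#'   `grDevices::colorRamp`; default a dark-red-to-yellow heat ramp.
#' @param alpha blend weight of the projection color.
#' @return array `nrow x ncol x 3` of RGB in `[0,1]`.
#' @export
overlay_projection <- function(template_slice, projection, threshold = 0,
                               colormap = NULL, alpha = 0.7) {
  if (!identical(dim(template_slice), dim(projection)))
    stop("template and projection shapes differ", call. = FALSE)
  if (is.null(colormap))
    colormap <- grDevices::colorRamp(c("#67000d", "#ef3b2c", "#fed976"))
  tmax <- max(template_slice); tmin <- min(template_slice)
  gray <- if (tmax > tmin) (template_slice - tmin) / (tmax - tmin)
          else template_slice * 0
  rgb <- array(rep(gray, 3), c(dim(gray), 3))
  pmax_ <- max(projection)
  if (pmax_ > threshold) {
    sel <- projection > threshold
    pv <- (projection[sel] - threshold) / (max(pmax_, 1e-12) - threshold)
    cols <- colormap(pmin(1, pv)) / 255
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[sel] <- (1 - alpha) * plane[sel] + alpha * cols[, ch]
      rgb[, , ch] <- plane
    }
  }
  rgb
}

#' Write a rendered overlay (or any image array) as PNG
#'
#' @param img 2D matrix or H x W x 3 array in `[0,1]`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Write a heat map as NIfTI
#'
#' @param heatmap a `cnt_heatmap`.
#' @param path output `.nii`/`.nii.gz` path.
#' @return invisibly, `path`.
#' @export
write_heatmap <- function(heatmap, path) {
  stopifnot(inherits(heatmap, "cnt_heatmap"))
  write_mask(heatmap$grid, path, spacing = heatmap$spacing)
}
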