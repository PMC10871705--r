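#' Voxel neighborhood offsets for a 3D connectivity
#'
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+
#'   corners) — the standard 3D digital connectivities.
#' @param half if `TRUE`, return only one offset per unordered neighbor
#'   pair (used to enumerate undirected adjacencies exactly once).
#' @return integer matrix with columns dx, dy, dz.
#' @keywords internal
neighbor_offsets <- function(connectivity = 26, half = FALSE) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26", call. = FALSE)
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(g))
  keep <- ord > 0 & ord <= switch(as.character(connectivity),
                                  "6" = 1L, "18" = 2L, "26" = 3L)
  g <- g[keep, , drop = FALSE]
  if (half) {
    # keep the lexicographically positive half
    pos <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 |
             (g[, 2] == 0 & g[, 1] > 0)))
    g <- g[pos, , drop = FALSE]
  }
  g
}

#' Extract connected components (lesions) from a binary mask
#'
#' Labels the foreground of a 3D binary mask into maximal connected
#' components under the chosen voxel connectivity. Components are numbered
#' deterministically by raster order of their first-encountered voxel
#' (array storage order: first axis fastest), so repeated runs are
#' byte-identical.
#'
#' Adjacencies are enumerated vectorized over foreground voxels and the
#' components found on the resulting voxel graph (via igraph).
#'
#' @param mask a [binary_mask()].
#' @param connectivity 6, 18 or 26 (default 26, the neuroimaging convention
#'   for lesion counting).
#' @return Object of class `cnt_components`: list with `label_grid` (integer
#'   array, 0 background, 1..K), `sizes` (voxel count per component),
#'   `count` (K), `connectivity`, `spacing`, `subject_id`, `source`.
#' @examples
#' m <- binary_mask(array(0L, c(5, 5, 5)), spacing = c(1, 1, 1))
#' m$grid[1:2, 1, 1] <- 1L; m$grid[4:5, 5, 5] <- 1L
#' cs <- extract_components(m)
#' cs$count   # 2
#' @export
extract_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be one of 6, 18, 26", call. = FALSE)
  dm <- dim(mask$grid)
  fg <- which(mask$grid != 0L)             # linear indices, raster order
  lab <- array(0L, dm)
  if (length(fg) == 0L) {
    return(structure(list(label_grid = lab, sizes = integer(0), count = 0L,
                          connectivity = as.integer(connectivity),
                          spacing = mask$spacing,
                          subject_id = mask$subject_id, source = mask$source),
                     class = "cnt_components"))
  }
  node <- integer(prod(dm))                # linear voxel -> node id
  node[fg] <- seq_along(fg)
  coords <- arrayInd(fg, dm)
  offs <- neighbor_offsets(connectivity, half = TRUE)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- coords
    nb[, 1] <- nb[, 1] + offs[r, 1]
    nb[, 2] <- nb[, 2] + offs[r, 2]
    nb[, 3] <- nb[, 3] + offs[r, 3]
    ok <- nb[, 1] >= 1L & nb[, 1] <= dm[1] &
          nb[, 2] >= 1L & nb[, 2] <= dm[2] &
          nb[, 3] >= 1L & nb[, 3] <= dm[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1L) * (dm[1] * dm[2]) +
           (nb[ok, 2] - 1L) * dm[1] + nb[ok, 1]
    nbnode <- node[lin]
    hit <- nbnode > 0L
    from <- c(from, which(ok)[hit])
    to <- c(to, nbnode[hit])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  # renumber by raster order of first-encountered voxel: fg is sorted, so
  # the first occurrence of each membership value is its raster rank
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  lab[fg] <- relab[memb]
  sizes <- tabulate(relab[memb])
  structure(list(label_grid = lab, sizes = as.integer(sizes),
                 count = length(sizes),
                 connectivity = as.integer(connectivity),
                 spacing = mask$spacing,
                 subject_id = mask$subject_id, source = mask$source),
            class = "cnt_components")
}

#' @export
print.cnt_components <- function(x, ...) {
  cat("<cnt_components> ", x$count, " component(s), ",
      x$connectivity, "-connectivity\n", sep = "")
  if (x$count > 0)
    cat("  sizes (voxels): ",
        paste(utils::head(x$sizes, 10), collapse = ", "),
        if (x$count > 10) ", ...", "\n", sep = "")
  invisible(x)
}

#' Physical volume of a labeled component
#'
#' Voxel count times the voxel volume (product of spacings). On a 0.8 mm
#' isotropic grid one voxel is 0.512 mm^3.
#'
#' @param component_size voxel count (positive integer), or a
#'   `cnt_components` object (returns the vector of all component volumes).
#' @param spacing per-axis voxel edge length, mm.
#' @return volume(s) in mm^3.
#' @export
lesion_volume <- function(component_size, spacing = NULL) {
  if (inherits(component_size, "cnt_components")) {
    spacing <- component_size$spacing
    component_size <- component_size$sizes
  }
  if (any(component_size <= 0))
    stop("empty component has no volume", call. = FALSE)
  component_size * prod(spacing)
}
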