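#' Construct a bipartite overlap graph
#'
#' The overlap graph links component `g` of delineation G to component `h`
#' of delineation H exactly when their voxel sets intersect; the edge
#' weight is the exact voxel intersection count. The degree of a node is
#' the cardinality-of-intersection operator: the number of components of
#' the opposite delineation it intersects.
#'
#' `overlap_graph()` builds the object directly from node counts and an
#' edge list (used for synthetic topologies and exhaustive enumeration);
#' [build_overlap_graph()] derives it from two labeled component sets.
#'
#' @param n_left,n_right component counts I and J of G and H.
#' @param edges data.frame/matrix with columns `g`, `h`, `weight`
#'   (positive integers); may have zero rows.
#' @param sizes_left,sizes_right voxel counts per component (optional for
#'   synthetic graphs; required for SDI computations).
#' @return Object of class `cnt_overlap`: list with `n_left`, `n_right`,
#'   `edges`, `deg_left`, `deg_right`, `sizes_left`, `sizes_right`.
#' @export
overlap_graph <- function(n_left, n_right, edges = NULL,
                          sizes_left = NULL, sizes_right = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(g = integer(0), h = integer(0), weight = integer(0))
  } else {
    edges <- as.data.frame(edges)
    names(edges) <- c("g", "h", "weight")[seq_len(ncol(edges))]
    if (is.null(edges$weight)) edges$weight <- 1L
    if (any(edges$weight <= 0))
      stop("edge weights must be positive voxel counts", call. = FALSE)
    if (any(edges$g < 1 | edges$g > n_left) ||
        any(edges$h < 1 | edges$h > n_right))
      stop("edge references a component id outside 1..K", call. = FALSE)
    if (anyDuplicated(edges[c("g", "h")]))
      stop("duplicate (g,h) edge", call. = FALSE)
  }
  structure(list(
    n_left = as.integer(n_left), n_right = as.integer(n_right),
    edges = edges,
    deg_left = tabulate(edges$g, nbins = n_left),
    deg_right = tabulate(edges$h, nbins = n_right),
    sizes_left = sizes_left, sizes_right = sizes_right),
    class = "cnt_overlap")
}

#' @rdname overlap_graph
#' @param G,H `cnt_components` objects on the same grid.
#' @examples
#' m <- binary_mask(array(0L, c(4, 4, 1)), spacing = c(1, 1, 1))
#' a <- b <- m
#' a$grid[1:2, 1, 1] <- 1L
#' b$grid[2:3, 1, 1] <- 1L
#' og <- build_overlap_graph(extract_components(a), extract_components(b))
#' og$edges  # one edge of weight 1
#' @export
build_overlap_graph <- function(G, H) {
  stopifnot(inherits(G, "cnt_components"), inherits(H, "cnt_components"))
  if (!identical(dim(G$label_grid), dim(H$label_grid)))
    stop("component sets are not on the same grid", call. = FALSE)
  both <- G$label_grid > 0L & H$label_grid > 0L
  if (any(both)) {
    gl <- G$label_grid[both]
    hl <- H$label_grid[both]
    key <- (gl - 1L) * H$count + hl
    cnt <- tabulate(key, nbins = G$count * H$count)
    nz <- which(cnt > 0L)
    edges <- data.frame(g = (nz - 1L) %/% H$count + 1L,
                        h = (nz - 1L) %% H$count + 1L,
                        weight = cnt[nz])
  } else edges <- NULL
  overlap_graph(G$count, H$count, edges, G$sizes, H$sizes)
}

#' @export
print.cnt_overlap <- function(x, ...) {
  cat("<cnt_overlap> ", x$n_left, " x ", x$n_right, " components, ",
      nrow(x$edges), " overlap edge(s)\n", sep = "")
  invisible(x)
}

#' Cardinality of intersection for one component
#'
#' The number of components of the opposite delineation intersected by the
#' named component — its degree in the overlap graph.
#'
#' @param graph a `cnt_overlap`.
#' @param component_id component id on `side`.
#' @param side `"G"` (left) or `"H"` (right).
#' @return nonnegative integer.
#' @export
intersection_cardinality <- function(graph, component_id, side = c("G", "H")) {
  stopifnot(inherits(graph, "cnt_overlap"))
  side <- match.arg(side)
  n <- if (side == "G") graph$n_left else graph$n_right
  if (length(component_id) != 1L || is.na(component_id) ||
      component_id < 1 || component_id > n)
    stop("unknown component id ", component_id, " on side ", side,
         call. = FALSE)
  if (side == "G") graph$deg_left[component_id] else
    graph$deg_right[component_id]
}
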