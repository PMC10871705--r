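#' @name taxonomy
#' @title Object-correspondence taxonomies for paired segmentations
#'
#' @description
#' Two classification schemes over the bipartite overlap graph of the
#' connected components of two delineations.
#'
#' The six-class Nascimento taxonomy operates on the connected subgraphs
#' of the overlap graph, using the X–Y count of components on each side:
#' \itemize{
#'   \item 1–0 isolated left node: \strong{DetectionFailure}
#'   \item 0–1 isolated right node: \strong{FalseAlarm}
#'   \item 1–1: \strong{CorrectDetection}
#'   \item 1–N (N>1): \strong{Split}
#'   \item M–1 (M>1): \strong{Merge}
#'   \item M–N (M,N>1): \strong{SplitMerge}
#' }
#'
#' The three-class condensed taxonomy (CNT) treats the two delineations as
#' equally authoritative and is defined per node from intersection
#' cardinalities: degree 0 is \strong{Disagreement}; degree 1 with a
#' partner of degree 1 is \strong{Agreement} (a matched pair); anything
#' else — degree > 1, or degree 1 against a partner of degree > 1 — is
#' \strong{Checkered}. Every component receives exactly one class under
#' each scheme, and condensing the six classes
#' (CorrectDetection→Agreement; DetectionFailure, FalseAlarm→Disagreement;
#' Split, Merge, SplitMerge→Checkered) reproduces the per-node CNT rules.
NULL

NASCIMENTO_CLASSES <- c("CorrectDetection", "DetectionFailure", "FalseAlarm",
                        "Split", "Merge", "SplitMerge")
CNT_CLASSES <- c("Agreement", "Disagreement", "Checkered")

# connected subgraphs of the bipartite overlap graph; returns a list of
# list(left=ids, right=ids)
overlap_subgraphs <- function(graph) {
  nl <- graph$n_left; nr <- graph$n_right
  g <- igraph::make_empty_graph(n = nl + nr, directed = FALSE)
  if (nrow(graph$edges))
    g <- igraph::add_edges(g, rbind(graph$edges$g, nl + graph$edges$h))
  memb <- igraph::components(g)$membership
  lapply(split(seq_len(nl + nr), memb), function(v)
    list(left = v[v <= nl], right = v[v > nl] - nl))
}

#' Classify components under the six-class Nascimento taxonomy
#'
#' @param graph a [overlap_graph()].
#' @return Object of class `cnt_nascimento`: list with `left` and `right`
#'   (character class per component id), and `subgraphs` (the connected
#'   subgraphs each assignment derives from).
#' @seealso [classify_cnt()], [condense()]
#' @export
classify_nascimento <- function(graph) {
  stopifnot(inherits(graph, "cnt_overlap"))
  subs <- overlap_subgraphs(graph)
  left <- character(graph$n_left)
  right <- character(graph$n_right)
  for (s in subs) {
    m <- length(s$left); n <- length(s$right)
    cls <-
      if (m == 1 && n == 0) "DetectionFailure"
      else if (m == 0 && n == 1) "FalseAlarm"
      else if (m == 1 && n == 1) "CorrectDetection"
      else if (m == 1 && n > 1) "Split"
      else if (m > 1 && n == 1) "Merge"
      else "SplitMerge"
    left[s$left] <- cls
    right[s$right] <- cls
  }
  structure(list(left = left, right = right, subgraphs = subs),
            class = "cnt_nascimento")
}

#' Classify components under the condensed (three-class) taxonomy
#'
#' Direct per-node application of the CNT set definitions (see
#' [taxonomy]). Matched one-to-one pairs are recorded in `pairs`.
#'
#' @param graph a [overlap_graph()].
#' @return Object of class `cnt_labeling`: list with `left`, `right`
#'   (class per component), and `pairs` (data.frame `g`, `h` of Agreement
#'   pairs).
#' @export
classify_cnt <- function(graph) {
  stopifnot(inherits(graph, "cnt_overlap"))
  dl <- graph$deg_left; dr <- graph$deg_right
  e <- graph$edges
  left <- ifelse(dl == 0, "Disagreement", "Checkered")
  right <- ifelse(dr == 0, "Disagreement", "Checkered")
  # degree-1 nodes whose unique partner also has degree 1 -> Agreement
  pair_ok <- dl[e$g] == 1 & dr[e$h] == 1
  left[e$g[pair_ok]] <- "Agreement"
  right[e$h[pair_ok]] <- "Agreement"
  pairs <- e[pair_ok, c("g", "h"), drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(left = as.character(left), right = as.character(right),
                 pairs = pairs),
            class = "cnt_labeling")
}

#' Condense a six-class labeling into the three-class taxonomy
#'
#' CorrectDetection maps to Agreement; DetectionFailure and FalseAlarm to
#' Disagreement; Split, Merge and SplitMerge to Checkered. For every
#' overlap graph `condense(classify_nascimento(g))` equals
#' `classify_cnt(g)` component-for-component.
#'
#' @param labeling a `cnt_nascimento` labeling.
#' @return a `cnt_labeling`.
#' @export
condense <- function(labeling) {
  stopifnot(inherits(labeling, "cnt_nascimento"))
  map <- c(CorrectDetection = "Agreement",
           DetectionFailure = "Disagreement",
           FalseAlarm = "Disagreement",
           Split = "Checkered", Merge = "Checkered",
           SplitMerge = "Checkered")
  bad <- setdiff(unique(c(labeling$left, labeling$right)), names(map))
  if (length(bad))
    stop("unknown Nascimento class: ", paste(bad, collapse = ", "),
         call. = FALSE)
  pr <- lapply(labeling$subgraphs, function(s)
    if (length(s$left) == 1 && length(s$right) == 1)
      c(g = s$left, h = s$right))
  pr <- do.call(rbind, pr[!vapply(pr, is.null, TRUE)])
  pairs <- if (is.null(pr)) data.frame(g = integer(0), h = integer(0))
           else data.frame(g = as.integer(pr[, 1]), h = as.integer(pr[, 2]))
  pairs <- pairs[order(pairs$g), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(left = unname(map[labeling$left]),
                 right = unname(map[labeling$right]),
                 pairs = pairs),
            class = "cnt_labeling")
}

#' @export
print.cnt_labeling <- function(x, ...) {
  cat("<cnt_labeling>\n  G:",
      paste(names(table(factor(x$left, CNT_CLASSES))),
            table(factor(x$left, CNT_CLASSES)), collapse = ", "), "\n  H:",
      paste(names(table(factor(x$right, CNT_CLASSES))),
            table(factor(x$right, CNT_CLASSES)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.cnt_nascimento <- function(x, ...) {
  tab <- table(factor(c(x$left, x$right), NASCIMENTO_CLASSES))
  cat("<cnt_nascimento>", paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

#' Sorensen-Dice index of two voxel sets
#'
#' `2|A∩B| / (|A|+|B|)`, in `[0,1]`, 1 for perfect overlap, 0 for none.
#' Accepts logical/0-1 arrays on a common grid or integer voxel-index
#' vectors. Both-empty input has no defined value and raises an error of
#' class `cnt_undefined_sdi` so the caller chooses a convention.
#'
#' @param A,B voxel sets: logical (or 0/1) arrays of identical dimension,
#'   or vectors of voxel linear indices.
#' @return numeric in `[0,1]`.
#' @examples
#' a <- c(1:100); b <- c(51:100, 201:250)
#' sdi(a, b)  # 2*50/150
#' @export
sdi <- function(A, B) {
  if (is.array(A) || is.array(B)) {
    stopifnot(identical(dim(A), dim(B)))
    A <- which(A != 0); B <- which(B != 0)
  }
  na <- length(A); nb <- length(B)
  if (na + nb == 0L)
    stop(structure(class = c("cnt_undefined_sdi", "error", "condition"),
                   list(message = "SDI undefined: both sets empty",
                        call = sys.call(-1))))
  2 * length(intersect(A, B)) / (na + nb)
}
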