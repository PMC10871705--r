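#' Whole-foreground Sorensen-Dice index of two masks
#'
#' The subject-level agreement measure: SDI applied to the full foreground
#' of each delineation.
#'
#' @param maskG,maskH [binary_mask()] objects on the same grid.
#' @return numeric in `[0,1]`; error of class `cnt_undefined_sdi` if both
#'   masks are empty.
#' @export
global_sdi <- function(maskG, maskH) {
  check_same_grid(maskG, maskH)
  sdi(maskG$grid, maskH$grid)
}

#' Per-lesion SDI records under the condensed taxonomy
#'
#' One record per Agreement pair (symmetric SDI of the two members), one
#' record per Checkered component per side (SDI of the component against
#' the union of its overlapping partners), and one record per Disagreement
#' component per side (SDI 0 by definition). All quantities derive from the
#' overlap graph: components of one delineation are pairwise disjoint, so
#' intersection and union cardinalities are sums of edge weights and
#' component sizes.
#'
#' @param graph a [overlap_graph()] with component sizes.
#' @param labeling the matching [classify_cnt()] labeling.
#' @param spacing voxel spacing (mm) for volumes.
#' @param subject_id tag copied into the records.
#' @return data.frame with columns `subject_id`, `side` (`"G"`, `"H"`, or
#'   `"G+H"` for a matched pair), `component_id`, `cnt_class`,
#'   `volume_mm3`, `lesion_sdi`, `partner_ids` (comma-separated). An
#'   Agreement record's volume is the mean of the two members' volumes.
#' @export
per_lesion_sdi <- function(graph, labeling, spacing = c(1, 1, 1),
                           subject_id = "subject") {
  stopifnot(inherits(graph, "cnt_overlap"), inherits(labeling, "cnt_labeling"))
  if (is.null(graph$sizes_left) || is.null(graph$sizes_right))
    stop("graph lacks component sizes; build it from component sets",
         call. = FALSE)
  vox <- prod(spacing)
  e <- graph$edges
  rec <- list()
  ## Agreement: one symmetric record per matched pair
  if (nrow(labeling$pairs)) {
    p <- labeling$pairs
    w <- e$weight[match(paste(p$g, p$h), paste(e$g, e$h))]
    sg <- graph$sizes_left[p$g]; sh <- graph$sizes_right[p$h]
    rec[[length(rec) + 1L]] <- data.frame(
      subject_id = subject_id, side = "G+H", component_id = p$g,
      cnt_class = "Agreement", volume_mm3 = (sg + sh) / 2 * vox,
      lesion_sdi = 2 * w / (sg + sh),
      partner_ids = as.character(p$h))
  }
  one_side <- function(side) {
    cls <- if (side == "G") labeling$left else labeling$right
    sizes <- if (side == "G") graph$sizes_left else graph$sizes_right
    osizes <- if (side == "G") graph$sizes_right else graph$sizes_left
    ids <- which(cls != "Agreement")
    if (!length(ids)) return(NULL)
    own <- if (side == "G") e$g else e$h
    oth <- if (side == "G") e$h else e$g
    out <- lapply(ids, function(i) {
      sel <- own == i
      partners <- oth[sel]
      s <- if (length(partners))
        2 * sum(e$weight[sel]) / (sizes[i] + sum(osizes[partners])) else 0
      data.frame(subject_id = subject_id, side = side, component_id = i,
                 cnt_class = cls[i], volume_mm3 = sizes[i] * vox,
                 lesion_sdi = s,
                 partner_ids = paste(partners, collapse = ","))
    })
    do.call(rbind, out)
  }
  rec[[length(rec) + 1L]] <- one_side("G")
  rec[[length(rec) + 1L]] <- one_side("H")
  out <- do.call(rbind, rec[!vapply(rec, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(subject_id = character(0), side = character(0),
                      component_id = integer(0), cnt_class = character(0),
                      volume_mm3 = numeric(0), lesion_sdi = numeric(0),
                      partner_ids = character(0))
  rownames(out) <- NULL
  out
}

#' Disagreement volume of a comparison
#'
#' Total volume of lesions present in one delineation with no voxel
#' overlap in the other, reported per side and combined.
#'
#' @inheritParams per_lesion_sdi
#' @return list with `total_mm3`, `G_mm3`, `H_mm3`.
#' @export
disagreement_volume <- function(graph, labeling, spacing = c(1, 1, 1)) {
  stopifnot(inherits(graph, "cnt_overlap"), inherits(labeling, "cnt_labeling"))
  vox <- prod(spacing)
  gvol <- sum(graph$sizes_left[labeling$left == "Disagreement"]) * vox
  hvol <- sum(graph$sizes_right[labeling$right == "Disagreement"]) * vox
  list(total_mm3 = gvol + hvol, G_mm3 = gvol, H_mm3 = hvol)
}

#' Descriptive statistics for one CNT class
#'
#' Range, median, mean and SD of a chosen measure over the lesion records
#' of one class — the row format used for class summary tables.
#'
#' @param records data.frame from [per_lesion_sdi()].
#' @param class one of `"Agreement"`, `"Disagreement"`, `"Checkered"`.
#' @param measure `"lesion_sdi"` or `"volume_mm3"`.
#' @return list `range` (length 2), `median`, `mean`, `sd`, `n`; or an
#'   empty-summary marker (`n = 0`, all else `NA`) when no records exist.
#' @export
summarize_class <- function(records, class = CNT_CLASSES,
                            measure = c("lesion_sdi", "volume_mm3")) {
  class <- match.arg(class)
  measure <- match.arg(measure)
  v <- records[[measure]][records$cnt_class == class]
  if (!length(v))
    return(list(range = c(NA_real_, NA_real_), median = NA_real_,
                mean = NA_real_, sd = NA_real_, n = 0L, empty = TRUE))
  list(range = range(v), median = stats::median(v), mean = mean(v),
       sd = if (length(v) > 1) stats::sd(v) else 0, n = length(v),
       empty = FALSE)
}

#' Compare two delineations lesion-wise
#'
#' The main entry point: extracts connected components of both masks,
#' builds the bipartite overlap graph, classifies every component under
#' the six-class and condensed taxonomies, and assembles per-lesion
#' records plus subject-level summaries.
#'
#' @param maskG,maskH [binary_mask()] objects on the same grid.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Object of class `cnt_comparison`: list with `components_G/H`,
#'   `graph`, `nascimento`, `cnt`, `records` (per-lesion data.frame),
#'   `global_sdi` (NA with `no_lesions = TRUE` if both masks empty),
#'   `class_counts` (components per CNT class per side),
#'   `disagreement_volume`, `spacing`, `connectivity`, `subject_id`,
#'   `condition`.
#' @examples
#' a <- b <- binary_mask(array(0L, c(8, 8, 8)), spacing = c(1, 1, 1))
#' a$grid[2:4, 2:4, 2:4] <- 1L
#' b$grid[3:5, 2:4, 2:4] <- 1L
#' cmp <- cnt_compare(a, b)
#' cmp$global_sdi
#' @export
cnt_compare <- function(maskG, maskH, connectivity = 26) {
  check_same_grid(maskG, maskH)
  G <- extract_components(maskG, connectivity)
  H <- extract_components(maskH, connectivity)
  graph <- build_overlap_graph(G, H)
  nas <- classify_nascimento(graph)
  lab <- classify_cnt(graph)
  no_lesions <- G$count == 0L && H$count == 0L
  gs <- if (no_lesions) NA_real_ else global_sdi(maskG, maskH)
  records <- per_lesion_sdi(graph, lab, maskG$spacing, maskG$subject_id)
  counts <- sapply(CNT_CLASSES, function(k)
    c(G = sum(lab$left == k), H = sum(lab$right == k)))
  structure(list(
    components_G = G, components_H = H, graph = graph,
    nascimento = nas, cnt = lab, records = records,
    global_sdi = gs, no_lesions = no_lesions,
    class_counts = counts,
    disagreement_volume = disagreement_volume(graph, lab, maskG$spacing),
    spacing = maskG$spacing, connectivity = as.integer(connectivity),
    subject_id = maskG$subject_id, condition = maskG$condition),
    class = "cnt_comparison")
}

#' @export
print.cnt_comparison <- function(x, ...) {
  cat("<cnt_comparison> subject", x$subject_id,
      if (nzchar(x$condition)) paste0("[", x$condition, "]"), "\n")
  cat("  components: G =", x$components_G$count,
      " H =", x$components_H$count,
      sprintf(" (%d-connectivity)\n", x$connectivity))
  if (x$no_lesions) cat("  no lesions in either mask; SDI undefined\n")
  else cat(sprintf("  global SDI: %.3f\n", x$global_sdi))
  cc <- x$class_counts
  cat("  CNT components (G/H): ",
      paste(sprintf("%s %d/%d", colnames(cc), cc["G", ], cc["H", ]),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  disagreement volume: %.3f mm^3 (G %.3f, H %.3f)\n",
              x$disagreement_volume$total_mm3,
              x$disagreement_volume$G_mm3, x$disagreement_volume$H_mm3))
  invisible(x)
}

#' @export
summary.cnt_comparison <- function(object, ...) {
  out <- list(comparison = object)
  for (k in CNT_CLASSES) {
    out[[paste0(tolower(k), "_sdi")]] <-
      summarize_class(object$records, k, "lesion_sdi")
    out[[paste0(tolower(k), "_volume")]] <-
      summarize_class(object$records, k, "volume_mm3")
  }
  class(out) <- "summary.cnt_comparison"
  out
}

#' @export
print.summary.cnt_comparison <- function(x, ...) {
  print(x$comparison)
  fmt <- function(s) if (s$empty) "  (no lesions)"
    else sprintf("  range [%.3f, %.3f]  med %.3f  mean %.3f (+/- %.3f)  n=%d",
                 s$range[1], s$range[2], s$median, s$mean, s$sd, s$n)
  for (k in CNT_CLASSES) {
    cat(k, "class SDI:\n", fmt(x[[paste0(tolower(k), "_sdi")]]), "\n")
    cat(k, "class volume (mm^3):\n",
        fmt(x[[paste0(tolower(k), "_volume")]]), "\n")
  }
  invisible(x)
}

#' Scatter of per-lesion SDI against volume
#'
#' Volume on a log10 x-axis, colored by CNT class, with optional per-class
#' least-squares fits of SDI on log10 volume and pointwise confidence
#' bands. Disagreement lesions (SDI 0 by definition) are omitted.
#'
#' @param x a `cnt_comparison` (or a records data.frame via `records`).
#' @param fits draw per-class linear fits with confidence bands.
#' @param level band level.
#' @param ... passed to `plot`.
#' @export
plot.cnt_comparison <- function(x, fits = TRUE, level = 0.95, ...) {
  r <- x$records
  r <- r[r$cnt_class != "Disagreement" & r$volume_mm3 > 0, , drop = FALSE]
  if (!nrow(r)) {
    warning("no Agreement/Checkered lesions to plot"); return(invisible(x))
  }
  cols <- c(Agreement = "#1b9e77", Checkered = "#d95f02")
  plot(log10(r$volume_mm3), r$lesion_sdi, col = cols[r$cnt_class],
       pch = ifelse(r$cnt_class == "Agreement", 16, 17),
       xlab = "log10 lesion volume (mm^3)", ylab = "per-lesion SDI",
       ylim = c(0, 1), ...)
  if (fits) for (k in names(cols)) {
    rr <- r[r$cnt_class == k, ]
    if (nrow(rr) >= 3 && length(unique(rr$volume_mm3)) > 1) {
      f <- linear_fit_ci(log10(rr$volume_mm3), rr$lesion_sdi, level = level)
      ord <- order(f$band$x)
      graphics::lines(f$band$x[ord], f$band$fit[ord], col = cols[k], lwd = 2)
      graphics::polygon(c(f$band$x[ord], rev(f$band$x[ord])),
                        c(f$band$lwr[ord], rev(f$band$upr[ord])),
                        col = grDevices::adjustcolor(cols[k], 0.2),
                        border = NA)
    }
  }
  graphics::legend("topleft", legend = names(cols), col = cols,
                   pch = c(16, 17), bty = "n")
  invisible(x)
}

#' Per-voxel CNT class-code map
#'
#' Codes: 0 background, 1 Agreement, 2 Disagreement, 3 Checkered. On
#' overlap voxels the two covering components always share a CNT class
#' (Agreement partners are both Agreement; any overlapping non-pair
#' components are both Checkered), so the per-voxel code is well defined.
#'
#' @param comparison a `cnt_comparison`.
#' @param classes subset of classes to paint (others left 0).
#' @return integer 3D array of class codes.
#' @export
class_map <- function(comparison, classes = CNT_CLASSES) {
  stopifnot(inherits(comparison, "cnt_comparison"))
  code <- c(Agreement = 1L, Disagreement = 2L, Checkered = 3L)
  lg <- comparison$components_G$label_grid
  lh <- comparison$components_H$label_grid
  out <- array(0L, dim(lg))
  lcode <- code[comparison$cnt$left]; lcode[!comparison$cnt$left %in% classes] <- 0L
  rcode <- code[comparison$cnt$right]; rcode[!comparison$cnt$right %in% classes] <- 0L
  if (comparison$components_G$count)
    out[lg > 0L] <- lcode[lg[lg > 0L]]
  if (comparison$components_H$count) {
    hsel <- lh > 0L & out == 0L
    out[hsel] <- rcode[lh[hsel]]
  }
  out
}
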