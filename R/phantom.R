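#' @name phantom
#' @title Synthetic paired-delineation phantom
#' @description
#' A mask-level phantom that emulates the structure of a paired
#' intra-rater lesion study: a shared ground truth of discrete
#' ellipsoidal lesions per subject, and two rater masks derived from that
#' truth by independent detection failures, smooth boundary jitter,
#' split/merge events and false-positive blobs. The phantom knows its own
#' event log, so expected CNT class counts are available in closed form
#' for parameter-recovery checks. It does not model MRI intensities —
#' only delineation geometry.
NULL

# deterministic substream seeds below 2^31, derived from a master seed
# and a stream label
derive_seed <- function(master, ...) {
  lab <- paste(c(...), collapse = "/")
  h <- 0
  for (k in utf8ToInt(lab)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(master) %% 1048573 * 2039 + h) %% 2147483629 + 1)
}

#' Rater noise model
#'
#' @param p_det probability a true lesion is delineated.
#' @param jitter_mm boundary jitter scale (mm): smooth perturbation of the
#'   lesion boundary, realized as random shifts of the lesion center and
#'   radii of this magnitude.
#' @param p_split probability a detected lesion is cut by removing a
#'   1-voxel-thick interior plane.
#' @param p_merge probability a detected lesion is bridged to its nearest
#'   detected neighbor.
#' @param fp_rate Poisson mean number of false-positive blobs per mask.
#' @return list of class `cnt_rater_model`.
#' @export
rater_model <- function(p_det = 1, jitter_mm = 0, p_split = 0,
                        p_merge = 0, fp_rate = 0) {
  stopifnot(p_det >= 0, p_det <= 1, p_split >= 0, p_split <= 1,
            p_merge >= 0, p_merge <= 1, jitter_mm >= 0, fp_rate >= 0)
  structure(list(p_det = p_det, jitter_mm = jitter_mm, p_split = p_split,
                 p_merge = p_merge, fp_rate = fp_rate),
            class = "cnt_rater_model")
}

#' Phantom specification
#'
#' Defaults describe one synthetic subject on a 0.8 mm isotropic template
#' grid with 30 discrete white-matter-lesion-like blobs of log-normal
#' size (median radius 3 mm), pairwise separated so that true lesions
#' never touch.
#'
#' @param grid_shape 3D grid dimensions (voxels).
#' @param spacing voxel spacing, mm.
#' @param n_lesions number of true lesions.
#' @param radius_meanlog,radius_sdlog log-normal parameters of the base
#'   lesion radius in mm.
#' @param min_gap minimum inter-lesion gap, voxels.
#' @param raters named list of two [rater_model()]s.
#' @param seed master seed; all randomness flows from it via named
#'   substreams (truth, rater1, rater2).
#' @return list of class `cnt_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         spacing = c(0.8, 0.8, 0.8),
                         n_lesions = 30,
                         radius_meanlog = log(3), radius_sdlog = 0.35,
                         min_gap = 2,
                         raters = list(rater1 = rater_model(),
                                       rater2 = rater_model()),
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            all(spacing > 0), n_lesions >= 0, radius_sdlog >= 0,
            min_gap >= 0, length(raters) == 2)
  stopifnot(vapply(raters, inherits, TRUE, "cnt_rater_model"))
  if (is.null(names(raters))) names(raters) <- c("rater1", "rater2")
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 n_lesions = as.integer(n_lesions),
                 radius_meanlog = radius_meanlog,
                 radius_sdlog = radius_sdlog,
                 min_gap = min_gap, raters = raters,
                 seed = as.integer(seed)),
            class = "cnt_phantom_spec")
}

# linear voxel indices of an ellipsoid; voxel centers at (i - 0.5) * spacing
rasterize_ellipsoid <- function(center, radii, grid_shape, spacing) {
  lo <- pmax(1L, floor((center - radii) / spacing - 0.5) + 1L)
  hi <- pmin(grid_shape, ceiling((center + radii) / spacing + 0.5))
  if (any(lo > hi)) return(integer(0))
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  qx <- (((ix - 0.5) * spacing[1] - center[1]) / radii[1])^2
  qy <- (((iy - 0.5) * spacing[2] - center[2]) / radii[2])^2
  qz <- (((iz - 0.5) * spacing[3] - center[3]) / radii[3])^2
  q <- outer(outer(qx, qy, "+"), qz, "+")
  inside <- which(q <= 1)
  if (!length(inside)) return(integer(0))
  coord <- arrayInd(inside, dim(q))
  (iz[coord[, 3]] - 1L) * (grid_shape[1] * grid_shape[2]) +
    (iy[coord[, 2]] - 1L) * grid_shape[1] + ix[coord[, 1]]
}

#' Generate a phantom ground truth
#'
#' Places `n_lesions` ellipsoids with log-normal base radii and mild
#' per-axis anisotropy, centers uniform in the volume, rejecting
#' placements that violate the inter-lesion gap (conservative
#' center-distance bound). Fully determined by the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed optional override of the truth substream seed.
#' @param retry_budget placement attempts per lesion before giving up.
#' @return Object of class `cnt_phantom_truth`: list `spec`, `lesions`
#'   (data.frame id, center/radii in mm), `mask` (a [binary_mask()]).
#' @export
generate_truth <- function(spec, seed = NULL,
                           retry_budget = 400) {
  stopifnot(inherits(spec, "cnt_phantom_spec"))
  if (is.null(seed)) seed <- derive_seed(spec$seed, "truth")
  set.seed(seed)
  extent <- spec$grid_shape * spec$spacing
  gap_mm <- spec$min_gap * max(spec$spacing)
  maxr <- min(extent) / 4
  les <- matrix(NA_real_, spec$n_lesions, 7)
  colnames(les) <- c("cx", "cy", "cz", "rx", "ry", "rz", "r0")
  k <- 0
  while (k < spec$n_lesions) {
    placed <- FALSE
    for (try in seq_len(retry_budget)) {
      r0 <- min(maxr, stats::rlnorm(1, spec$radius_meanlog, spec$radius_sdlog))
      radii <- pmax(min(spec$spacing) * 0.8, r0 * stats::runif(3, 0.8, 1.25))
      rmax <- max(radii)
      if (any(extent <= 2 * (rmax + gap_mm))) next
      center <- stats::runif(3, rmax + gap_mm / 2, extent - rmax - gap_mm / 2)
      ok <- TRUE
      if (k > 0) {
        dc <- sqrt(colSums((t(les[seq_len(k), 1:3, drop = FALSE]) - center)^2))
        ok <- all(dc >= rmax + apply(les[seq_len(k), 4:6, drop = FALSE],
                                     1, max) + gap_mm)
      }
      if (ok) {
        k <- k + 1; les[k, ] <- c(center, radii, r0); placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place ", spec$n_lesions, " lesions after ",
           retry_budget, " attempts each; reduce n_lesions or enlarge ",
           "the grid", call. = FALSE)
  }
  lesions <- data.frame(id = seq_len(spec$n_lesions),
                        les[seq_len(spec$n_lesions), , drop = FALSE])
  grid <- array(0L, spec$grid_shape)
  for (i in seq_len(nrow(lesions)))
    grid[rasterize_ellipsoid(unlist(lesions[i, c("cx", "cy", "cz")]),
                             unlist(lesions[i, c("rx", "ry", "rz")]),
                             spec$grid_shape, spec$spacing)] <- 1L
  structure(list(spec = spec, lesions = lesions,
                 mask = binary_mask(grid, spec$spacing,
                                    subject_id = "phantom",
                                    condition = "truth")),
            class = "cnt_phantom_truth")
}

#' Simulate one rater's delineation of a phantom truth
#'
#' Each true lesion is independently missed with probability `1 - p_det`.
#' Retained lesions get smooth boundary jitter of scale `jitter_mm`
#' (random center shift and radius perturbation). With probability
#' `p_split` a retained lesion is cut by removing a 1-voxel-thick plane
#' through its interior (along its longest axis); with probability
#' `p_merge` a 1-voxel bridge is drawn to the nearest retained lesion.
#' False-positive blobs arrive as a Poisson count and are placed clear of
#' true lesions.
#'
#' @param truth a [generate_truth()] result.
#' @param rater [rater_model()] parameters.
#' @param seed substream seed for this rater.
#' @param rater_name tag written into the mask's `source`.
#' @return list of class `cnt_rater_sim`: `mask` (a [binary_mask()]) and
#'   `events` (data.frame per true lesion: detected, split, merged_with)
#'   plus `n_false_positive`.
#' @export
simulate_rater <- function(truth, rater, seed, rater_name = "rater") {
  stopifnot(inherits(truth, "cnt_phantom_truth"),
            inherits(rater, "cnt_rater_model"))
  spec <- truth$spec
  set.seed(seed)
  n <- nrow(truth$lesions)
  grid <- array(0L, spec$grid_shape)
  detected <- if (n) stats::runif(n) < rater$p_det else logical(0)
  split_ev <- logical(n); merged_with <- rep(NA_integer_, n)
  centers <- as.matrix(truth$lesions[, c("cx", "cy", "cz"), drop = FALSE])
  vox_sets <- vector("list", n)
  for (i in seq_len(n)) {
    if (!detected[i]) next
    cen <- centers[i, ] + stats::rnorm(3, 0, rater$jitter_mm)
    rad <- unlist(truth$lesions[i, c("rx", "ry", "rz")]) +
      stats::rnorm(3, 0, rater$jitter_mm / 2)
    rad <- pmax(min(spec$spacing) * 0.8, rad)
    vox <- rasterize_ellipsoid(cen, rad, spec$grid_shape, spec$spacing)
    if (!length(vox)) { detected[i] <- FALSE; next }
    if (stats::runif(1) < rater$p_split && length(vox) >= 3) {
      co <- arrayInd(vox, spec$grid_shape)
      ax <- which.max(apply(co, 2, function(v) diff(range(v))))
      plane <- round(mean(range(co[, ax])))
      keep <- co[, ax] != plane
      if (any(co[, ax] < plane) && any(co[, ax] > plane)) {
        vox <- vox[keep]; split_ev[i] <- TRUE
      }
    }
    vox_sets[[i]] <- vox
  }
  ## merge bridges between detected lesions
  det_ids <- which(detected)
  if (length(det_ids) >= 2) for (i in det_ids) {
    if (stats::runif(1) < rater$p_merge) {
      others <- setdiff(det_ids, i)
      d <- sqrt(colSums((t(centers[others, , drop = FALSE]) - centers[i, ])^2))
      j <- others[which.min(d)]
      merged_with[i] <- j
      steps <- ceiling(min(d) / (min(spec$spacing) / 2)) + 1
      tseq <- seq(0, 1, length.out = max(2, steps))
      pts <- outer(tseq, centers[j, ] - centers[i, ]) +
        matrix(centers[i, ], length(tseq), 3, byrow = TRUE)
      idx <- floor(t(t(pts) / spec$spacing)) + 1
      for (cc in 1:3)
        idx[, cc] <- pmin(pmax(idx[, cc], 1L), spec$grid_shape[cc])
      lin <- unique((idx[, 3] - 1L) * prod(spec$grid_shape[1:2]) +
                      (idx[, 2] - 1L) * spec$grid_shape[1] + idx[, 1])
      vox_sets[[i]] <- union(vox_sets[[i]], lin)
    }
  }
  ## false positives, clear of true lesions
  n_fp <- stats::rpois(1, rater$fp_rate)
  n_fp_placed <- 0
  extent <- spec$grid_shape * spec$spacing
  gap_mm <- spec$min_gap * max(spec$spacing)
  fp_sets <- list()
  if (n_fp > 0) for (f in seq_len(n_fp)) {
    for (try in 1:200) {
      r0 <- stats::rlnorm(1, spec$radius_meanlog - 0.6, spec$radius_sdlog)
      rad <- pmax(min(spec$spacing) * 0.8, r0 * stats::runif(3, 0.8, 1.25))
      rmax <- max(rad)
      if (any(extent <= 2 * rmax)) next
      cen <- stats::runif(3, rmax, extent - rmax)
      ok <- !n || all(sqrt(colSums((t(centers) - cen)^2)) >=
          rmax + apply(truth$lesions[, c("rx", "ry", "rz"), drop = FALSE],
                       1, max) + gap_mm)
      if (ok) {
        fp_sets[[length(fp_sets) + 1L]] <-
          rasterize_ellipsoid(cen, rad, spec$grid_shape, spec$spacing)
        n_fp_placed <- n_fp_placed + 1
        break
      }
    }
  }
  for (v in c(vox_sets, fp_sets)) if (length(v)) grid[v] <- 1L
  events <- data.frame(lesion = seq_len(n), detected = detected,
                       split = split_ev, merged_with = merged_with)
  structure(list(
    mask = binary_mask(grid, spec$spacing, subject_id = "phantom",
                       source = rater_name),
    events = events, n_false_positive = n_fp_placed),
    class = "cnt_rater_sim")
}

#' Simulate a paired delineation of one phantom subject
#'
#' Generates (or reuses) a truth and draws both raters' masks from it via
#' named seed substreams, so the pair is coupled through a common truth.
#'
#' @param spec a [phantom_spec()].
#' @param truth optional pre-generated truth (for paired condition
#'   contrasts on a fixed truth).
#' @param seed master seed override (default `spec$seed`).
#' @return list `truth`, `rater1`, `rater2` (each a `cnt_rater_sim`).
#' @export
simulate_pair <- function(spec, truth = NULL, seed = NULL) {
  stopifnot(inherits(spec, "cnt_phantom_spec"))
  if (is.null(seed)) seed <- spec$seed
  if (is.null(truth)) truth <- generate_truth(spec,
                                              derive_seed(seed, "truth"))
  r1 <- simulate_rater(truth, spec$raters[[1]],
                       derive_seed(seed, "rater", 1), names(spec$raters)[1])
  r2 <- simulate_rater(truth, spec$raters[[2]],
                       derive_seed(seed, "rater", 2), names(spec$raters)[2])
  list(truth = truth, rater1 = r1, rater2 = r2)
}

#' Expected CNT class counts under the independent-event rater model
#'
#' Closed-form expectations over the phantom's event model, valid when
#' jitter is small enough that lesions detected by both raters overlap:
#' a true lesion yields a Disagreement component when detected by exactly
#' one rater (probability `p1(1-p2) + p2(1-p1)`); false-positive blobs
#' are Disagreement; lesions detected by both raters with no split/merge
#' event form one Agreement pair; a both-detected lesion with a single
#' split event yields three Checkered components (an approximate
#' accounting when split and merge events compound).
#'
#' @param spec a [phantom_spec()].
#' @return list `agreement_pairs`, `disagreement_components`,
#'   `checkered_components`.
#' @export
expected_class_counts <- function(spec) {
  stopifnot(inherits(spec, "cnt_phantom_spec"))
  r1 <- spec$raters[[1]]; r2 <- spec$raters[[2]]
  n <- spec$n_lesions
  p_one <- r1$p_det * (1 - r2$p_det) + r2$p_det * (1 - r1$p_det)
  p_both <- r1$p_det * r2$p_det
  p_clean <- (1 - r1$p_split) * (1 - r2$p_split) *
    (1 - r1$p_merge) * (1 - r2$p_merge)
  list(
    agreement_pairs = n * p_both * p_clean,
    disagreement_components = n * p_one + r1$fp_rate + r2$fp_rate,
    checkered_components = n * p_both * (1 - p_clean) * 3)
}

#' Paired low/high-noise rater conditions
#'
#' Two stock rater-pair settings mirroring a harmonized-like (low-noise)
#' and original-like (high-noise) delineation condition: the high-noise
#' pair misses more lesions, jitters boundaries more, splits/merges more
#' often and produces more false positives.
#'
#' @return named list of two `raters` lists usable in [phantom_spec()].
#' @export
phantom_conditions <- function() {
  list(
    low_noise = list(
      rater1 = rater_model(p_det = 0.97, jitter_mm = 0.4, p_split = 0.02,
                           p_merge = 0.01, fp_rate = 1),
      rater2 = rater_model(p_det = 0.97, jitter_mm = 0.4, p_split = 0.02,
                           p_merge = 0.01, fp_rate = 1)),
    high_noise = list(
      rater1 = rater_model(p_det = 0.85, jitter_mm = 1.2, p_split = 0.06,
                           p_merge = 0.03, fp_rate = 4),
      rater2 = rater_model(p_det = 0.85, jitter_mm = 1.2, p_split = 0.06,
                           p_merge = 0.03, fp_rate = 4)))
}

#' Simulate a paired-condition phantom cohort
#'
#' For each synthetic subject one truth is generated; each condition's
#' rater pair then delineates that same truth with condition-independent
#' rater seed substreams (common random numbers), so condition contrasts
#' are paired within subject — the paired study design of intra-rater
#' inter-scanner comparisons.
#'
#' @param spec a [phantom_spec()]; its `raters` slot is overridden per
#'   condition.
#' @param n_subjects number of synthetic subjects.
#' @param conditions named list of `raters` lists (default
#'   [phantom_conditions()]).
#' @param seed master seed (default `spec$seed`).
#' @return nested list: `result[[condition]][[subject]]` is a list
#'   `truth`, `rater1`, `rater2`.
#' @export
simulate_cohort <- function(spec, n_subjects = 10,
                            conditions = phantom_conditions(),
                            seed = NULL) {
  stopifnot(inherits(spec, "cnt_phantom_spec"))
  if (is.null(seed)) seed <- spec$seed
  truths <- lapply(seq_len(n_subjects), function(s)
    generate_truth(spec, derive_seed(seed, "truth", s)))
  out <- lapply(names(conditions), function(cn) {
    raters <- conditions[[cn]]
    lapply(seq_len(n_subjects), function(s) {
      r1 <- simulate_rater(truths[[s]], raters[[1]],
                           derive_seed(seed, "subject", s, "rater", 1),
                           names(raters)[1])
      r2 <- simulate_rater(truths[[s]], raters[[2]],
                           derive_seed(seed, "subject", s, "rater", 2),
                           names(raters)[2])
      r1$mask$subject_id <- r2$mask$subject_id <- paste0("phantom", s)
      r1$mask$condition <- r2$mask$condition <- cn
      list(truth = truths[[s]], rater1 = r1, rater2 = r2)
    })
  })
  names(out) <- names(conditions)
  out
}
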