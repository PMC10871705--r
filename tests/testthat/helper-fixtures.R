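# Fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (flood fill, exhaustive enumeration, brute-force
# counting) and share no code path with the implementation they check.

mk_mask <- function(dim, spacing = c(1, 1, 1), vox = NULL) {
  g <- array(0L, dim)
  if (!is.null(vox)) g[vox] <- 1L
  binary_mask(g, spacing = spacing)
}

rand_mask <- function(dim = c(10, 10, 6), p = 0.2) {
  binary_mask(array(as.integer(stats::runif(prod(dim)) < p), dim),
              spacing = c(1, 1, 1))
}

# ---- flood-fill component oracle (queue BFS over explicit neighbors) ----
bf_components <- function(grid, connectivity) {
  dm <- dim(grid)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ord <- rowSums(abs(offs))
  offs <- offs[ord > 0 & ord <= c("6" = 1, "18" = 2,
                                  "26" = 3)[as.character(connectivity)], ]
  lab <- array(0L, dm)
  nxt <- 0L
  for (lin in which(grid != 0)) {
    if (lab[lin] != 0L) next
    nxt <- nxt + 1L
    queue <- lin
    lab[lin] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      co <- arrayInd(v, dm)
      for (r in seq_len(nrow(offs))) {
        nb <- co + as.integer(offs[r, ])
        if (any(nb < 1) || any(nb > dm)) next
        if (grid[nb[1], nb[2], nb[3]] != 0 &&
            lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          queue <- c(queue,
                     (nb[3] - 1) * dm[1] * dm[2] + (nb[2] - 1) * dm[1] + nb[1])
        }
      }
    }
  }
  lab
}

# ---- exhaustive bipartite topology enumeration (<= nmax per side) ----
all_bipartite_graphs <- function(nmax = 3) {
  out <- list()
  for (i in 0:nmax) for (j in 0:nmax) {
    ne <- i * j
    for (code in 0:(2^ne - 1)) {
      if (ne == 0 && code > 0) next
      edges <- NULL
      if (ne > 0) {
        bits <- as.integer(intToBits(code))[seq_len(ne)]
        sel <- which(bits == 1L)
        if (length(sel))
          edges <- data.frame(g = (sel - 1) %/% j + 1,
                              h = (sel - 1) %% j + 1, weight = 1L)
      }
      out[[length(out) + 1L]] <-
        overlap_graph(i, j, edges, sizes_left = rep(2L, i),
                      sizes_right = rep(2L, j))
    }
  }
  out
}

# ---- exact p-value oracles by full enumeration ----
enum_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  Vall <- vapply(0:(2^n - 1), function(code) {
    signs <- as.integer(intToBits(code))[seq_len(n)] == 1L
    sum(r[signs])
  }, numeric(1))
  min(1, 2 * min(mean(Vall <= V), mean(Vall >= V)))
}

enum_mannwhitney_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  Uall <- apply(combs, 2, function(id) sum(r[id]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(Uall <= U), mean(Uall >= U)))
}

bf_u_statistic <- function(x, y) {
  # pairwise wins of x over y, ties counting half
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# two-group Hotelling T^2 (pooled covariance), closed form
hotelling_t2 <- function(Y, group) {
  g <- factor(group)
  Y1 <- Y[g == levels(g)[1], , drop = FALSE]
  Y2 <- Y[g == levels(g)[2], , drop = FALSE]
  n1 <- nrow(Y1); n2 <- nrow(Y2)
  S <- ((n1 - 1) * stats::cov(Y1) + (n2 - 1) * stats::cov(Y2)) / (n1 + n2 - 2)
  dbar <- colMeans(Y1) - colMeans(Y2)
  as.numeric(n1 * n2 / (n1 + n2) * t(dbar) %*% solve(S) %*% dbar)
}

# ---- the six canonical overlap panels as voxel mask pairs ----
# each on its own small grid; returns list(maskG, maskH, classes = expected
# Nascimento class per component (left then right), cnt = CNT class)
taxonomy_panels <- function() {
  panel <- function(gvox, hvox, classes, cnt, dim = c(9, 5, 3)) {
    list(maskG = mk_mask(dim, vox = gvox), maskH = mk_mask(dim, vox = hvox),
         classes = classes, cnt = cnt)
  }
  ix <- function(x, y, z = 2) cbind(x, y, z)
  list(
    CorrectDetection = panel(ix(2:4, 2), ix(3:5, 2),
                             list(left = "CorrectDetection",
                                  right = "CorrectDetection"),
                             "Agreement"),
    DetectionFailure = panel(ix(2:4, 2), NULL,
                             list(left = "DetectionFailure",
                                  right = character(0)),
                             "Disagreement"),
    FalseAlarm = panel(NULL, ix(2:4, 2),
                       list(left = character(0), right = "FalseAlarm"),
                       "Disagreement"),
    Split = panel(ix(2:8, 2), rbind(ix(2:3, 2), ix(6:7, 2)),
                  list(left = "Split", right = rep("Split", 2)),
                  "Checkered"),
    Merge = panel(rbind(ix(2:3, 2), ix(6:7, 2)), ix(2:8, 2),
                  list(left = rep("Merge", 2), right = "Merge"),
                  "Checkered"),
    SplitMerge = panel(rbind(ix(2:4, 2), ix(6:8, 2)),
                       rbind(ix(4:6, 2), ix(8, 2)),
                       # 2 left, 2 right, one connected subgraph (M-N)
                       list(left = rep("SplitMerge", 2),
                            right = rep("SplitMerge", 2)),
                       "Checkered")
  )
}
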