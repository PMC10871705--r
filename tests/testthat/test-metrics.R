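test_that("global SDI: identity, half overlap, undefined case", {
  m <- mk_mask(c(8, 8, 4), vox = as.matrix(expand.grid(2:5, 2:5, 2)))
  expect_equal(global_sdi(m, m), 1)
  # equal-size foregrounds overlapping on half their voxels -> 1/2
  a <- mk_mask(c(10, 4, 3), vox = cbind(1:4, 2, 2))
  b <- mk_mask(c(10, 4, 3), vox = cbind(3:6, 2, 2))
  expect_equal(global_sdi(a, b), 0.5)
  e <- mk_mask(c(8, 8, 4))
  expect_error(global_sdi(e, e), class = "cnt_undefined_sdi")
})

test_that("per-lesion records follow the class conventions", {
  # split picture: g of 14 voxels covered by two h's of 7 each
  g <- mk_mask(c(16, 5, 3), vox = cbind(2:15, 2, 2))
  h <- mk_mask(c(16, 5, 3), vox = rbind(cbind(2:8, 2, 2), cbind(10:16, 2, 2)))
  # h2 extends one voxel past g (x=16), so h covers 13 of g's 14 voxels
  cmp <- cnt_compare(g, h)
  rec <- cmp$records
  grec <- rec[rec$side == "G", ]
  expect_equal(grec$cnt_class, "Checkered")
  expect_equal(grec$lesion_sdi, 2 * 13 / (14 + 14))
  hrec <- rec[rec$side == "H", ]
  expect_equal(hrec$lesion_sdi, c(2 * 7 / (7 + 14), 2 * 6 / (7 + 14)))
  # exact cover case: g fully covered by two h's -> g's union SDI is 1
  h2 <- mk_mask(c(16, 5, 3), vox = rbind(cbind(2:8, 2, 2), cbind(10:15, 2, 2)))
  # drop the voxel at x=9 from g so the two h's cover g exactly
  g2 <- mk_mask(c(16, 5, 3), vox = cbind(c(2:8, 10:15), 2, 2))
  cmp2 <- cnt_compare(g2, h2)
  # g2 forms two components (gap at x=9): this is two Agreement pairs
  expect_equal(nrow(cmp2$cnt$pairs), 2L)
  expect_true(all(cmp2$records$lesion_sdi == 1))
})

test_that("perfect pair yields one Agreement record with SDI 1", {
  m <- mk_mask(c(6, 6, 3), vox = as.matrix(expand.grid(2:4, 2:4, 2)))
  cmp <- cnt_compare(m, m)
  expect_equal(nrow(cmp$records), 1L)
  expect_equal(cmp$records$cnt_class, "Agreement")
  expect_equal(cmp$records$lesion_sdi, 1)
  expect_equal(cmp$records$side, "G+H")
})

test_that("Disagreement records have SDI 0 and no partners; Checkered > 0", {
  set.seed(21)
  for (i in 1:20) {
    a <- rand_mask(c(9, 9, 5), p = 0.2); b <- rand_mask(c(9, 9, 5), p = 0.2)
    cmp <- cnt_compare(a, b)
    r <- cmp$records
    dis <- r[r$cnt_class == "Disagreement", ]
    expect_true(all(dis$lesion_sdi == 0))
    expect_true(all(dis$partner_ids == ""))
    chk <- r[r$cnt_class == "Checkered", ]
    expect_true(all(chk$lesion_sdi > 0))
    expect_true(all(r$volume_mm3 > 0))
  }
})

test_that("disagreement volume accounting", {
  m <- mk_mask(c(10, 10, 4), vox = as.matrix(expand.grid(2:4, 2:4, 2)),
               spacing = c(0.8, 0.8, 0.8))
  expect_equal(cnt_compare(m, m)$disagreement_volume$total_mm3, 0)
  # one extra 10-voxel blob in H only on a 0.8 mm grid -> 5.12 on side H
  h <- m; h$grid[7:8, 7:8, 2] <- 1L; h$grid[7:8, 7:8, 3] <- 1L
  h$grid[7:8, 7, 4] <- 1L   # 10-voxel blob, disjoint from the shared one
  dv <- cnt_compare(m, h)$disagreement_volume
  expect_equal(dv$G_mm3, 0)
  expect_equal(dv$H_mm3, 10 * 0.512)
  expect_equal(dv$total_mm3, 5.12)
  # no overlap at all: total equals the sum of both foreground volumes
  a <- mk_mask(c(10, 10, 4), vox = cbind(2:3, 2, 2), spacing = c(1, 1, 1))
  b <- mk_mask(c(10, 10, 4), vox = cbind(7:9, 7, 3), spacing = c(1, 1, 1))
  expect_equal(cnt_compare(a, b)$disagreement_volume$total_mm3, 5)
})

test_that("volume conservation across components and classes", {
  set.seed(31)
  for (i in 1:10) {
    a <- rand_mask(c(9, 9, 5), p = 0.25); b <- rand_mask(c(9, 9, 5), p = 0.25)
    cmp <- cnt_compare(a, b)
    # component sizes sum to foreground per side
    expect_equal(sum(cmp$components_G$sizes), sum(a$grid))
    expect_equal(sum(cmp$components_H$sizes), sum(b$grid))
    # per side: disagreement + agreement/checkered volumes = lesion load
    vox <- prod(a$spacing)
    for (side in c("G", "H")) {
      cls <- if (side == "G") cmp$cnt$left else cmp$cnt$right
      sizes <- if (side == "G") cmp$components_G$sizes else
        cmp$components_H$sizes
      dis <- if (side == "G") cmp$disagreement_volume$G_mm3 else
        cmp$disagreement_volume$H_mm3
      expect_equal(dis + sum(sizes[cls != "Disagreement"]) * vox,
                   sum(sizes) * vox)
    }
  }
})

test_that("false-positive blobs never help: monotone SDI and volume", {
  # a false-positive blob is a new component: it must sit clear (Chebyshev
  # distance > 1) of all existing foreground of both masks
  isolated_voxel <- function(a, b) {
    dm <- dim(a)
    occ <- a | b
    for (lin in sample(which(!occ))) {
      co <- arrayInd(lin, dm)
      xs <- max(1, co[1] - 1):min(dm[1], co[1] + 1)
      ys <- max(1, co[2] - 1):min(dm[2], co[2] + 1)
      zs <- max(1, co[3] - 1):min(dm[3], co[3] + 1)
      if (!any(occ[xs, ys, zs])) return(lin)
    }
    NA_integer_
  }
  set.seed(8)
  base <- rand_mask(c(12, 12, 6), p = 0.1)
  grown <- other <- rand_mask(c(12, 12, 6), p = 0.1)
  cmp0 <- cnt_compare(base, other)
  for (k in 1:5) {
    v <- isolated_voxel(base$grid, grown$grid)
    if (is.na(v)) break
    grown$grid[v] <- 1L
    cmp1 <- cnt_compare(base, grown)
    expect_lte(cmp1$global_sdi, cmp0$global_sdi + 1e-12)
    expect_gte(cmp1$disagreement_volume$total_mm3,
               cmp0$disagreement_volume$total_mm3 - 1e-12)
    cmp0 <- cmp1
  }
})

test_that("class summaries reproduce base descriptive statistics", {
  rec <- data.frame(cnt_class = rep("Agreement", 3),
                    lesion_sdi = c(0.2, 0.4, 0.6),
                    volume_mm3 = c(1, 2, 3))
  s <- summarize_class(rec, "Agreement", "lesion_sdi")
  expect_equal(s$median, 0.4); expect_equal(s$mean, 0.4)
  expect_equal(s$range, c(0.2, 0.6)); expect_equal(s$n, 3L)
  one <- summarize_class(rec[1, ], "Agreement", "volume_mm3")
  expect_equal(one$range, c(1, 1)); expect_equal(one$sd, 0)
  empty <- summarize_class(rec, "Checkered")
  expect_true(empty$empty); expect_equal(empty$n, 0L)
  set.seed(3)
  v <- rlnorm(50)
  rr <- data.frame(cnt_class = "Checkered", lesion_sdi = v, volume_mm3 = v)
  s2 <- summarize_class(rr, "Checkered", "volume_mm3")
  expect_equal(s2$mean, mean(v)); expect_equal(s2$sd, sd(v))
  expect_equal(s2$median, median(v))
})

test_that("class counts in the comparison partition all components", {
  set.seed(17)
  a <- rand_mask(c(10, 10, 5), p = 0.25); b <- rand_mask(c(10, 10, 5), p = 0.25)
  cmp <- cnt_compare(a, b)
  expect_equal(sum(cmp$class_counts["G", ]), cmp$components_G$count)
  expect_equal(sum(cmp$class_counts["H", ]), cmp$components_H$count)
})

test_that("class map codes every foreground voxel consistently", {
  p <- taxonomy_panels()$Split
  cmp <- cnt_compare(p$maskG, p$maskH)
  cm <- class_map(cmp)
  fg <- p$maskG$grid | p$maskH$grid
  expect_true(all(cm[fg] > 0))
  expect_true(all(cm[!fg] == 0))
  expect_true(all(cm[p$maskG$grid == 1] == 3))  # Split panel is Checkered
})
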