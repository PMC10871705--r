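small_spec <- function(...) {
  phantom_spec(grid_shape = c(40, 40, 40), spacing = c(1, 1, 1),
               n_lesions = 8, radius_meanlog = log(2.2),
               radius_sdlog = 0.3, seed = 5L, ...)
}

test_that("truth generation is deterministic and respects the gap", {
  sp <- small_spec()
  t1 <- generate_truth(sp); t2 <- generate_truth(sp)
  expect_identical(t1$mask$grid, t2$mask$grid)
  expect_identical(t1$lesions, t2$lesions)
  # lesions never touch: component count equals n_lesions
  cs <- extract_components(t1$mask)
  expect_equal(cs$count, sp$n_lesions)
  # centers honor the conservative separation bound
  cen <- as.matrix(t1$lesions[, c("cx", "cy", "cz")])
  rmax <- apply(t1$lesions[, c("rx", "ry", "rz")], 1, max)
  for (i in 1:(nrow(cen) - 1)) for (j in (i + 1):nrow(cen))
    expect_gte(sqrt(sum((cen[i, ] - cen[j, ])^2)),
               rmax[i] + rmax[j] + sp$min_gap * max(sp$spacing) - 1e-9)
})

test_that("zero lesions and impossible placements are handled", {
  sp0 <- phantom_spec(grid_shape = c(16, 16, 16), spacing = c(1, 1, 1),
                      n_lesions = 0)
  t0 <- generate_truth(sp0)
  expect_equal(nrow(t0$lesions), 0L)
  expect_true(all(t0$mask$grid == 0L))
  crowded <- phantom_spec(grid_shape = c(12, 12, 12), spacing = c(1, 1, 1),
                          n_lesions = 60, radius_meanlog = log(3))
  expect_error(generate_truth(crowded, retry_budget = 20),
               "reduce n_lesions")
})

test_that("sampled base radii follow the log-normal size law", {
  # pooled over sparse placements (little rejection bias); KS against the
  # sampling distribution, fixed seed
  sp <- phantom_spec(grid_shape = c(56, 56, 56), spacing = c(1, 1, 1),
                     n_lesions = 6, radius_meanlog = log(2),
                     radius_sdlog = 0.3)
  r0 <- unlist(lapply(1:60, function(s)
    generate_truth(sp, seed = 1000 + s)$lesions$r0))
  ks <- suppressWarnings(
    ks.test(r0, plnorm, meanlog = log(2), sdlog = 0.3))
  expect_gt(ks$p.value, 0.001)
})

test_that("a perfect rater reproduces the truth exactly", {
  sp <- small_spec()
  tr <- generate_truth(sp)
  sim <- simulate_rater(tr, rater_model(), seed = 1)
  expect_identical(sim$mask$grid, tr$mask$grid)
  expect_true(all(sim$events$detected))
  cmp <- cnt_compare(tr$mask, sim$mask)
  expect_equal(cmp$global_sdi, 1)
  expect_true(all(cmp$cnt$left == "Agreement"))
  expect_equal(cmp$disagreement_volume$total_mm3, 0)
})

test_that("a blind rater yields all-Disagreement from the other side", {
  sp <- small_spec()
  tr <- generate_truth(sp)
  sim <- simulate_rater(tr, rater_model(p_det = 0), seed = 2)
  expect_true(all(sim$mask$grid == 0L))
  cmp <- cnt_compare(tr$mask, sim$mask)
  expect_true(all(cmp$cnt$left == "Disagreement"))
  expect_equal(cmp$components_H$count, 0L)
})

test_that("split events cut a detected lesion into two pieces", {
  sp <- small_spec()
  tr <- generate_truth(sp)
  sim <- simulate_rater(tr, rater_model(p_split = 1), seed = 3)
  expect_true(any(sim$events$split))
  cs <- extract_components(sim$mask)
  expect_equal(cs$count, sp$n_lesions + sum(sim$events$split))
  # and the comparison sees them as Checkered
  cmp <- cnt_compare(tr$mask, sim$mask)
  expect_true(sum(cmp$cnt$right == "Checkered") >=
                2 * sum(sim$events$split))
})

test_that("merge events bridge to the nearest lesion", {
  sp <- small_spec()
  tr <- generate_truth(sp)
  sim <- simulate_rater(tr, rater_model(p_merge = 1), seed = 4)
  expect_true(any(!is.na(sim$events$merged_with)))
  # bridging can only reduce the component count
  expect_lt(extract_components(sim$mask)$count, sp$n_lesions)
})

test_that("false positives appear clear of true lesions", {
  sp <- small_spec()
  tr <- generate_truth(sp)
  sim <- simulate_rater(tr, rater_model(fp_rate = 3), seed = 6)
  if (sim$n_false_positive > 0) {
    cmp <- cnt_compare(tr$mask, sim$mask)
    expect_equal(sum(cmp$cnt$right == "Disagreement"),
                 sim$n_false_positive)
  }
  expect_true(sim$n_false_positive >= 0)
})

test_that("expected class counts follow the closed-form event accounting", {
  sp <- phantom_spec(n_lesions = 50,
                     raters = list(r1 = rater_model(p_det = 1),
                                   r2 = rater_model(p_det = 0.8)))
  ex <- expected_class_counts(sp)
  expect_equal(ex$disagreement_components, 50 * 0.2)
  expect_equal(ex$agreement_pairs, 40)
  expect_equal(ex$checkered_components, 0)
  # all agreement when both raters are perfect
  spp <- phantom_spec(n_lesions = 20)
  exp <- expected_class_counts(spp)
  expect_equal(exp$agreement_pairs, 20)
  expect_equal(exp$disagreement_components, 0)
  # one rater splitting 30% of detected lesions: 3 components per event
  sps <- phantom_spec(n_lesions = 50,
                      raters = list(r1 = rater_model(p_split = 0.3),
                                    r2 = rater_model()))
  exs <- expected_class_counts(sps)
  expect_equal(exs$checkered_components, 0.3 * 50 * 3)
  expect_equal(exs$agreement_pairs, 0.7 * 50)
})

test_that("paired simulation is reproducible and tags its outputs", {
  sp <- small_spec(raters = phantom_conditions()$high_noise)
  s1 <- simulate_pair(sp); s2 <- simulate_pair(sp)
  expect_identical(s1$rater1$mask$grid, s2$rater1$mask$grid)
  expect_identical(s1$rater2$mask$grid, s2$rater2$mask$grid)
  expect_false(identical(s1$rater1$mask$grid, s1$rater2$mask$grid))
  co <- simulate_cohort(small_spec(), n_subjects = 2)
  expect_named(co, c("low_noise", "high_noise"))
  expect_equal(co$low_noise[[2]]$rater1$mask$subject_id, "phantom2")
  # same truth underlies both conditions (paired design)
  expect_identical(co$low_noise[[1]]$truth$mask$grid,
                   co$high_noise[[1]]$truth$mask$grid)
})
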