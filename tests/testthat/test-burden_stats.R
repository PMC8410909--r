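test_that("expected counts, AD and PC reproduce the desk arithmetic", {
  ## synonymous-normalized expectation
  es <- expected_count(157, 499, 484)
  expect_equal(round(es, 2), 161.87)
  expect_equal(expected_count(0, 100, 50), 0)
  expect_error(expected_count(10, 5, 0), "positive")

  ## child-count normalization
  expect_equal(round(expected_count(86, 1869, 1874), 2), 85.77)

  expect_equal(round(ascertainment_differential(283, es, 1869), 2), 6.48)
  expect_equal(ascertainment_differential(100, 100, 50), 0)
  expect_equal(round(ascertainment_differential(
    116, expected_count(157, 309, 484), 1107), 2), 1.42)
  expect_error(ascertainment_differential(1, 1, 0), "positive")

  expect_equal(round(percent_contributory(283, es), 1), 42.8)
  expect_equal(percent_contributory(50, 50), 0)
  expect_equal(round(percent_contributory(26, 10.97), 1), 57.8)
  expect_warning(pc0 <- percent_contributory(0, 5), "S_a = 0")
  expect_true(is.na(pc0))
  ## PC can never exceed 100
  expect_lte(percent_contributory(7, 0.1), 100)
})

test_that("burden invariants: scale invariance and monotonicity", {
  inp <- simulate_burden_counts(100, 100, subject_rate = 1, norm_rate = 2,
                                seed = 2)
  pt <- dnburden:::burden_point(inp)
  scaled <- inp
  scaled$affected$norm <- scaled$affected$norm * 7L
  scaled$unaffected$norm <- scaled$unaffected$norm * 7L
  pt2 <- dnburden:::burden_point(scaled)
  expect_equal(pt2$AD, pt$AD)
  expect_equal(pt2$PC, pt$PC)

  ## increasing S_a strictly increases AD and PC
  more <- inp
  more$affected$subject[1] <- more$affected$subject[1] + 5L
  pt3 <- dnburden:::burden_point(more)
  expect_gt(pt3$AD, pt$AD)
  expect_gt(pt3$PC, pt$PC)
})

test_that("fitted-normal permutation p agrees with the exhaustive oracle", {
  for (s in c(3, 8, 15, 21, 30)) {
    inp <- simulate_burden_counts(4, 4, subject_rate = 3, norm_rate = 5,
                                  seed = s)
    tails <- exhaustive_permutation_tails(inp)
    p <- permutation_p(inp, n_perm = 2000, seed = s + 100)
    expect_gte(p, tails["lo"] - 0.1)
    expect_lte(p, tails["hi"] + 0.1)
  }
})

test_that("permutation p edge cases", {
  ## constant counts: zero spread across permutations
  flat <- burden_input(
    data.frame(child_id = sprintf("a%d", 1:10), subject = 1L, norm = 2L),
    data.frame(child_id = sprintf("u%d", 1:10), subject = 1L, norm = 2L))
  expect_warning(p <- permutation_p(flat, n_perm = 100, seed = 1), "constant")
  expect_equal(p, 1)

  ## observed AD at the permutation mean gives p near 0.5
  inp <- simulate_burden_counts(300, 300, subject_rate = 1, norm_rate = 2,
                                seed = 6)
  p <- permutation_p(inp, n_perm = 2000, seed = 7)
  expect_gt(p, 0.1); expect_lt(p, 0.9)

  ## a strongly planted excess is detected
  strong <- simulate_burden_counts(1000, 1000, planted_ad = 10, seed = 8)
  expect_lt(permutation_p(strong, n_perm = 1000, seed = 9), 1e-3)
})

test_that("bootstrap confidence intervals behave correctly", {
  ## degenerate cohort: zero-width interval at the point estimate
  flat <- burden_input(
    data.frame(child_id = sprintf("a%d", 1:10), subject = 2L, norm = 4L),
    data.frame(child_id = sprintf("u%d", 1:10), subject = 1L, norm = 4L))
  ci <- bootstrap_ci(flat, n_boot = 200, seed = 1)
  pt <- dnburden:::burden_point(flat)
  expect_equal(ci$AD_ci, c(pt$AD, pt$AD))
  expect_equal(ci$PC_ci, c(pt$PC, pt$PC))

  ## SSC-like planted cohort: CI width within a factor 2 of ~5 points
  inp <- simulate_burden_counts(1869, 1874, planted_ad = 6.5, seed = 3)
  ci <- bootstrap_ci(inp, n_boot = 600, seed = 4)
  width <- diff(ci$AD_ci)
  expect_gt(width, 2.5); expect_lt(width, 10)
})

test_that("affected-group comparison is symmetric and detects planted ratios", {
  u <- simulate_burden_counts(400, 400, seed = 11)$unaffected
  a1 <- simulate_burden_counts(400, 400, planted_ad = 8, seed = 12)$affected
  a2 <- simulate_burden_counts(400, 400, planted_ad = 8, seed = 13)$affected
  i1 <- burden_input(a1, u); i2 <- burden_input(a2, u)
  ## identically generated groups: p well inside (0, 1)
  p <- compare_affected_groups(i1, i2, n_perm = 1000, seed = 5)$p_value
  expect_gt(p, 0.05); expect_lt(p, 0.95)
  ## swapping the groups maps p to 1 - p up to Monte-Carlo error
  p_swap <- compare_affected_groups(i2, i1, n_perm = 1000, seed = 5)$p_value
  expect_lt(abs((1 - p_swap) - p), 0.1)

  ## planted 8% vs 0%: detected
  a3 <- simulate_burden_counts(400, 400, planted_ad = 0, seed = 14)$affected
  i3 <- burden_input(a3, u)
  expect_lt(compare_affected_groups(i1, i3, n_perm = 1000, seed = 6)$p_value,
            0.01)
})

test_that("aggregation with mixed normalization reproduces the joint AD", {
  ## single class: aggregation reduces to the plain result
  inp <- simulate_burden_counts(200, 200, subject_rate = 1, norm_rate = 2,
                                seed = 21)
  single <- aggregate_burden(list(A = inp), n_perm = 0, n_boot = 0)
  pt <- dnburden:::burden_point(inp)
  expect_equal(single$AD, pt$AD)
  expect_equal(single$ES_a, pt$ES_a)

  ## two classes over the same children, event-class + child-count modes
  set.seed(31)
  ids_a <- sprintf("a%d", 1:150); ids_u <- sprintf("u%d", 1:160)
  lgd <- burden_input(
    data.frame(child_id = ids_a, subject = rpois(150, 0.3),
               norm = rpois(150, 0.5)),
    data.frame(child_id = ids_u, subject = rpois(160, 0.2),
               norm = rpois(160, 0.5)))
  cnv <- burden_input(
    data.frame(child_id = ids_a, subject = rpois(150, 0.1)),
    data.frame(child_id = ids_u, subject = rpois(160, 0.05)),
    mode = "child_count")
  agg <- aggregate_burden(list(lgd = lgd, cnv = cnv), n_perm = 400,
                          n_boot = 400, seed = 5)
  p1 <- dnburden:::burden_point(lgd); p2 <- dnburden:::burden_point(cnv)
  expect_equal(agg$S_a, p1$S_a + p2$S_a)
  expect_equal(agg$ES_a, p1$ES_a + p2$ES_a)
  expect_equal(agg$AD, 100 * (agg$S_a - agg$ES_a) / 150)
  expect_true(agg$p_value >= 0 && agg$p_value <= 1)

  ## mismatched children are rejected
  bad <- burden_input(
    data.frame(child_id = paste0(ids_a, "x"), subject = 1L, norm = 1L),
    data.frame(child_id = ids_u, subject = 1L, norm = 1L))
  expect_error(aggregate_burden(list(lgd, bad)), "same children")
})

test_that("burden inputs can be built from annotated calls", {
  g <- toy_genome_fixture()
  spec <- cohort_spec(n_affected = 60, n_unaffected = 60,
                      planted_AD = c(LGD = 30), seed = 44)
  cohort <- simulate_children(spec)
  calls <- simulate_denovo_calls(cohort, g, spec)
  ann <- annotate_small_variants(calls$small, g)
  inp <- burden_input_from_calls(ann, cohort, "LGD", "SYN")
  expect_s3_class(inp, "burden_input")
  expect_equal(inp$C_a, 60)
  counts <- count_events_by_class(ann, cohort)
  expect_equal(sum(inp$affected$subject), sum(counts$LGD[cohort$affected]))
  expect_equal(sum(inp$unaffected$norm), sum(counts$SYN[!cohort$affected]))
  inp2 <- burden_input_from_calls(ann, cohort, "LGD")
  expect_true(all(inp2$affected$norm == 1))
})
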