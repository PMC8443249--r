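# Conditional overlap test, identification, concordance, chaining, and
# the naive-intersection baseline.

test_that("a fully shared signal block gives pi1|1 near 1 and the minimum
           attainable empirical p", {
  pair <- make_pair(m = 1000L, n_signal = 100L, shared = TRUE, seed = 3)
  # the fixed-lambda counting estimator makes the example exact: every
  # conditioning p-value is 1e-6, so pi1|1 = 1 and no random size-100
  # draw (~10 signal features) can tie with it
  res <- suppressWarnings(
    conditional_overlap_test(pair$exp1, pair$exp2, fdr_level = 0.1,
                             n_resamples = 199L, pi0_method = "fixed",
                             fixed_lambda = 0.5, seed = 3))
  expect_identical(res$n_conditioning, 100L)
  expect_setequal(res$conditioning_ids, pair$signal_ids)
  expect_gte(res$pi1_given_1, 0.95)
  # every conditioning p-value is extreme: cross-check against the
  # fixed-lambda counting formula on the conditioning subset
  p2 <- setNames(pair$exp2$p_value, pair$exp2$feature_id)
  oracle_pi1 <- 1 - sum(p2[pair$signal_ids] > 0.5) / (100 * 0.5)
  expect_gte(res$pi1_given_1, oracle_pi1 - 0.05)
  expect_equal(res$empirical_p, 1 / 200)
  expect_lt(res$normal_approx_p, 0.01)
  expect_identical(res$estimated_shared_count,
                   as.integer(round(res$pi1_given_1 * 100)))
  expect_length(res$null_pi1_samples, 199L)
  # pi1|0 on the complement carries no signal
  expect_lt(res$pi1_given_0, 0.15)

  # the default bootstrap estimator agrees on the overlap proportion
  res_boot <- suppressWarnings(
    conditional_overlap_test(pair$exp1, pair$exp2, fdr_level = 0.1,
                             n_resamples = 49L, seed = 3))
  expect_gte(res_boot$pi1_given_1, 0.95)
})

test_that("with no shared signal the test is null and its p-value formula
           uses the pseudocount convention", {
  pair <- make_pair(m = 1000L, n_signal = 100L, shared = FALSE, seed = 5)
  res <- suppressWarnings(
    conditional_overlap_test(pair$exp1, pair$exp2, n_resamples = 99L,
                             seed = 5))
  expect_equal(res$empirical_p,
               (1 + sum(res$null_pi1_samples >= res$pi1_given_1)) / 100)
  expect_lt(res$pi1_given_1, 0.35)
  expect_gt(res$empirical_p, 0.01)
})

test_that("estimated shared count is monotone in the conditioning-set
           signal strength", {
  pair <- make_pair(m = 1000L, n_signal = 100L, shared = TRUE, seed = 9,
                    signal_p = 0.2)
  counts <- vapply(c(1, 0.3, 0.01), function(scale) {
    exp2 <- pair$exp2
    idx <- match(pair$signal_ids, exp2$feature_id)
    exp2$p_value[idx] <- exp2$p_value[idx] * scale
    res <- suppressWarnings(
      conditional_overlap_test(pair$exp1, exp2, n_resamples = 49L,
                               pi0_method = "fixed", fixed_lambda = 0.5,
                               seed = 9))
    res$estimated_shared_count
  }, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("identification restricts the multiple-testing burden to the
           conditioning set", {
  # hand-checkable 4-feature conditioning set, fixed lambda = 0.5:
  # pi0 = #{p > 0.5}/(4 * 0.5) = 1; q = (0.004, 0.004, 0.95, 0.95)
  exp2 <- differential_table(c("a", "b", "c", "d", "e"),
                             c(0.001, 0.002, 0.9, 0.95, 0.5))
  shared <- suppressWarnings(
    identify_shared_features(c("a", "b", "c", "d"), exp2,
                             fdr_level = 0.1, pi0_method = "fixed",
                             fixed_lambda = 0.5))
  expect_equal(attr(shared, "pi0"), 1)
  expect_setequal(shared$feature_id, c("a", "b"))
  expect_equal(sort(shared$qvalue), c(0.004, 0.004))
  expect_true(all(shared$qvalue < 0.1))

  # no signal in the conditioning set: empty identification
  exp_null <- differential_table(letters[1:10], rep(0.99, 10))
  none <- suppressWarnings(
    identify_shared_features(letters[1:4], exp_null, fdr_level = 0.1,
                             pi0_method = "fixed", fixed_lambda = 0.5))
  expect_identical(nrow(none), 0L)

  # conditioning on the entire universe is no conditioning
  set.seed(21)
  ids <- sprintf("u%03d", 1:500)
  p <- c(rbeta(100, 0.1, 1), runif(400))
  tab <- differential_table(ids, p)
  via_identify <- identify_shared_features(ids, tab, fdr_level = 0.1,
                                           pi0_method = "fixed",
                                           fixed_lambda = 0.5)
  pi0_full <- estimate_pi0(p, method = "fixed", fixed_lambda = 0.5)
  via_qvalues <- compute_qvalues(p, pi0 = pi0_full, alpha = 0.1,
                                 feature_ids = ids)
  expect_setequal(via_identify$feature_id,
                  via_qvalues$feature_id[via_qvalues$significant])

  expect_error(
    suppressWarnings(identify_shared_features("a", exp2)), "at least 2")
  expect_warning(
    identify_shared_features(c("a", "b", "c"), exp2,
                             pi0_method = "fixed", fixed_lambda = 0.5),
    "200")
})

test_that("concordance filtering keeps same-sign effects and drops zero
           effects with a warning", {
  ids <- sprintf("p%02d", 1:10)
  lfc_a <- c(1.2, 1.2, 0.0, -2, -1, 0.5, 0.3, -0.2, 0.8, 1.5)
  lfc_b <- c(0.3, -0.3, 0.5, -1, -3, 0.1, 0.9, -0.1, 0.2, 0.4)
  # same nonzero sign: 1, 4, 5, 6, 7, 8, 9, 10; feature 2 is discordant
  # and feature 3 has a zero lfc
  exp_a <- differential_table(ids, runif(10), lfc = lfc_a)
  exp_b <- differential_table(ids, runif(10), lfc = lfc_b)
  shared <- suppressWarnings(
    identify_shared_features(ids, differential_table(ids, rep(1e-4, 10)),
                             pi0_method = "fixed", fixed_lambda = 0.5))
  expect_identical(nrow(shared), 10L)
  expect_warning(kept <- filter_concordant(shared, exp_a, exp_b),
                 "0")
  expect_identical(nrow(kept), 8L)
  expect_false("p02" %in% kept$feature_id)  # discordant
  expect_false("p03" %in% kept$feature_id)  # zero lfc
  expect_true(all(kept$direction_concordant))

  no_lfc <- differential_table(ids, runif(10))
  expect_error(filter_concordant(shared, no_lfc, exp_b), "lfc")
})

test_that("a two-table chain is exactly the composition of test, identify,
           and concordance filter", {
  pair <- make_pair(m = 800L, n_signal = 120L, shared = TRUE, seed = 31)
  chained <- suppressWarnings(
    chain_overlap(list(pair$exp1, pair$exp2), fdr_level = 0.1,
                  n_resamples = 49L, seed = 31))
  composed_test <- suppressWarnings(
    conditional_overlap_test(pair$exp1, pair$exp2, fdr_level = 0.1,
                             n_resamples = 49L, seed = 31))
  composed_shared <- suppressWarnings(
    identify_shared_features(composed_test$conditioning_ids, pair$exp2,
                             fdr_level = 0.1))
  composed_shared <- filter_concordant(composed_shared, pair$exp1,
                                       pair$exp2)
  st <- chained$stages[[1]]
  expect_identical(st$test$null_pi1_samples,
                   composed_test$null_pi1_samples)
  expect_identical(st$test$pi1_given_1, composed_test$pi1_given_1)
  expect_identical(st$test$empirical_p, composed_test$empirical_p)
  expect_identical(st$shared$feature_id, composed_shared$feature_id)
  expect_identical(st$shared$qvalue, composed_shared$qvalue)
  expect_identical(chained$status, "complete")
})

test_that("a three-table chain conditions each stage on the previous
           shared set and stops on an empty set", {
  cfg <- small_config(seed = 41)
  trio <- simulate_trio(cfg, rep_index = 0L)
  chained <- suppressWarnings(
    chain_overlap(trio$tables, fdr_level = 0.1, n_resamples = 29L,
                  seed = 41))
  expect_length(chained$stages, 2L)
  st1 <- chained$stages[[1]]; st2 <- chained$stages[[2]]
  expect_identical(st2$test$n_conditioning, nrow(st1$shared))
  expect_setequal(st2$test$conditioning_ids, st1$shared$feature_id)
  expect_true(all(st2$shared$feature_id %in% st1$shared$feature_id))

  # no signal anywhere downstream: the chain stops after stage 1
  pair <- make_pair(m = 500L, n_signal = 60L, shared = FALSE, seed = 43)
  t3 <- pair$exp2
  t3$feature_id <- pair$exp2$feature_id
  stopped <- suppressWarnings(
    chain_overlap(list(pair$exp1, pair$exp2, t3), fdr_level = 0.1,
                  n_resamples = 29L, seed = 43))
  expect_true(stopped$status == "stopped" ||
                nrow(stopped$stages[[length(stopped$stages)]]$shared) < 5L)
})

test_that("naive intersection thresholds each experiment separately and
           intersects the hit ids", {
  m <- 100L
  ids <- sprintf("n%03d", seq_len(m))
  set.seed(51)
  base_a <- runif(m, 0.5, 1); base_b <- runif(m, 0.5, 1)
  pa <- base_a; pa[1:3] <- 1e-8            # hits {1, 2, 3}
  pb <- base_b; pb[2:4] <- 1e-8            # hits {2, 3, 4}
  ta <- differential_table(ids, pa)
  tb <- differential_table(ids, pb)
  res <- suppressWarnings(
    naive_intersection(list(ta, tb), fdr_level = 0.1,
                       pi0_method = "fixed", fixed_lambda = 0.25))
  expect_identical(res$count, 2L)
  expect_setequal(res$ids, ids[2:3])

  # disjoint hit lists
  pb2 <- base_b; pb2[5:7] <- 1e-8
  res2 <- suppressWarnings(
    naive_intersection(list(ta, differential_table(ids, pb2)),
                       fdr_level = 0.1, pi0_method = "fixed",
                       fixed_lambda = 0.25))
  expect_identical(res2$count, 0L)
})

test_that("feature universes are harmonized by inner join with a warning,
           and an empty conditioning set is an error", {
  t1 <- differential_table(c("a", "b", "c", "d"), c(1e-8, 0.6, 0.7, 0.8))
  t2 <- differential_table(c("b", "c", "d", "e"), runif(4))
  expect_warning(
    tabs <- condoverlap:::.harmonize_tables(list(t1, t2)), "dropped")
  expect_setequal(tabs[[1]]$feature_id, c("b", "c", "d"))

  flat <- differential_table(sprintf("x%03d", 1:300),
                             runif(300, 0.5, 1))
  resp <- differential_table(sprintf("x%03d", 1:300), runif(300))
  expect_error(
    suppressWarnings(
      conditional_overlap_test(flat, resp, fdr_level = 0.1,
                               n_resamples = 9L,
                               pi0_method = "fixed", fixed_lambda = 0.5)),
    "0.1")
})
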