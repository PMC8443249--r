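# Sliding rank-threshold scans, effect collapsing, unique-top selection,
# and quartile cross-tabulation.

test_that("the default threshold grid yields one point per threshold", {
  set.seed(61)
  m <- 6000L
  ids <- sprintf("pk%04d", seq_len(m))
  genes <- sprintf("g%04d", seq_len(m))
  ranking <- differential_table(ids, runif(m))
  response <- differential_table(genes, runif(m))
  map <- feature_map(ids, genes)
  curve <- rank_conditional_proportion(ranking, response, map,
                                       pi0_method = "fixed",
                                       fixed_lambda = 0.5)
  expect_identical(nrow(curve), 17L)  # (5000 - 1000) / 250 + 1
  expect_identical(curve$threshold, seq(1000L, 5000L, by = 250L))
  # uniform response: proportions near 0 everywhere
  expect_true(all(curve$proportion < 0.15))
})

test_that("the full-universe threshold with an identity map reproduces the
           global pi1", {
  set.seed(63)
  m <- 800L
  ids <- sprintf("pk%03d", seq_len(m))
  ranking <- differential_table(ids, runif(m))
  response <- differential_table(ids, c(rbeta(200, 0.1, 1), runif(600)))
  map <- feature_map(ids, ids)
  curve <- rank_conditional_proportion(ranking, response, map,
                                       thresholds = c(400L, m),
                                       pi0_method = "fixed",
                                       fixed_lambda = 0.5)
  full <- estimate_pi0(response$p_value, method = "fixed",
                       fixed_lambda = 0.5)
  expect_identical(curve$proportion[2], full$pi1)
  expect_identical(curve$n_mapped[2], m)
})

test_that("signal concentrated in the top ranks dilutes as the threshold
           grows", {
  set.seed(65)
  m <- 5000L
  peaks <- sprintf("pk%04d", seq_len(m))
  genes <- sprintf("g%04d", seq_len(m))
  p_rank <- sort(runif(m))              # ranking order = index order
  p_resp <- runif(m)
  p_resp[1:1000] <- rbeta(1000, 0.1, 1) # mapped genes of the top 1000
  ranking <- differential_table(peaks, p_rank)
  response <- differential_table(genes, p_resp)
  map <- feature_map(peaks, genes)
  curve <- rank_conditional_proportion(ranking, response, map,
                                       thresholds = c(1000L, 3000L, 5000L),
                                       pi0_method = "fixed",
                                       fixed_lambda = 0.5)
  expect_gt(curve$proportion[1], 0.85)
  expect_true(all(diff(curve$proportion) < 0))
})

test_that("rank scan validates thresholds and map targets", {
  ids <- sprintf("a%02d", 1:50)
  tab <- differential_table(ids, runif(50))
  expect_error(
    rank_conditional_proportion(tab, tab, feature_map(ids, ids),
                                thresholds = c(10L, 60L)),
    "exceeds")
  bad_map <- feature_map(ids, paste0("missing_", ids))
  expect_error(
    rank_conditional_proportion(tab, tab, bad_map, thresholds = 10L),
    "absent")
})

test_that("effect collapsing takes per-target medians with the midpoint
           convention", {
  src <- differential_table(sprintf("pk%d", 1:6), runif(6),
                            lfc = c(0.2, 0.4, -1, 0, 2, 0.7))
  map <- feature_map(sprintf("pk%d", 1:6),
                     c("gA", "gA", "gB", "gB", "gB", "gC"))
  got <- collapse_effects(map, src)
  expect_equal(got$median_lfc[got$target_id == "gA"], 0.3)  # midpoint
  expect_equal(got$median_lfc[got$target_id == "gB"], 0)    # odd count
  expect_equal(got$median_lfc[got$target_id == "gC"], 0.7)  # identity

  # permutation invariance in the source rows
  perm <- c(4, 2, 6, 1, 3, 5)
  src_p <- differential_table(src$feature_id[perm], src$p_value[perm],
                              lfc = src$lfc[perm])
  expect_equal(collapse_effects(map, src_p), got)

  # idempotence on already-collapsed input
  collapsed_tab <- differential_table(got$target_id,
                                      runif(nrow(got)),
                                      lfc = got$median_lfc)
  idem <- collapse_effects(feature_map(got$target_id, got$target_id),
                           collapsed_tab)
  expect_equal(idem$median_lfc, got$median_lfc)

  expect_error(collapse_effects(map, differential_table("pk1", 0.5)),
               "lfc")
})

test_that("unique-top selection excludes shared and other-experiment top
           features", {
  ids <- sprintf("f%02d", 1:10)
  # focal ranking = id order; other experiment ranks 1..5 = focal 6..10
  focal <- differential_table(ids, seq(0.01, 0.1, by = 0.01))
  other <- differential_table(ids, c(seq(0.6, 1, length.out = 5),
                                     seq(0.01, 0.05, by = 0.01)))
  exps <- list(A = focal, B = other)
  # top 5 of A = f01..f05; top 5 of B = f06..f10, no exclusion overlap
  got <- select_unique_top(exps, "A", top_k = 5L, exclusion_k = 5L)
  expect_identical(got, ids[1:5])
  # widening the exclusion window can only shrink the answer
  got8 <- select_unique_top(exps, "A", top_k = 5L, exclusion_k = 8L)
  expect_true(all(got8 %in% got))
  expect_identical(got8, ids[4:5])  # B's top 8 adds f01..f03
  # shared ids removed regardless of rank
  got_sh <- select_unique_top(exps, "A", top_k = 5L, exclusion_k = 5L,
                              shared_ids = c("f02", "f04"))
  expect_identical(got_sh, c("f01", "f03", "f05"))
  # identical rankings exclude everything
  expect_length(select_unique_top(list(A = focal, B = focal), "A",
                                  top_k = 5L, exclusion_k = 5L), 0L)
  expect_error(select_unique_top(exps, "C"), "not found")
  expect_error(select_unique_top(exps, "A", top_k = 6L,
                                 exclusion_k = 5L), "exceed")
})

test_that("quartile cross-tabulation matches hand computation and the
           exchangeable baseline", {
  genes <- sprintf("g%d", 1:8)
  pb <- seq(0.1, 0.8, by = 0.1)
  pa <- c(0.15, 0.9, 0.2, 0.8, 0.7, 0.6, 0.5, 0.4)
  ra <- differential_table(genes, pa)
  rb <- differential_table(genes, pb)
  got <- quartile_cross_table(ra, rb, genes)
  # hand computation: quartile bins by pb = {g1,g2} {g3,g4} {g5,g6}
  # {g7,g8}; top 25% by pa = {g1, g3}
  expect_equal(got$n, rep(2L, 4))
  expect_equal(got$fraction_top_a, c(0.5, 0.5, 0, 0))

  # identical rankings: all top-quarter mass in the first bin
  same <- quartile_cross_table(rb, rb, genes)
  expect_equal(same$fraction_top_a, c(1, 0, 0, 0))

  # independent rankings: each bin near 1/4
  set.seed(71)
  m <- 4000L
  ids <- sprintf("r%04d", seq_len(m))
  ind <- quartile_cross_table(differential_table(ids, runif(m)),
                              differential_table(ids, runif(m)),
                              sample(ids, 800))
  expect_true(all(abs(ind$fraction_top_a - 0.25) < 0.1))

  expect_error(quartile_cross_table(ra, rb, genes[1:4]), "at least 8")
})
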