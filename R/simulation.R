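# Ground-truth simulation study: three experiments with a known sharing
# structure, per-feature Welch two-sample tests, and evaluation of the
# conditional overlap method against the naive intersection.

#' Simulation configuration
#'
#' Settings of the ground-truth simulation: three experiments, each
#' testing `m` features between two groups of `n_per_group` samples.
#' `n_diff` features per experiment are truly differential; `n_shared_12`
#' of them are shared between experiments 1 and 2, and `n_shared_123`
#' across all three. Null features are N(0, variance) in both groups;
#' differential features get a mean shift of `effect` in group 2. The
#' defaults are the study conditions: 10,000 features, 2,000 differential,
#' 1,400 shared between the first two experiments, 1,000 shared across all
#' three, effect 0.5, unit variance, 75 samples per group, 10% FDR.
#'
#' @param m Features per experiment.
#' @param n_diff Truly differential features per experiment.
#' @param n_shared_12 Shared truly differential features between
#'   experiments 1 and 2.
#' @param n_shared_123 Shared truly differential features across all three.
#' @param effect Mean shift of differential features (standardised units).
#' @param variance Observation variance (both groups, all features).
#' @param n_per_group Samples per group.
#' @param fdr_level FDR level used throughout the study.
#' @param n_reps Number of simulation repetitions.
#' @param seed Base integer seed; every repetition derives its own stream.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(m = 10000L, n_diff = 2000L, n_shared_12 = 1400L,
                       n_shared_123 = 1000L, effect = 0.5, variance = 1,
                       n_per_group = 75L, fdr_level = 0.1, n_reps = 1000L,
                       seed = 1L) {
  cfg <- list(m = as.integer(m), n_diff = as.integer(n_diff),
              n_shared_12 = as.integer(n_shared_12),
              n_shared_123 = as.integer(n_shared_123),
              effect = effect, variance = variance,
              n_per_group = as.integer(n_per_group),
              fdr_level = fdr_level, n_reps = as.integer(n_reps),
              seed = as.integer(seed))
  with(cfg, {
    if (any(c(m, n_diff, n_shared_12, n_shared_123, n_per_group,
              n_reps) <= 0L)) {
      stop("all counts must be positive", call. = FALSE)
    }
    if (n_shared_123 > n_shared_12) {
      stop("infeasible: n_shared_123 > n_shared_12", call. = FALSE)
    }
    if (n_shared_12 > n_diff) {
      stop("infeasible: n_shared_12 > n_diff", call. = FALSE)
    }
    if (n_diff > m) stop("infeasible: n_diff > m", call. = FALSE)
    needed <- n_shared_12 + 2L * (n_diff - n_shared_12) +
      (n_diff - n_shared_123)
    if (needed > m) {
      stop("infeasible: disjoint differential blocks need ", needed,
           " features but m = ", m, call. = FALSE)
    }
    if (variance <= 0) stop("variance must be positive", call. = FALSE)
    if (fdr_level <= 0 || fdr_level >= 1) {
      stop("fdr_level must lie in (0, 1)", call. = FALSE)
    }
    if (n_per_group < 2L) stop("n_per_group must be >= 2", call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  m = %d features, %d differential per experiment\n",
              x$m, x$n_diff))
  cat(sprintf("  shared 1&2 = %d, shared 1&2&3 = %d\n",
              x$n_shared_12, x$n_shared_123))
  cat(sprintf("  effect = %g, variance = %g, n/group = %d, FDR = %g\n",
              x$effect, x$variance, x$n_per_group, x$fdr_level))
  cat(sprintf("  n_reps = %d, seed = %d\n", x$n_reps, x$seed))
  invisible(x)
}

#' Assign ground-truth differential status
#'
#' Lays out the truth labels as disjoint feature blocks: features
#' `1..n_shared_123` are differential in all three experiments; the next
#' `n_shared_12 - n_shared_123` in experiments 1 and 2 only; each
#' experiment's remaining differential slots are filled from further
#' disjoint blocks so every column sums to `n_diff`. Pairwise overlaps
#' beyond the three-way block (1&3, 2&3) are zero by construction. The
#' layout is deterministic.
#'
#' @param config A [sim_config()].
#' @return An `m x 3` logical matrix of class `"truth_labels"`; row i,
#'   column e is `TRUE` when feature i is truly differential in
#'   experiment e.
#' @export
assign_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$m
  truth <- matrix(FALSE, nrow = m, ncol = 3L,
                  dimnames = list(NULL, paste0("exp", 1:3)))
  s123 <- config$n_shared_123
  s12 <- config$n_shared_12
  nd <- config$n_diff
  truth[seq_len(s123), ] <- TRUE
  if (s12 > s123) truth[(s123 + 1L):s12, 1:2] <- TRUE
  extra <- nd - s12                       # experiment 1 / 2 private blocks
  at <- s12
  if (extra > 0L) {
    truth[(at + 1L):(at + extra), 1L] <- TRUE; at <- at + extra
    truth[(at + 1L):(at + extra), 2L] <- TRUE; at <- at + extra
  }
  extra3 <- nd - s123                     # experiment 3 private block
  if (extra3 > 0L) truth[(at + 1L):(at + extra3), 3L] <- TRUE
  class(truth) <- c("truth_labels", class(truth))
  truth
}

# Per-(seed, repetition, experiment) RNG stream, kept below 2^31.
.derive_seed <- function(seed, rep_index, stream) {
  as.integer((as.numeric(seed) * 48271 + rep_index * 16807 + stream * 69621) %%
               2147483647)
}

# Vectorised Welch two-sample t-test over the rows of a matrix.
.row_welch <- function(x, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  xa <- x[, idx_a, drop = FALSE]; xb <- x[, idx_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  stat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p, mean_diff = mb - ma)
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t-test with Welch-Satterthwaite degrees of
#' freedom: \eqn{t = (\bar y_b - \bar y_a) / \sqrt{s_a^2/n_a + s_b^2/n_b}},
#' two-sided p-value from the t distribution. This is the per-feature test
#' of the simulation study.
#'
#' @param group_a,group_b Numeric vectors of at least 2 observations each.
#' @return A list with `statistic`, `df`, and `p_value`.
#' @examples
#' welch_t_pvalue(c(1, 2, 3), c(2, 3, 4))
#' @export
welch_t_pvalue <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    stop("zero variance in both groups", call. = FALSE)
  }
  x <- rbind(c(group_a, group_b))
  w <- .row_welch(x, seq_along(group_a),
                  length(group_a) + seq_along(group_b))
  list(statistic = unname(w$statistic), df = unname(w$df),
       p_value = unname(w$p_value))
}

#' Simulate one repetition of the three-experiment study
#'
#' Draws the observation matrices for the three experiments (null
#' features N(0, variance) in both groups; differential features shifted
#' by `effect` in group 2), applies the per-feature Welch t-test, and
#' returns the three result tables. The per-feature effect column (`lfc`)
#' is the difference of group means. RNG streams are split per
#' (seed, repetition, experiment), so reducing the number of repetitions
#' leaves earlier ones unchanged.
#'
#' @param config A [sim_config()].
#' @param rep_index Repetition index, 0-based.
#' @return A list with `tables` (three [differential_table()]s named
#'   `exp1..exp3`) and `truth` (the [assign_truth()] matrix).
#' @export
simulate_trio <- function(config, rep_index = 0L) {
  stopifnot(inherits(config, "sim_config"), rep_index >= 0L)
  truth <- assign_truth(config)
  m <- config$m; g <- config$n_per_group
  sdv <- sqrt(config$variance)
  ids <- sprintf("feature_%0*d", nchar(m), seq_len(m))
  idx_a <- seq_len(g); idx_b <- g + seq_len(g)
  tables <- lapply(1:3, function(e) {
    set.seed(.derive_seed(config$seed, rep_index, e))
    x <- matrix(stats::rnorm(m * 2L * g, mean = 0, sd = sdv),
                nrow = m, ncol = 2L * g)
    x[truth[, e], idx_b] <- x[truth[, e], idx_b] + config$effect
    w <- .row_welch(x, idx_a, idx_b)
    differential_table(ids, w$p_value, lfc = w$mean_diff, stat = w$statistic)
  })
  names(tables) <- paste0("exp", 1:3)
  list(tables = tables, truth = truth)
}

#' Run the ground-truth simulation study
#'
#' Repeats the three-experiment simulation, applying per repetition (a)
#' the conditional overlap chain — experiment-1 calls at `fdr_level`,
#' conditional estimation and identification against experiment 2, then
#' against experiment 3 — and (b) the naive intersection of independently
#' thresholded hit lists. The false-discovery proportion (FDP) of the
#' final identified set is measured against the truth labels: the
#' fraction of identified features not truly differential in all three
#' experiments (0 when the identified set is empty). The summary reports
#' means over repetitions.
#'
#' The chain is run without direction-concordance filtering: what is
#' being validated here is the conditional estimation and identification
#' procedure itself, and in this design every true effect shifts the same
#' group, so a concordance filter would act only as an extra filter on
#' false discoveries rather than as part of the method under evaluation.
#' The resampling null of the overlap test is not part of the summary
#' metrics, so a small `n_resamples` suffices.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of repetitions; defaults to `config$n_reps`.
#' @param n_resamples Null resamples per overlap test (not summarised).
#' @param pi0_method pi0 selection rule. Default `"bootstrap"`.
#' @param n_boot Bootstrap resamples per pi0 estimate.
#' @return An object of class `"simulation_summary"`: mean estimated
#'   overlaps and naive intersection counts for 1&2 and 1&2&3, the mean
#'   three-way FDP, per-repetition metrics (`per_rep`), and the number of
#'   repetitions run and excluded.
#' @export
run_simulation_study <- function(config, n_reps = config$n_reps,
                                 n_resamples = 20L,
                                 pi0_method = "bootstrap",
                                 n_boot = 100L) {
  stopifnot(inherits(config, "sim_config"))
  truth <- assign_truth(config)
  all3 <- truth[, 1L] & truth[, 2L] & truth[, 3L]
  m <- config$m
  ids <- sprintf("feature_%0*d", nchar(m), seq_len(m))
  names(all3) <- ids
  per_rep <- vector("list", n_reps)
  excluded <- 0L
  for (r in seq_len(n_reps)) {
    trio <- simulate_trio(config, rep_index = r - 1L)
    set.seed(.derive_seed(config$seed, r - 1L, 99L))
    chain <- tryCatch(
      suppressWarnings(
        chain_overlap(trio$tables, fdr_level = config$fdr_level,
                      n_resamples = n_resamples, pi0_method = pi0_method,
                      n_boot = n_boot,
                      seed = .derive_seed(config$seed, r - 1L, 7L),
                      concordant = FALSE)),
      error = function(e) NULL)
    if (is.null(chain) || length(chain$stages) < 2L) {
      excluded <- excluded + 1L
      per_rep[[r]] <- NULL
      next
    }
    st1 <- chain$stages[[1L]]; st2 <- chain$stages[[2L]]
    identified3 <- st2$shared$feature_id
    fdp <- if (length(identified3)) mean(!all3[identified3]) else 0
    # naive baseline: per-table significance once, then set intersections
    sig_sets <- lapply(trio$tables, function(t) {
      pi1 <- .pi1_subset(t$p_value, pi0_method,
                         seq(0.05, 0.95, by = 0.05), NULL, n_boot)
      qt <- compute_qvalues(t$p_value, pi0 = 1 - pi1,
                            alpha = config$fdr_level,
                            feature_ids = t$feature_id)
      qt$feature_id[qt$significant]
    })
    naive <- list(count = length(intersect(sig_sets[[1L]], sig_sets[[2L]])))
    naive3 <- list(count = length(Reduce(intersect, sig_sets)))
    per_rep[[r]] <- data.frame(
      rep = r,
      n_conditioning = st1$test$n_conditioning,
      estimated_overlap_12 = st1$test$estimated_shared_count,
      identified_12 = attr(st2$shared, "n_conditioning"),
      estimated_overlap_123 = st2$test$estimated_shared_count,
      identified_123 = length(identified3),
      naive_12 = naive$count,
      naive_123 = naive3$count,
      fdp_123 = fdp)
  }
  per_rep <- do.call(rbind, per_rep)
  if (is.null(per_rep) || nrow(per_rep) == 0L) {
    stop("no repetition produced a usable conditioning set", call. = FALSE)
  }
  structure(
    list(mean_estimated_overlap_12 = mean(per_rep$estimated_overlap_12),
         mean_estimated_overlap_123 = mean(per_rep$estimated_overlap_123),
         mean_naive_intersection_12 = mean(per_rep$naive_12),
         mean_naive_intersection_123 = mean(per_rep$naive_123),
         mean_fdp_shared_123 = mean(per_rep$fdp_123),
         n_reps_run = nrow(per_rep),
         n_excluded = excluded,
         per_rep = per_rep,
         config = config),
    class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat("Simulation study summary (", x$n_reps_run, " repetitions",
      if (x$n_excluded) paste0(", ", x$n_excluded, " excluded") else "",
      ")\n", sep = "")
  cat(sprintf("  true overlap 1&2 = %d, 1&2&3 = %d\n",
              x$config$n_shared_12, x$config$n_shared_123))
  cat(sprintf("  mean estimated overlap:  1&2 = %.1f, 1&2&3 = %.1f\n",
              x$mean_estimated_overlap_12, x$mean_estimated_overlap_123))
  cat(sprintf("  mean naive intersection: 1&2 = %.1f, 1&2&3 = %.1f\n",
              x$mean_naive_intersection_12, x$mean_naive_intersection_123))
  cat(sprintf("  mean FDP of identified three-way set: %.1f%% (nominal %g%%)\n",
              100 * x$mean_fdp_shared_123, 100 * x$config$fdr_level))
  invisible(x)
}
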