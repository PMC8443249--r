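# The conditional overlap framework: test whether significance in one
# experiment is informative about a second, estimate the overlap size,
# identify the shared features, filter for direction concordance, and
# chain across three or more experiments.

# pi1 on a p-value subset, falling back to the fixed-lambda (0.5)
# counting estimator if the requested method fails (e.g. degenerate
# resample). Consumes the current RNG stream; no validation or warnings.
.pi1_subset <- function(p, method, lambda, fixed_lambda, n_boot,
                        fallback_note = NULL) {
  core <- tryCatch(
    .pi0_core(p, method, lambda, fixed_lambda, n_boot),
    error = function(e) NULL)
  if (is.null(core)) {
    if (!is.null(fallback_note)) {
      message("pi0 estimation failed (", fallback_note,
              "); falling back to fixed lambda = 0.5")
    }
    core <- .pi0_core(p, "fixed", lambda, 0.5, n_boot)
  }
  1 - core$pi0
}

# Conditional overlap test against an explicit conditioning id set.
# Assumes the RNG has been seeded by the caller.
.overlap_test_on_ids <- function(group1, exp2, n_resamples, pi0_method,
                                 lambda, fixed_lambda, n_boot) {
  p2 <- exp2$p_value
  names(p2) <- exp2$feature_id
  n <- length(group1)
  m <- length(p2)
  pi1_11 <- .pi1_subset(p2[group1], pi0_method, lambda, fixed_lambda,
                        n_boot, fallback_note = "conditioning set")
  complement <- setdiff(exp2$feature_id, group1)
  pi1_10 <- if (length(complement) >= 1L) {
    .pi1_subset(p2[complement], pi0_method, lambda, fixed_lambda, n_boot,
                fallback_note = "complement set")
  } else NA_real_
  null_samples <- vapply(seq_len(n_resamples), function(b) {
    .pi1_subset(p2[sample.int(m, n)], pi0_method, lambda, fixed_lambda,
                n_boot)
  }, numeric(1L))
  empirical_p <- (1 + sum(null_samples >= pi1_11)) / (n_resamples + 1)
  mu <- mean(null_samples)
  sdv <- stats::sd(null_samples)
  normal_approx_p <- if (is.na(sdv) || sdv == 0) {
    as.numeric(pi1_11 <= mu)
  } else {
    stats::pnorm(pi1_11, mean = mu, sd = sdv, lower.tail = FALSE)
  }
  structure(
    list(n_conditioning = n,
         pi1_given_1 = pi1_11,
         pi1_given_0 = pi1_10,
         null_pi1_samples = null_samples,
         empirical_p = empirical_p,
         normal_approx_p = normal_approx_p,
         estimated_shared_count = as.integer(round(pi1_11 * n)),
         n_resamples = n_resamples,
         pi0_method = pi0_method,
         conditioning_ids = group1),
    class = "conditional_overlap")
}

#' Test for conditional overlap between two differential experiments
#'
#' Tests whether the features called significant in experiment 1 are
#' enriched for truly differential features in experiment 2, without
#' thresholding experiment 2. Writing \eqn{\pi_{1|1}} for the proportion of
#' truly differential experiment-2 features among the experiment-1 hits and
#' \eqn{\pi_{1|0}} for the same proportion among the non-hits, the null
#' hypothesis is \eqn{H_0 : \pi_{1|0} = \pi_{1|1}} (experiment 1 carries no
#' information about experiment 2). The procedure: (1) call experiment-1
#' features at `fdr_level` via q-values; let group 1 be the hits, of size
#' n. (2) Estimate \eqn{\hat\pi_{1|1} = 1 - \hat\pi_0} on the experiment-2
#' p-values restricted to group 1. (3) Build the null distribution of
#' \eqn{\hat\pi_1(n)}, the same estimate on random size-n feature draws
#' from experiment 2 (without replacement, `n_resamples` independent
#' draws), and report the empirical upper-tail p-value with a pseudocount,
#' `(1 + exceedances) / (n_resamples + 1)`, alongside a Gaussian tail
#' approximation based on the null sample moments (useful when the
#' resampling resolution of `1/(n_resamples + 1)` is too coarse).
#'
#' The estimated number of shared differential features is
#' \eqn{\mathrm{round}(\hat\pi_{1|1} \cdot n)}; unlike the naive
#' intersection of two thresholded hit lists it does not require each
#' shared feature to clear a significance threshold in both experiments.
#'
#' @param exp1,exp2 [differential_table()] objects. They are restricted to
#'   their common feature universe (a warning reports features dropped).
#' @param fdr_level FDR level for calling experiment-1 features. Default 0.1.
#' @param n_resamples Number of null draws B. Default 1000.
#' @param pi0_method pi0 selection rule passed to the estimator
#'   (`"bootstrap"`, `"smoother"`, or `"fixed"`).
#' @param fixed_lambda Lambda for `pi0_method = "fixed"`.
#' @param lambda Lambda grid for bootstrap/smoother selection.
#' @param n_boot Bootstrap resamples inside each pi0 estimation.
#' @param seed Integer seed; the whole procedure is reproducible for a
#'   fixed seed.
#' @return An object of class `"conditional_overlap"` with elements
#'   `n_conditioning`, `pi1_given_1`, `pi1_given_0` (diagnostic, from the
#'   complement set), `null_pi1_samples`, `empirical_p`,
#'   `normal_approx_p`, `estimated_shared_count`, and `conditioning_ids`.
#' @seealso [identify_shared_features()], [chain_overlap()],
#'   [naive_intersection()]
#' @export
conditional_overlap_test <- function(exp1, exp2, fdr_level = 0.1,
                                     n_resamples = 1000L,
                                     pi0_method = c("bootstrap", "smoother",
                                                    "fixed"),
                                     fixed_lambda = NULL,
                                     lambda = seq(0.05, 0.95, by = 0.05),
                                     n_boot = 100L,
                                     seed = 1L) {
  pi0_method <- match.arg(pi0_method)
  if (n_resamples < 1L) stop("n_resamples must be >= 1", call. = FALSE)
  tabs <- .harmonize_tables(list(exp1, exp2))
  exp1 <- tabs[[1L]]; exp2 <- tabs[[2L]]
  set.seed(seed)
  pi1_1 <- .pi1_subset(exp1$p_value, pi0_method, lambda, fixed_lambda,
                       n_boot, fallback_note = "experiment 1")
  q1 <- compute_qvalues(exp1$p_value, pi0 = 1 - pi1_1, alpha = fdr_level,
                        feature_ids = exp1$feature_id)
  group1 <- q1$feature_id[q1$significant]
  if (length(group1) == 0L) {
    stop("no features significant in experiment 1 at FDR level ",
         fdr_level, call. = FALSE)
  }
  out <- .overlap_test_on_ids(group1, exp2, n_resamples, pi0_method,
                              lambda, fixed_lambda, n_boot)
  out$fdr_level <- fdr_level
  out$seed <- seed
  out
}

#' @export
print.conditional_overlap <- function(x, ...) {
  cat("Conditional overlap test\n")
  cat(sprintf("  conditioning set: n = %d features\n", x$n_conditioning))
  cat(sprintf("  pi1|1 = %.3f  (pi1|0 = %.3f, diagnostic)\n",
              x$pi1_given_1, x$pi1_given_0))
  cat(sprintf("  estimated shared differential features: %d\n",
              x$estimated_shared_count))
  cat(sprintf("  empirical p = %.4g (B = %d resamples), normal approx p = %.4g\n",
              x$empirical_p, x$n_resamples, x$normal_approx_p))
  invisible(x)
}

#' @export
summary.conditional_overlap <- function(object, ...) {
  cat("Conditional overlap test (pi0 method:", object$pi0_method, ")\n\n")
  print(object)
  cat(sprintf("\n  null pi1(n): mean = %.4f, sd = %.4f, max = %.4f\n",
              mean(object$null_pi1_samples),
              stats::sd(object$null_pi1_samples),
              max(object$null_pi1_samples)))
  invisible(object)
}

#' @export
plot.conditional_overlap <- function(x, ...) {
  graphics::hist(x$null_pi1_samples,
                 main = "Resampling null of pi1(n)",
                 xlab = expression(hat(pi)[1](n)),
                 xlim = range(c(x$null_pi1_samples, x$pi1_given_1)), ...)
  graphics::abline(v = x$pi1_given_1, col = "red", lwd = 2)
  invisible(x)
}

#' Identify the shared differential features
#'
#' Computes q-values on experiment 2's p-values restricted to the
#' conditioning set (the features called significant in experiment 1) and
#' returns those below `fdr_level`. Restricting the multiple-testing
#' burden to the conditioning set decouples overlap identification from
#' overlap estimation: only the identification of specific features pays
#' the multiplicity cost.
#'
#' @param conditioning_ids Character vector of feature ids (typically the
#'   experiment-1 significant set); must be a subset of `exp2`'s universe.
#' @param exp2 A [differential_table()].
#' @param fdr_level FDR level for identification. Default 0.1.
#' @inheritParams conditional_overlap_test
#' @param seed Optional seed; `NULL` (default) continues the current RNG
#'   stream, so a chained analysis is reproducible end-to-end from one
#'   seed.
#' @return An object of class `"shared_features"`: a data.frame with
#'   columns `feature_id`, `p_value`, `qvalue`, `direction_concordant`
#'   (`NA` until [filter_concordant()] is applied), with attributes `pi0`,
#'   `fdr_level`, `n_conditioning`, and `source_experiments`.
#' @export
identify_shared_features <- function(conditioning_ids, exp2, fdr_level = 0.1,
                                     pi0_method = c("bootstrap", "smoother",
                                                    "fixed"),
                                     fixed_lambda = NULL,
                                     lambda = seq(0.05, 0.95, by = 0.05),
                                     n_boot = 100L,
                                     seed = NULL) {
  pi0_method <- match.arg(pi0_method)
  exp2 <- .as_diff_table(exp2)
  conditioning_ids <- as.character(conditioning_ids)
  missing_ids <- setdiff(conditioning_ids, exp2$feature_id)
  if (length(missing_ids)) {
    stop("conditioning ids absent from experiment 2: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "),
         call. = FALSE)
  }
  if (length(conditioning_ids) < 2L) {
    stop("conditioning set must contain at least 2 features", call. = FALSE)
  }
  if (length(conditioning_ids) < 200L) {
    warning("conditioning set has fewer than 200 features; ",
            "pi0 (and hence q-value) estimation may be unstable",
            call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sub <- exp2[match(conditioning_ids, exp2$feature_id), , drop = FALSE]
  pi1 <- .pi1_subset(sub$p_value, pi0_method, lambda, fixed_lambda, n_boot,
                     fallback_note = "conditioning set")
  qt <- compute_qvalues(sub$p_value, pi0 = 1 - pi1, alpha = fdr_level,
                        feature_ids = sub$feature_id)
  hit <- qt[qt$significant, , drop = FALSE]
  out <- data.frame(feature_id = hit$feature_id,
                    p_value = hit$p_value,
                    qvalue = hit$qvalue,
                    direction_concordant = rep(NA, nrow(hit)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "pi0") <- 1 - pi1
  attr(out, "fdr_level") <- fdr_level
  attr(out, "n_conditioning") <- length(conditioning_ids)
  attr(out, "source_experiments") <- character(0)
  class(out) <- c("shared_features", "data.frame")
  out
}

#' @export
print.shared_features <- function(x, ...) {
  cat(sprintf(
    "shared features: %d of %d conditioning features at FDR %g (pi0 = %.3f)\n",
    nrow(x), attr(x, "n_conditioning"), attr(x, "fdr_level"),
    attr(x, "pi0")))
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x), 6L), ...)
    if (nrow(x) > 6L) cat("  ... (", nrow(x) - 6L, " more rows)\n", sep = "")
  }
  invisible(x)
}

# Concordance on two named lfc vectors; zero lfc is non-concordant with
# any sign and is dropped with a warning.
.filter_concordant_lfc <- function(shared, lfc_a, lfc_b) {
  ids <- shared$feature_id
  sa <- sign(lfc_a[ids])
  sb <- sign(lfc_b[ids])
  zero <- sa == 0 | sb == 0
  if (any(zero)) {
    warning(sum(zero), " feature(s) with a log fold change of exactly 0 ",
            "dropped (no direction)", call. = FALSE)
  }
  keep <- !zero & sa == sb
  out <- shared[keep, , drop = FALSE]
  out$direction_concordant <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  for (a in c("pi0", "fdr_level", "n_conditioning", "source_experiments")) {
    attr(out, a) <- attr(shared, a)
  }
  class(out) <- class(shared)
  out
}

#' Filter shared features for direction concordance
#'
#' Retains the shared features whose log2 fold changes have the same
#' (nonzero) sign in both experiments, i.e. whose accessibility or
#' expression is altered in the same direction. Features with an lfc of
#' exactly 0 in either experiment carry no direction and are dropped with
#' a warning.
#'
#' @param shared A `"shared_features"` object.
#' @param exp_a,exp_b [differential_table()]s with an `lfc` column; every
#'   shared feature must be present in both.
#' @return The filtered `"shared_features"` object with
#'   `direction_concordant` set to `TRUE` for all retained rows.
#' @export
filter_concordant <- function(shared, exp_a, exp_b) {
  exp_a <- .as_diff_table(exp_a)
  exp_b <- .as_diff_table(exp_b)
  for (t in list(exp_a, exp_b)) {
    if (is.null(t$lfc)) {
      stop("log fold change (lfc) column required for concordance filtering",
           call. = FALSE)
    }
    missing_ids <- setdiff(shared$feature_id, t$feature_id)
    if (length(missing_ids)) {
      stop("shared features absent from an experiment table: ",
           paste(utils::head(missing_ids, 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  lfc_a <- stats::setNames(exp_a$lfc, exp_a$feature_id)
  lfc_b <- stats::setNames(exp_b$lfc, exp_b$feature_id)
  .filter_concordant_lfc(shared, lfc_a, lfc_b)
}

#' Chain the conditional overlap analysis across several experiments
#'
#' Runs the conditional overlap analysis sequentially over an ordered list
#' of experiments. Stage 1 conditions experiment 2 on experiment 1's
#' significant set ([conditional_overlap_test()]), identifies the shared
#' features ([identify_shared_features()]), and (optionally) keeps only
#' direction-concordant ones. At each later stage k, the previous stage's
#' shared set becomes the conditioning set for experiment k+1; concordance
#' then compares experiment k+1's lfc sign against the sign of the mean
#' lfc across all prior experiments.
#'
#' If a stage ends with an empty conditioning set the chain stops and the
#' partial results are returned with `status = "stopped"`.
#'
#' @param tables Ordered list (optionally named) of at least two
#'   [differential_table()]s; they are restricted to their common universe.
#' @param concordant Apply direction-concordance filtering between stages
#'   (requires `lfc` columns). Default `TRUE`.
#' @inheritParams conditional_overlap_test
#' @return An object of class `"overlap_chain"`: a list with `stages` (one
#'   `list(test =, shared =)` pair per stage), `status` (`"complete"` or
#'   `"stopped"`), and `labels`.
#' @export
chain_overlap <- function(tables, fdr_level = 0.1, n_resamples = 1000L,
                          pi0_method = c("bootstrap", "smoother", "fixed"),
                          fixed_lambda = NULL,
                          lambda = seq(0.05, 0.95, by = 0.05),
                          n_boot = 100L, seed = 1L, concordant = TRUE) {
  pi0_method <- match.arg(pi0_method)
  if (length(tables) < 2L) stop("need at least 2 tables", call. = FALSE)
  labels <- names(tables)
  if (is.null(labels)) labels <- paste0("experiment_", seq_along(tables))
  tables <- .harmonize_tables(tables)
  names(tables) <- labels
  stages <- list()
  status <- "complete"

  # Stage 1 is exactly the composition of the three single-step
  # operations: test, identify, concordance filter.
  res <- conditional_overlap_test(tables[[1L]], tables[[2L]],
                                  fdr_level = fdr_level,
                                  n_resamples = n_resamples,
                                  pi0_method = pi0_method,
                                  fixed_lambda = fixed_lambda,
                                  lambda = lambda, n_boot = n_boot,
                                  seed = seed)
  shared <- identify_shared_features(res$conditioning_ids, tables[[2L]],
                                     fdr_level = fdr_level,
                                     pi0_method = pi0_method,
                                     fixed_lambda = fixed_lambda,
                                     lambda = lambda, n_boot = n_boot)
  if (concordant && nrow(shared)) {
    shared <- filter_concordant(shared, tables[[1L]], tables[[2L]])
  }
  attr(shared, "source_experiments") <- labels[1:2]
  stages[[1L]] <- list(test = res, shared = shared)

  k <- 2L
  while (k < length(tables)) {
    cond_ids <- stages[[k - 1L]]$shared$feature_id
    if (length(cond_ids) < 2L) {
      status <- "stopped"
      break
    }
    res <- .overlap_test_on_ids(cond_ids, tables[[k + 1L]], n_resamples,
                                pi0_method, lambda, fixed_lambda, n_boot)
    res$fdr_level <- fdr_level
    shared <- identify_shared_features(cond_ids, tables[[k + 1L]],
                                       fdr_level = fdr_level,
                                       pi0_method = pi0_method,
                                       fixed_lambda = fixed_lambda,
                                       lambda = lambda, n_boot = n_boot)
    if (concordant && nrow(shared)) {
      prior_lfc <- sapply(tables[seq_len(k)], function(t) {
        stats::setNames(t$lfc, t$feature_id)[shared$feature_id]
      })
      mean_prior <- if (is.matrix(prior_lfc)) rowMeans(prior_lfc) else prior_lfc
      names(mean_prior) <- shared$feature_id
      next_lfc <- stats::setNames(tables[[k + 1L]]$lfc,
                                  tables[[k + 1L]]$feature_id)
      shared <- .filter_concordant_lfc(shared, mean_prior, next_lfc)
    }
    attr(shared, "source_experiments") <- labels[seq_len(k + 1L)]
    stages[[k]] <- list(test = res, shared = shared)
    k <- k + 1L
  }
  structure(list(stages = stages, status = status, labels = labels,
                 fdr_level = fdr_level, seed = seed),
            class = "overlap_chain")
}

#' @export
print.overlap_chain <- function(x, ...) {
  cat(sprintf("Conditional overlap chain over %d experiments (%s)\n",
              length(x$labels), x$status))
  for (i in seq_along(x$stages)) {
    st <- x$stages[[i]]
    cat(sprintf(
      "  stage %d [%s -> %s]: n = %d, pi1|1 = %.3f, est. shared = %d, identified = %d, p = %.3g\n",
      i, paste(x$labels[seq_len(i)], collapse = "+"),
      x$labels[i + 1L], st$test$n_conditioning, st$test$pi1_given_1,
      st$test$estimated_shared_count, nrow(st$shared),
      st$test$empirical_p))
  }
  invisible(x)
}

#' Naive intersection of independently thresholded hit lists
#'
#' The baseline the conditional approach improves on: call significant
#' features in every experiment separately at `fdr_level` (each with its
#' own pi0 and q-values over its full universe) and intersect the hit
#' lists. Because every shared feature must clear the threshold in every
#' experiment, this systematically underestimates the overlap.
#'
#' @param tables List of at least two [differential_table()]s on a common
#'   universe (inner join applied).
#' @inheritParams conditional_overlap_test
#' @param seed Optional seed for the pi0 bootstrap. Default `NULL`.
#' @return A list with `count` (integer) and `ids` (character vector).
#' @export
naive_intersection <- function(tables, fdr_level = 0.1,
                               pi0_method = c("bootstrap", "smoother",
                                              "fixed"),
                               fixed_lambda = NULL,
                               lambda = seq(0.05, 0.95, by = 0.05),
                               n_boot = 100L, seed = NULL) {
  pi0_method <- match.arg(pi0_method)
  tables <- .harmonize_tables(tables)
  if (!is.null(seed)) set.seed(seed)
  sig_sets <- lapply(tables, function(t) {
    pi1 <- .pi1_subset(t$p_value, pi0_method, lambda, fixed_lambda, n_boot,
                       fallback_note = "naive intersection table")
    qt <- compute_qvalues(t$p_value, pi0 = 1 - pi1, alpha = fdr_level,
                          feature_ids = t$feature_id)
    qt$feature_id[qt$significant]
  })
  ids <- Reduce(intersect, sig_sets)
  list(count = length(ids), ids = ids)
}
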