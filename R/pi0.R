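# Estimation of the proportion of true null hypotheses (pi0) and q-values.
# This is the statistical kernel used by every downstream analysis.

.check_pvalues <- function(p, what = "p-values") {
  if (length(p) == 0L) stop("empty ", what, " vector", call. = FALSE)
  if (anyNA(p)) stop(what, " contain NA", call. = FALSE)
  if (!is.numeric(p)) stop(what, " must be numeric", call. = FALSE)
  bad <- which(p < 0 | p > 1)
  if (length(bad)) {
    stop(what, " outside [0, 1] at positions ",
         paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  invisible(p)
}

# Raw counting estimator pi0(lambda) = #{p > lambda} / (m (1 - lambda)).
# Strict inequality; values may exceed 1 (clamping happens at the end).
.pi0_raw <- function(p, lambda) {
  m <- length(p)
  vapply(lambda, function(l) sum(p > l), numeric(1L)) / (m * (1 - lambda))
}

.clamp01 <- function(x) min(max(x, 0), 1)

# Core estimator without input validation or small-m warnings; used in hot
# resampling loops where the caller has already validated the inputs and
# consumes the current RNG stream.
.pi0_core <- function(p, method, lambda, fixed_lambda, n_boot) {
  if (method == "fixed") {
    raw <- .pi0_raw(p, fixed_lambda)
    return(list(pi0 = .clamp01(raw), raw = raw, grid = fixed_lambda,
                selected_lambda = fixed_lambda))
  }
  if (length(unique(p)) < 2L) {
    stop("fewer than 2 distinct p-values; use method = \"fixed\"",
         call. = FALSE)
  }
  raw <- .pi0_raw(p, lambda)
  if (method == "bootstrap") {
    m <- length(p)
    pi0_min <- min(raw)
    mse <- numeric(length(lambda))
    for (b in seq_len(n_boot)) {
      pb <- p[sample.int(m, m, replace = TRUE)]
      mse <- mse + (.pi0_raw(pb, lambda) - pi0_min)^2
    }
    sel <- which.min(mse)
    list(pi0 = .clamp01(raw[sel]), raw = raw, grid = lambda,
         selected_lambda = lambda[sel])
  } else { # smoother
    fit <- stats::smooth.spline(lambda, raw, df = 3)
    at_max <- stats::predict(fit, x = max(lambda))$y
    list(pi0 = .clamp01(at_max), raw = raw, grid = lambda,
         selected_lambda = NA_real_)
  }
}

#' Estimate the proportion of true null hypotheses
#'
#' Estimates pi0, the proportion of features whose null hypothesis is true,
#' from a collection of p-values using the counting estimator
#' \eqn{\hat\pi_0(\lambda) = \#\{p_i > \lambda\} / (m (1 - \lambda))}.
#' The tuning parameter lambda is the cutoff above which p-values are
#' assumed to come from truly non-differential features. Three selection
#' rules are offered: `"bootstrap"` picks the lambda on the grid that
#' minimises the mean squared deviation of bootstrap re-estimates from the
#' minimum full-data estimate; `"smoother"` fits a cubic smoothing spline
#' (3 effective degrees of freedom) to the \eqn{(\lambda, \hat\pi_0(\lambda))}
#' curve and evaluates it at the largest lambda; `"fixed"` evaluates the
#' counting estimator at a user-chosen lambda (useful when the p-value
#' histogram has irregular mass in the middle and the automatic rules
#' misbehave).
#'
#' The reported pi0 is clamped to `[0, 1]`; the raw per-lambda estimates
#' (which can exceed 1) are retained in `pi0_at_lambda` for diagnostics.
#' `pi1 = 1 - pi0` is the estimated proportion of truly differential
#' features, the quantity of interest in overlap estimation.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param method Selection rule: `"bootstrap"` (default), `"smoother"`,
#'   or `"fixed"`.
#' @param lambda Grid of candidate lambda values in (0, 1), strictly
#'   increasing. Default `seq(0.05, 0.95, by = 0.05)`.
#' @param fixed_lambda Lambda in (0, 1), required when `method = "fixed"`.
#' @param n_boot Number of bootstrap resamples for `method = "bootstrap"`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return An object of class `"pi0_estimate"`: a list with elements
#'   `pi0`, `pi1`, `method`, `lambda_grid`, `pi0_at_lambda` (raw,
#'   pre-clamp), and `selected_lambda` (`NA` for the smoother).
#' @examples
#' estimate_pi0(c(0.01, 0.02, 0.03, 0.9), method = "fixed",
#'              fixed_lambda = 0.5)
#' @seealso [compute_qvalues()]
#' @export
estimate_pi0 <- function(pvals,
                         method = c("bootstrap", "smoother", "fixed"),
                         lambda = seq(0.05, 0.95, by = 0.05),
                         fixed_lambda = NULL,
                         n_boot = 100L,
                         seed = NULL) {
  method <- match.arg(method)
  .check_pvalues(pvals)
  if (method == "fixed") {
    if (is.null(fixed_lambda) || length(fixed_lambda) != 1L ||
        fixed_lambda <= 0 || fixed_lambda >= 1) {
      stop("method = \"fixed\" requires fixed_lambda in (0, 1)",
           call. = FALSE)
    }
  } else {
    if (length(lambda) == 0L) stop("empty lambda grid", call. = FALSE)
    if (any(lambda <= 0 | lambda >= 1)) {
      stop("lambda grid entries must lie in (0, 1)", call. = FALSE)
    }
    if (is.unsorted(lambda, strictly = TRUE)) {
      stop("lambda grid must be strictly increasing", call. = FALSE)
    }
  }
  if (length(pvals) < 200L) {
    warning("pi0 estimation can be unreliable with fewer than 200 p-values ",
            "(m = ", length(pvals), ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  core <- .pi0_core(pvals, method, lambda, fixed_lambda, n_boot)
  structure(
    list(pi0 = core$pi0,
         pi1 = 1 - core$pi0,
         method = method,
         lambda_grid = core$grid,
         pi0_at_lambda = core$raw,
         selected_lambda = core$selected_lambda,
         m = length(pvals)),
    class = "pi0_estimate")
}

#' @export
print.pi0_estimate <- function(x, ...) {
  cat("Proportion of true nulls (pi0 estimate)\n")
  cat(sprintf("  pi0 = %.4f   pi1 = %.4f   (m = %d, method = %s)\n",
              x$pi0, x$pi1, x$m, x$method))
  if (!is.na(x$selected_lambda)) {
    cat(sprintf("  selected lambda = %g\n", x$selected_lambda))
  }
  invisible(x)
}

#' @export
plot.pi0_estimate <- function(x, ...) {
  graphics::plot(x$lambda_grid, x$pi0_at_lambda, type = "b",
                 xlab = expression(lambda),
                 ylab = expression(hat(pi)[0](lambda)), ...)
  graphics::abline(h = x$pi0, lty = 2)
  if (!is.na(x$selected_lambda)) {
    graphics::abline(v = x$selected_lambda, lty = 3)
  }
  invisible(x)
}

#' Compute Storey q-values
#'
#' Converts p-values to q-values using the estimated proportion of true
#' nulls: with sorted p-values \eqn{p_{(1)} \le \dots \le p_{(m)}},
#' \eqn{q_{(i)} = \min_{j \ge i} \pi_0 m p_{(j)} / j}, truncated at 1 and
#' mapped back to the original feature order. Calling features with
#' `qvalue < alpha` controls the false discovery rate at `alpha`. With
#' `pi0 = 1` the procedure coincides with Benjamini-Hochberg adjustment.
#'
#' @param pvals Numeric vector of p-values, or a [differential_table()]
#'   (whose `p_value` column and `feature_id`s are used).
#' @param pi0 Proportion of true nulls: a number in `[0, 1]` or a
#'   `"pi0_estimate"` object. Default 1 (conservative).
#' @param alpha FDR level in (0, 1) at which the `significant` flags are
#'   set. Default 0.1.
#' @param feature_ids Optional identifiers aligned with `pvals`; ties
#'   between equal p-values are broken stably by feature id.
#' @return An object of class `"qvalue_table"`: a data.frame with columns
#'   `feature_id`, `p_value`, `qvalue`, `significant`, and attributes
#'   `pi0` and `alpha`.
#' @examples
#' compute_qvalues(c(0.001, 0.5, 0.9), pi0 = 0.9)
#' @export
compute_qvalues <- function(pvals, pi0 = 1, alpha = 0.1, feature_ids = NULL) {
  if (inherits(pvals, "differential_table")) {
    if (is.null(feature_ids)) feature_ids <- pvals$feature_id
    pvals <- pvals$p_value
  }
  if (inherits(pi0, "pi0_estimate")) pi0 <- pi0$pi0
  .check_pvalues(pvals)
  if (length(pi0) != 1L || pi0 < 0 || pi0 > 1) {
    stop("pi0 must be a single number in [0, 1]", call. = FALSE)
  }
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  m <- length(pvals)
  if (is.null(feature_ids)) {
    feature_ids <- sprintf("feature_%0*d", nchar(m), seq_len(m))
  }
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature_ids", call. = FALSE)
  }
  ord <- order(pvals, feature_ids)
  ps <- pvals[ord]
  q_sorted <- pmin(rev(cummin(rev(pi0 * m * ps / seq_len(m)))), 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  out <- data.frame(feature_id = feature_ids,
                    p_value = pvals,
                    qvalue = q,
                    significant = q < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "pi0") <- pi0
  attr(out, "alpha") <- alpha
  class(out) <- c("qvalue_table", "data.frame")
  out
}

#' @export
print.qvalue_table <- function(x, ...) {
  cat(sprintf("q-value table: %d features, pi0 = %.4f, %d significant at FDR %g\n",
              nrow(x), attr(x, "pi0"), sum(x$significant), attr(x, "alpha")))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("  ... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}
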