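# Sliding-rank-threshold conditional-proportion analysis: how much
# differential signal do the top-K features of one experiment carry in a
# mapped second experiment (e.g. promoter peaks -> downstream genes).

#' Construct a feature map
#'
#' A many-to-many relation between source features (e.g. promoter peaks)
#' and target features (e.g. downstream genes).
#'
#' @param source_id,target_id Character vectors of equal length; duplicate
#'   pairs are removed.
#' @return A data.frame of class `"feature_map"` with columns `source_id`
#'   and `target_id`.
#' @export
feature_map <- function(source_id, target_id) {
  source_id <- as.character(source_id)
  target_id <- as.character(target_id)
  if (length(source_id) != length(target_id)) {
    stop("source_id and target_id lengths differ", call. = FALSE)
  }
  if (any(!nzchar(source_id)) || any(!nzchar(target_id))) {
    stop("empty ids in feature map", call. = FALSE)
  }
  out <- unique(data.frame(source_id = source_id, target_id = target_id,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("feature_map", "data.frame")
  out
}

# Ranks by ascending p-value, ties broken stably by feature id.
.rank_order <- function(table) {
  order(table$p_value, table$feature_id)
}

#' Conditional proportion of differential targets over sliding rank
#' thresholds
#'
#' For each threshold K: take the top-K source features of `ranking` by
#' ascending p-value (ties broken by feature id), map them to target
#' features (deduplicated — each target contributes one p-value however
#' many sources point to it), and estimate the proportion of truly
#' differential targets, \eqn{\hat\pi_1 = 1 - \hat\pi_0}, from the
#' `response` p-values on that target set. K counts source features, so a
#' threshold of 1000 means the top 1000 peaks, not genes.
#'
#' @param ranking Source-experiment [differential_table()] (defines the
#'   ranking).
#' @param response Target-experiment [differential_table()] (supplies the
#'   p-values whose differential proportion is estimated).
#' @param map A [feature_map()] from ranking to response features.
#' @param thresholds Strictly increasing integer rank thresholds; default
#'   `seq(1000, 5000, by = 250)`.
#' @param pi0_method pi0 selection rule; `"bootstrap"` by default.
#' @param fixed_lambda Optional lambda: when supplied the counting
#'   estimator at that lambda is used regardless of `pi0_method` (the
#'   manual override for irregular p-value histograms).
#' @param lambda Lambda grid for bootstrap/smoother selection.
#' @param n_boot Bootstrap resamples per pi0 estimate.
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `"rank_scan"`: a data.frame with columns
#'   `threshold`, `proportion` (`NA` where no targets were mapped, with a
#'   warning), and `n_mapped`.
#' @export
rank_conditional_proportion <- function(ranking, response, map,
                                        thresholds = seq(1000L, 5000L,
                                                         by = 250L),
                                        pi0_method = c("bootstrap",
                                                       "smoother", "fixed"),
                                        fixed_lambda = NULL,
                                        lambda = seq(0.05, 0.95, by = 0.05),
                                        n_boot = 100L, seed = NULL) {
  pi0_method <- match.arg(pi0_method)
  ranking <- .as_diff_table(ranking)
  response <- .as_diff_table(response)
  if (!inherits(map, "feature_map")) {
    map <- feature_map(map[[1L]], map[[2L]])
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing", call. = FALSE)
  }
  if (max(thresholds) > nrow(ranking)) {
    stop("largest threshold exceeds the number of ranked features",
         call. = FALSE)
  }
  outside <- setdiff(map$target_id, response$feature_id)
  if (length(outside)) {
    stop("map targets absent from the response universe: ",
         paste(utils::head(outside, 5L), collapse = ", "), call. = FALSE)
  }
  if (!is.null(fixed_lambda)) pi0_method <- "fixed"
  if (!is.null(seed)) set.seed(seed)
  ord <- .rank_order(ranking)
  p_resp <- stats::setNames(response$p_value, response$feature_id)
  proportion <- numeric(length(thresholds))
  n_mapped <- integer(length(thresholds))
  for (i in seq_along(thresholds)) {
    top_ids <- ranking$feature_id[ord[seq_len(thresholds[i])]]
    targets <- unique(map$target_id[map$source_id %in% top_ids])
    n_mapped[i] <- length(targets)
    if (length(targets) == 0L) {
      warning("no mapped targets at threshold ", thresholds[i],
              call. = FALSE)
      proportion[i] <- NA_real_
      next
    }
    proportion[i] <- .pi1_subset(p_resp[targets], pi0_method, lambda,
                                 fixed_lambda, n_boot,
                                 fallback_note = paste0("threshold ",
                                                        thresholds[i]))
  }
  out <- data.frame(threshold = as.integer(thresholds),
                    proportion = proportion, n_mapped = n_mapped)
  class(out) <- c("rank_scan", "data.frame")
  out
}

#' @export
print.rank_scan <- function(x, ...) {
  cat(sprintf("rank-threshold scan: %d thresholds (%d..%d)\n",
              nrow(x), min(x$threshold), max(x$threshold)))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

#' @export
plot.rank_scan <- function(x, ...) {
  graphics::plot(x$threshold, x$proportion, type = "b",
                 xlab = "rank threshold (top-K source features)",
                 ylab = "estimated proportion differential",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' Collapse source effects to target-level medians
#'
#' For each target feature, the median of the log2 fold changes of all
#' source features mapping to it (e.g. the median across the peaks of one
#' promoter); even counts use the midpoint convention.
#'
#' @param map A [feature_map()].
#' @param source A [differential_table()] with an `lfc` column containing
#'   every mapped source feature.
#' @return A data.frame with columns `target_id` and `median_lfc`, one row
#'   per target, ordered by `target_id`.
#' @export
collapse_effects <- function(map, source) {
  source <- .as_diff_table(source)
  if (is.null(source$lfc)) stop("source table lacks an lfc column",
                                call. = FALSE)
  if (!inherits(map, "feature_map")) map <- feature_map(map[[1L]], map[[2L]])
  missing_ids <- setdiff(map$source_id, source$feature_id)
  if (length(missing_ids)) {
    stop("mapped source ids absent from the source table: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "),
         call. = FALSE)
  }
  lfc <- stats::setNames(source$lfc, source$feature_id)
  med <- tapply(lfc[map$source_id], map$target_id, stats::median)
  out <- data.frame(target_id = names(med),
                    median_lfc = as.numeric(med),
                    stringsAsFactors = FALSE)
  out <- out[order(out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select features uniquely top-ranked in one experiment
#'
#' Returns the features ranked within the top `top_k` (by ascending
#' p-value) of the focal experiment that are neither in `shared_ids` nor
#' within the top `exclusion_k` of any other experiment — i.e. the
#' features whose signal is specific to the focal experiment.
#'
#' @param experiments Named list of [differential_table()]s.
#' @param focal Name of the focal experiment.
#' @param top_k Rank cutoff defining the focal top set. Default 1000.
#' @param exclusion_k Rank cutoff in the other experiments above which a
#'   feature is considered shared and excluded. Default 5000.
#' @param shared_ids Feature ids (e.g. the identified shared set) to
#'   exclude regardless of rank.
#' @return Character vector of feature ids, in focal rank order.
#' @export
select_unique_top <- function(experiments, focal, top_k = 1000L,
                              exclusion_k = 5000L,
                              shared_ids = character(0)) {
  if (!focal %in% names(experiments)) {
    stop("focal experiment \"", focal, "\" not found", call. = FALSE)
  }
  experiments <- lapply(experiments, .as_diff_table)
  if (top_k > exclusion_k) {
    stop("top_k must not exceed exclusion_k", call. = FALSE)
  }
  foc <- experiments[[focal]]
  if (top_k > nrow(foc)) stop("top_k exceeds universe size", call. = FALSE)
  top_ids <- foc$feature_id[.rank_order(foc)[seq_len(top_k)]]
  for (nm in setdiff(names(experiments), focal)) {
    oth <- experiments[[nm]]
    k <- min(exclusion_k, nrow(oth))
    excl <- oth$feature_id[.rank_order(oth)[seq_len(k)]]
    top_ids <- setdiff(top_ids, excl)
  }
  setdiff(top_ids, as.character(shared_ids))
}

#' Cross-tabulate a gene set's p-value quartiles between two rankings
#'
#' Bins the genes of `gene_set` by their p-value quartile in `ranking_b`
#' (quartiles computed within the gene set; boundary ties go to the lower
#' quartile) and reports, per bin, the fraction of genes that belong to
#' the top 25% of the gene set by `ranking_a` p-value. Identical rankings
#' put all mass in the first quartile; independent rankings spread it
#' evenly (~0.25 per bin).
#'
#' @param ranking_a,ranking_b [differential_table()]s whose universes both
#'   contain `gene_set`.
#' @param gene_set Character vector of at least 8 gene ids.
#' @return A data.frame with columns `quartile` (1-4), `n`, and
#'   `fraction_top_a`.
#' @export
quartile_cross_table <- function(ranking_a, ranking_b, gene_set) {
  ranking_a <- .as_diff_table(ranking_a)
  ranking_b <- .as_diff_table(ranking_b)
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) < 8L) {
    stop("gene_set must contain at least 8 genes for quartiles",
         call. = FALSE)
  }
  for (t in list(ranking_a, ranking_b)) {
    missing_ids <- setdiff(gene_set, t$feature_id)
    if (length(missing_ids)) {
      stop("gene set members absent from a ranking: ",
           paste(utils::head(missing_ids, 5L), collapse = ", "),
           call. = FALSE)
    }
  }
  pa <- stats::setNames(ranking_a$p_value, ranking_a$feature_id)[gene_set]
  pb <- stats::setNames(ranking_b$p_value, ranking_b$feature_id)[gene_set]
  qs <- stats::quantile(pb, probs = c(0.25, 0.5, 0.75), names = FALSE)
  # right-closed bins: boundary ties fall in the lower quartile
  bin <- findInterval(pb, qs, left.open = TRUE) + 1L
  top_a <- pa <= stats::quantile(pa, probs = 0.25, names = FALSE)
  out <- data.frame(quartile = 1:4,
                    n = as.integer(tabulate(bin, nbins = 4L)),
                    fraction_top_a = vapply(1:4, function(q) {
                      if (any(bin == q)) mean(top_a[bin == q]) else NA_real_
                    }, numeric(1L)))
  out
}
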