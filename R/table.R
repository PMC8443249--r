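# The per-experiment differential-analysis result container.

#' Construct a differential-analysis result table
#'
#' Holds one experiment's per-feature differential-analysis results: a
#' unique feature identifier, a p-value, and optionally a log2 fold change
#' (the effect direction used for concordance filtering) and a test
#' statistic.
#'
#' @param feature_id Character vector of unique feature identifiers.
#' @param p_value Numeric p-values in `[0, 1]`, aligned with `feature_id`.
#' @param lfc Optional signed log2 fold changes, aligned with `feature_id`.
#' @param stat Optional signed test statistics.
#' @return A data.frame of class `"differential_table"` with columns
#'   `feature_id`, `p_value`, and optionally `lfc`, `stat`.
#' @examples
#' differential_table(c("a", "b"), c(0.01, 0.8), lfc = c(1.2, -0.3))
#' @export
differential_table <- function(feature_id, p_value, lfc = NULL, stat = NULL) {
  feature_id <- as.character(feature_id)
  if (length(feature_id) != length(p_value)) {
    stop("feature_id and p_value lengths differ", call. = FALSE)
  }
  if (anyDuplicated(feature_id)) {
    dup <- unique(feature_id[duplicated(feature_id)])
    stop("duplicate feature_ids: ",
         paste(utils::head(dup, 5L), collapse = ", "),
         if (length(dup) > 5L) " ..." else "", call. = FALSE)
  }
  if (any(!nzchar(feature_id))) stop("empty feature_id", call. = FALSE)
  .check_pvalues(p_value)
  out <- data.frame(feature_id = feature_id, p_value = p_value,
                    stringsAsFactors = FALSE)
  if (!is.null(lfc)) {
    if (length(lfc) != length(feature_id)) {
      stop("lfc length differs from feature_id", call. = FALSE)
    }
    out$lfc <- as.numeric(lfc)
  }
  if (!is.null(stat)) {
    if (length(stat) != length(feature_id)) {
      stop("stat length differs from feature_id", call. = FALSE)
    }
    out$stat <- as.numeric(stat)
  }
  class(out) <- c("differential_table", "data.frame")
  out
}

.is_diff_table <- function(x) {
  inherits(x, "differential_table") ||
    (is.data.frame(x) && all(c("feature_id", "p_value") %in% names(x)))
}

.as_diff_table <- function(x, arg = deparse(substitute(x))) {
  if (!.is_diff_table(x)) {
    stop(arg, " is not a differential table (needs feature_id and p_value)",
         call. = FALSE)
  }
  if (!inherits(x, "differential_table")) {
    x <- differential_table(x$feature_id, x$p_value, lfc = x$lfc,
                            stat = x$stat)
  }
  x
}

#' @export
print.differential_table <- function(x, ...) {
  cat(sprintf("differential table: %d features (%s)\n", nrow(x),
              paste(setdiff(names(x), "feature_id"), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("  ... (", nrow(x) - 6L, " more rows)\n", sep = "")
  invisible(x)
}

# Restrict a list of tables to their common feature universe (inner join
# on feature_id), warning about the number dropped from each side.
.harmonize_tables <- function(tables) {
  stopifnot(length(tables) >= 2L)
  tables <- lapply(tables, .as_diff_table)
  common <- Reduce(intersect, lapply(tables, function(t) t$feature_id))
  if (length(common) == 0L) {
    stop("tables share no common features", call. = FALSE)
  }
  dropped <- vapply(tables, function(t) nrow(t) - length(common), integer(1L))
  if (any(dropped > 0L)) {
    warning("restricting to ", length(common), " common features; dropped ",
            paste(dropped, collapse = ", "),
            " features from the respective tables", call. = FALSE)
  }
  lapply(tables, function(t) {
    t <- t[match(common, t$feature_id), , drop = FALSE]
    rownames(t) <- NULL
    t
  })
}
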