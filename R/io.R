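# Readers, writers, fixture generation. The single interchange dialect is
# tab-separated text with a header; dot decimal separator only.

#' Read a differential-analysis result table from TSV
#'
#' Expects a tab-separated file with a header and at least the columns
#' `feature_id` and `p_value`; `lfc` and `stat` are picked up when
#' present. Scientific-notation p-values are accepted. Rows with
#' unparseable or out-of-range p-values are rejected with their file line
#' numbers; duplicate feature ids are an error.
#'
#' @param path Path to the file.
#' @param column_map Optional named character vector renaming file columns
#'   to the canonical names, e.g. `c(pval = "p_value")` maps a file column
#'   `pval` onto `p_value`.
#' @return A [differential_table()].
#' @export
read_differential_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    hit <- names(raw) %in% names(column_map)
    names(raw)[hit] <- column_map[names(raw)[hit]]
  }
  for (col in c("feature_id", "p_value")) {
    if (!col %in% names(raw)) {
      stop("missing required column \"", col, "\" in ", path, call. = FALSE)
    }
  }
  if (nrow(raw) == 0L) stop("empty table: ", path, call. = FALSE)
  p <- suppressWarnings(as.numeric(raw$p_value))
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad)) {
    stop("unparseable or out-of-range p_value on line(s) ",
         paste(utils::head(bad + 1L, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "",
         " of ", path, call. = FALSE)
  }
  lfc <- if ("lfc" %in% names(raw)) {
    v <- suppressWarnings(as.numeric(raw$lfc))
    if (anyNA(v)) {
      stop("unparseable lfc on line(s) ",
           paste(utils::head(which(is.na(v)) + 1L, 5L), collapse = ", "),
           " of ", path, call. = FALSE)
    }
    v
  } else NULL
  stat <- if ("stat" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$stat))
  } else NULL
  differential_table(raw$feature_id, p, lfc = lfc, stat = stat)
}

#' Read a feature map from two-column TSV
#'
#' @param path Path to a tab-separated file with header columns
#'   `source_id` and `target_id` (or any two columns, taken in order).
#' @return A [feature_map()].
#' @export
read_feature_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("feature map needs two columns", call. = FALSE)
  if (all(c("source_id", "target_id") %in% names(raw))) {
    feature_map(raw$source_id, raw$target_id)
  } else {
    feature_map(raw[[1L]], raw[[2L]])
  }
}

#' Read a gene set (one id per line)
#'
#' @param path Path to a plain-text file, one gene id per line; blank
#'   lines and lines starting with `#` are skipped.
#' @return Character vector of unique ids.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ids <- readLines(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  unique(ids)
}

#' Write a shared-feature set to TSV
#'
#' Writes the identified shared features with q-values at full precision
#' (the write/read round trip preserves ids, q-values to 12 significant
#' digits, and concordance flags). An empty set yields a header-only file.
#'
#' @param shared A `"shared_features"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shared_features <- function(shared, path) {
  df <- data.frame(feature_id = shared$feature_id,
                   p_value = format(shared$p_value, digits = 15,
                                    scientific = TRUE, trim = TRUE),
                   qvalue = format(shared$qvalue, digits = 15,
                                   scientific = TRUE, trim = TRUE),
                   direction_concordant = shared$direction_concordant,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a shared-feature set written by [write_shared_features()]
#'
#' @param path Path to the TSV file.
#' @return A `"shared_features"` data.frame (without estimation
#'   attributes, which live in the run summary).
#' @export
read_shared_features <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  out <- data.frame(feature_id = raw$feature_id,
                    p_value = as.numeric(raw$p_value),
                    qvalue = as.numeric(raw$qvalue),
                    direction_concordant = as.logical(
                      raw$direction_concordant),
                    stringsAsFactors = FALSE)
  class(out) <- c("shared_features", "data.frame")
  out
}

#' Write a machine-readable run summary
#'
#' Key-value text (`key<TAB>value`, one per line) summarising an overlap
#' test: n, pi1|1, estimated shared count, B, empirical and normal
#' approximation p-values, seed.
#'
#' @param result A `"conditional_overlap"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_summary <- function(result, path) {
  kv <- c(n_conditioning = result$n_conditioning,
          pi1_given_1 = format(result$pi1_given_1, digits = 15),
          pi1_given_0 = format(result$pi1_given_0, digits = 15),
          estimated_shared_count = result$estimated_shared_count,
          n_resamples = result$n_resamples,
          empirical_p = format(result$empirical_p, digits = 15),
          normal_approx_p = format(result$normal_approx_p, digits = 15),
          pi0_method = result$pi0_method,
          seed = if (is.null(result$seed)) NA else result$seed)
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the package version, the command, the full parameter set
#' (including seeds), input file MD5 digests, and a timestamp, so a run
#' can be reproduced bit-exactly.
#'
#' @param path Output path.
#' @param command Character description of the invocation.
#' @param params Named list of parameters (seeds included).
#' @param inputs Character vector of input file paths to digest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, params = list(),
                           inputs = character(0)) {
  lines <- c(
    paste0("tool\tcondoverlap ",
           as.character(utils::packageVersion("condoverlap"))),
    paste0("command\t", command),
    paste0("timestamp\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  if (length(params)) {
    lines <- c(lines, paste0("param:", names(params), "\t",
                             vapply(params, function(v)
                               paste(format(v, digits = 15),
                                     collapse = ","), character(1L))))
  }
  for (f in inputs) {
    lines <- c(lines, paste0("input:", f, "\t",
                             unname(tools::md5sum(f))))
  }
  writeLines(lines, path)
  invisible(path)
}

.write_diff_table <- function(table, path) {
  df <- as.data.frame(table)
  df$p_value <- format(df$p_value, digits = 15, scientific = TRUE,
                       trim = TRUE)
  if (!is.null(df$lfc)) df$lfc <- format(df$lfc, digits = 15, trim = TRUE)
  if (!is.null(df$stat)) df$stat <- format(df$stat, digits = 15,
                                           trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Generate small deterministic fixture datasets
#'
#' Writes small TSV datasets (at most 2,000 features) that exercise each
#' analysis path end-to-end in seconds:
#' * `"null_pair"`: experiment 1 with 200 strongly differential features
#'   (Beta(0.1, 1) p-values), experiment 2 fully uniform — no shared
#'   signal, the overlap null holds.
#' * `"enriched_pair"`: as above but experiment 2's p-values on
#'   experiment 1's signal features are Beta(0.1, 1) — strong overlap.
#' * `"trio"`: a down-scaled three-experiment simulation (2,000 features,
#'   400 differential, 280 shared between 1 and 2, 200 across all three,
#'   30 samples per group) with truth labels.
#' * `"geneset"`: a 2,000-feature table plus a 50-gene set file whose
#'   members carry Beta(0.3, 1) p-values.
#'
#' @param kind One of `"null_pair"`, `"enriched_pair"`, `"trio"`,
#'   `"geneset"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the file paths written, invisibly.
#' @export
generate_fixtures <- function(kind = c("null_pair", "enriched_pair",
                                       "trio", "geneset"),
                              seed = 1L, dir = tempdir()) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  m <- 2000L
  ids <- sprintf("feature_%04d", seq_len(m))
  paths <- character(0)
  if (kind %in% c("null_pair", "enriched_pair")) {
    signal <- seq_len(200L)
    p1 <- stats::runif(m)
    p1[signal] <- stats::rbeta(length(signal), 0.1, 1)
    p2 <- stats::runif(m)
    if (kind == "enriched_pair") {
      p2[signal] <- stats::rbeta(length(signal), 0.1, 1)
    }
    lfc1 <- stats::rnorm(m); lfc2 <- stats::rnorm(m)
    if (kind == "enriched_pair") {
      # concordant directions on the signal block
      lfc2[signal] <- abs(lfc2[signal]) * sign(lfc1[signal])
    }
    t1 <- differential_table(ids, p1, lfc = lfc1)
    t2 <- differential_table(ids, p2, lfc = lfc2)
    paths <- c(exp1 = file.path(dir, paste0(kind, "_exp1.tsv")),
               exp2 = file.path(dir, paste0(kind, "_exp2.tsv")))
    .write_diff_table(t1, paths[["exp1"]])
    .write_diff_table(t2, paths[["exp2"]])
  } else if (kind == "trio") {
    cfg <- sim_config(m = 2000L, n_diff = 400L, n_shared_12 = 280L,
                      n_shared_123 = 200L, n_per_group = 30L,
                      n_reps = 20L, seed = seed)
    trio <- simulate_trio(cfg, rep_index = 0L)
    paths <- c(exp1 = file.path(dir, "trio_exp1.tsv"),
               exp2 = file.path(dir, "trio_exp2.tsv"),
               exp3 = file.path(dir, "trio_exp3.tsv"),
               truth = file.path(dir, "trio_truth.tsv"))
    for (e in 1:3) {
      .write_diff_table(trio$tables[[e]], paths[[e]])
    }
    truth_df <- data.frame(feature_id = trio$tables[[1L]]$feature_id,
                           exp1 = trio$truth[, 1L],
                           exp2 = trio$truth[, 2L],
                           exp3 = trio$truth[, 3L])
    utils::write.table(truth_df, paths[["truth"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else { # geneset
    set_members <- sample(ids, 50L)
    p <- stats::runif(m)
    p[match(set_members, ids)] <- stats::rbeta(50L, 0.3, 1)
    t1 <- differential_table(ids, p, lfc = stats::rnorm(m))
    paths <- c(table = file.path(dir, "geneset_table.tsv"),
               set = file.path(dir, "geneset_members.txt"))
    .write_diff_table(t1, paths[["table"]])
    writeLines(set_members, paths[["set"]])
  }
  invisible(paths)
}
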