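# Quality-control filters applied, in order, before the pairwise PCA:
#   1. remove cells with any missing parameter,
#   2. remove cells more than k (default 5) within-treatment SDs from the
#      within-treatment mean in ANY parameter (single pass),
#   3. balanced random subsample to equal per-treatment cell counts.
# Each step only deletes rows; values are never edited.

#' Remove cells with missing data
#'
#' Drops every row with at least one missing parameter value. Idempotent.
#'
#' @param table A feature table.
#' @return The filtered table, with attribute `n_removed`.
#' @export
drop_incomplete <- function(table) {
  check_feature_table(table)
  pars <- parameter_names(table)
  keep <- !apply(is.na(table[pars]), 1L, any)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L)
    warning("all cells removed: every row had missing data", call. = FALSE)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Remove within-treatment outlier cells
#'
#' For each treatment independently, computes each parameter's mean and
#' sample SD over that treatment's cells, then removes any cell lying more
#' than `k` SD from the mean in any parameter. A single pass: statistics
#' come from the table before any removal. Parameters with zero SD within
#' a treatment never remove a cell; treatments with fewer than two cells
#' are kept unchanged with a warning (SD undefined).
#'
#' @param table A complete feature table (run [drop_incomplete()] first).
#' @param k SD multiple; default 5.
#' @return The filtered table, with attribute `n_removed`.
#' @export
drop_outliers <- function(table, k = 5) {
  check_feature_table(table, require_complete = TRUE)
  stopifnot(is.numeric(k), length(k) == 1L, k > 0)
  pars <- parameter_names(table)
  keep <- rep(TRUE, nrow(table))
  for (tr in unique(table$treatment)) {
    idx <- which(table$treatment == tr)
    if (length(idx) < 2L) {
      warning("treatment ", sQuote(tr),
              " has fewer than 2 cells; SD undefined, cells kept",
              call. = FALSE)
      next
    }
    x <- as.matrix(table[idx, pars, drop = FALSE])
    mu <- colMeans(x)
    sd_ <- apply(x, 2L, stats::sd)
    z_ok <- sweep(abs(sweep(x, 2L, mu)), 2L, k * sd_, `<=`)
    z_ok[, sd_ == 0] <- TRUE              # zero spread: nothing is an outlier
    keep[idx] <- apply(z_ok, 1L, all)
  }
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Balanced random subsample per treatment
#'
#' Samples exactly `n` cells per treatment, uniformly without replacement,
#' so every treatment carries equal weight in the pairwise PCA. With
#' `n = "auto"` (the default) `n` is the smallest per-treatment count —
#' mirroring the usual practice of subsampling to the least-populated
#' treatment. Output rows are ordered by treatment (first appearance
#' order), then sampled order.
#'
#' @param table A feature table.
#' @param n Cells per treatment, or `"auto"`.
#' @param seed Integer seed; fully determines the selection.
#' @return The subsampled table.
#' @export
balanced_subsample <- function(table, n = "auto", seed = 1) {
  check_feature_table(table)
  counts <- table(table$treatment)
  if (identical(n, "auto")) n <- min(counts)
  stopifnot(is_count(n))
  short <- names(counts)[counts < n]
  if (length(short))
    stop("treatment(s) with fewer than ", n, " cells: ",
         paste(short, collapse = ", "), call. = FALSE)
  with_seed(seed, {
    picked <- lapply(unique(table$treatment), function(tr) {
      idx <- which(table$treatment == tr)
      idx[sample.int(length(idx), n)]
    })
    out <- table[unlist(picked), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Run the full QC sequence
#'
#' [drop_incomplete()], then [drop_outliers()], then
#' [balanced_subsample()], in that fixed order.
#'
#' @inheritParams drop_outliers
#' @inheritParams balanced_subsample
#' @return The QC'd table; attribute `qc_report` is a data frame of rows
#'   removed/retained per step.
#' @export
qc_filter <- function(table, k = 5, n = "auto", seed = 1) {
  t1 <- drop_incomplete(table)
  t2 <- drop_outliers(t1, k = k)
  t3 <- balanced_subsample(t2, n = n, seed = seed)
  attr(t3, "qc_report") <- data.frame(
    step = c("input", "drop_incomplete", "drop_outliers",
             "balanced_subsample"),
    n_rows = c(nrow(table), nrow(t1), nrow(t2), nrow(t3)),
    n_removed = c(0L, attr(t1, "n_removed"), attr(t2, "n_removed"),
                  nrow(t2) - nrow(t3)))
  t3
}
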