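# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All exported generators route their randomness through this so that a
# seed argument fully determines the output without clobbering the session.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed; kept below 2^31.
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

#' Metadata column names of a feature table
#'
#' Feature tables carry three metadata columns (`cell_id`, `treatment`,
#' `replicate`); every other column is a numeric cytological parameter.
#'
#' @return Character vector of the reserved metadata column names.
#' @export
feature_metadata_cols <- function() c("cell_id", "treatment", "replicate")

#' Names of the parameter columns of a feature table
#'
#' @param table A feature table (data frame with `cell_id`, `treatment`,
#'   `replicate` plus numeric parameter columns).
#' @return Character vector of parameter column names.
#' @export
parameter_names <- function(table) {
  setdiff(names(table), feature_metadata_cols())
}

# Validate the feature-table contract; returns the table invisibly.
check_feature_table <- function(table, require_complete = FALSE) {
  if (!is.data.frame(table))
    stop("feature table must be a data frame", call. = FALSE)
  missing_meta <- setdiff(feature_metadata_cols(), names(table))
  if (length(missing_meta))
    stop("feature table lacks metadata column(s): ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  if (anyDuplicated(table$cell_id))
    stop("duplicate cell_id in feature table", call. = FALSE)
  pars <- parameter_names(table)
  if (length(pars) == 0L)
    stop("feature table has zero parameter columns", call. = FALSE)
  if (!all(vapply(table[pars], is.numeric, logical(1L))))
    stop("non-numeric parameter column in feature table", call. = FALSE)
  if (require_complete && anyNA(table[pars]))
    stop("feature table contains missing values", call. = FALSE)
  invisible(table)
}
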