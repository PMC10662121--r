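# Seeded generator for per-cell feature tables with treatment structure:
# each treatment's cells are drawn from a multivariate normal with a
# treatment-specific mean and covariance, with optional entry-wise missing
# values and gross single-parameter outliers. This is the synthetic stand-in
# for CellProfiler-exported per-cell cytological measurements.

#' Specify one treatment's cell population
#'
#' Describes the generating distribution of one treatment's per-cell
#' cytological profile: a multivariate normal with optional completely-at-
#' random missing entries and gross outliers. Outliers displace exactly one
#' randomly chosen parameter of a contaminated cell by `outlier_scale` times
#' that parameter's SD, which makes the downstream 5-SD filter's action
#' predictable.
#'
#' @param name Treatment label.
#' @param n_cells Number of cells to draw.
#' @param mean_vector Numeric mean vector (length = number of parameters).
#' @param covariance Symmetric positive-semidefinite covariance matrix; a
#'   single number is expanded to `sigma^2 * I`.
#' @param missing_rate Probability in `[0, 1]` that any one entry is missing.
#' @param outlier_rate Probability in `[0, 1]` that a cell is contaminated.
#' @param outlier_scale Displacement, in per-parameter SD units, applied to
#'   the single contaminated parameter of an outlier cell.
#' @return An object of class `treatment_spec`.
#' @export
treatment_spec <- function(name, n_cells, mean_vector, covariance,
                           missing_rate = 0, outlier_rate = 0,
                           outlier_scale = 10) {
  stopifnot(is.character(name), length(name) == 1L, is_count(n_cells))
  p <- length(mean_vector)
  if (length(covariance) == 1L) covariance <- diag(as.numeric(covariance), p)
  covariance <- as.matrix(covariance)
  if (!isSymmetric(unname(covariance), tol = 1e-8))
    stop("covariance must be symmetric", call. = FALSE)
  if (nrow(covariance) != p)
    stop("mean_vector length must equal covariance dimension", call. = FALSE)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance is not positive semi-definite", call. = FALSE)
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1, outlier_scale > 0)
  structure(list(name = name, n_cells = as.integer(n_cells),
                 mean_vector = as.numeric(mean_vector),
                 covariance = covariance,
                 missing_rate = missing_rate, outlier_rate = outlier_rate,
                 outlier_scale = outlier_scale),
            class = "treatment_spec")
}

#' Generate a synthetic per-cell feature table
#'
#' Draws every treatment's cells from its multivariate normal model,
#' assigns replicate labels round-robin, then injects missing entries
#' (entry-wise, completely at random) and gross outliers (one parameter per
#' contaminated cell, displaced by `outlier_scale` SD). Identical arguments
#' and seed give an identical table.
#'
#' @param specs A `treatment_spec` or list of them; all must share the
#'   dimension of `parameter_names`.
#' @param parameter_names Character vector naming the parameter columns.
#' @param n_replicates Number of replicate labels to cycle through.
#' @param seed Integer seed; fully determines the output.
#' @return A feature table: data frame with columns `cell_id`, `treatment`,
#'   `replicate`, then one numeric column per parameter.
#' @examples
#' sp <- treatment_spec("ctrl", 50, rep(0, 3), diag(3))
#' tab <- gen_feature_table(sp, c("area", "perimeter", "ecc"),
#'                          n_replicates = 4, seed = 1)
#' @export
gen_feature_table <- function(specs, parameter_names, n_replicates = 4,
                              seed = 1) {
  if (inherits(specs, "treatment_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L, is_count(n_replicates))
  p <- length(parameter_names)
  for (sp in specs) {
    stopifnot(inherits(sp, "treatment_spec"))
    if (length(sp$mean_vector) != p)
      stop("treatment ", sQuote(sp$name), ": mean_vector length ",
           length(sp$mean_vector), " does not match ", p,
           " parameter names", call. = FALSE)
  }
  with_seed(seed, {
    blocks <- lapply(specs, function(sp) {
      n <- sp$n_cells
      x <- MASS::mvrnorm(n, mu = sp$mean_vector, Sigma = sp$covariance)
      x <- matrix(x, nrow = n, ncol = p)
      sds <- sqrt(diag(sp$covariance))
      # gross outliers: one random parameter per contaminated cell
      if (sp$outlier_rate > 0) {
        hit <- which(stats::runif(n) < sp$outlier_rate)
        if (length(hit)) {
          j <- sample.int(p, length(hit), replace = TRUE)
          x[cbind(hit, j)] <- x[cbind(hit, j)] +
            sp$outlier_scale * pmax(sds[j], 1e-12)
        }
      }
      if (sp$missing_rate > 0)
        x[stats::runif(n * p) < sp$missing_rate] <- NA_real_
      colnames(x) <- parameter_names
      data.frame(treatment = rep(sp$name, n),
                 replicate = paste0("rep", ((seq_len(n) - 1L) %% n_replicates) + 1L),
                 x, check.names = FALSE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, blocks)
    out <- cbind(cell_id = paste0("cell_", seq_len(nrow(out))), out,
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    check_feature_table(out)
    out
  })
}
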