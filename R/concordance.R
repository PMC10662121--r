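# The analysis core of bacterial cytological profiling: for a pair of
# treatments, PCA of the pooled, scaled-and-centred per-cell parameters;
# 95% confidence ellipses of each treatment's PC1-PC2 scores; and the
# concordance statistic
#
#     concordance = #{cells inside both ellipses} / #{cells inside either},
#
# evaluated over all cells of both treatments. High concordance between a
# query compound and a reference antibiotic is read as morphological (and
# hence mechanism-of-action) similarity.

#' Pairwise PCA of two treatments' feature tables
#'
#' Pools the cells of both treatments, centres and scales every parameter
#' on the pooled data, and runs a principal component analysis
#' ([stats::prcomp]) so both treatments live in one comparable PC space.
#' Parameters with zero pooled variance are dropped with a warning before
#' scaling. Loading signs follow the convention that each column's
#' largest-magnitude entry is positive.
#'
#' @param table_a,table_b Feature tables with identical parameter columns,
#'   already QC'd (complete).
#' @return A list of class `pairwise_pca`: `model` (centre, scale,
#'   loadings, explained variance, dropped parameters) and `scores_a`,
#'   `scores_b` (n x 2 matrices of PC1-PC2 scores).
#' @export
fit_pairwise_pca <- function(table_a, table_b) {
  check_feature_table(table_a, require_complete = TRUE)
  check_feature_table(table_b, require_complete = TRUE)
  pars <- intersect(parameter_names(table_a), parameter_names(table_b))
  if (length(pars) == 0L) stop("no common parameter columns", call. = FALSE)
  xa <- as.matrix(table_a[pars]); xb <- as.matrix(table_b[pars])
  pooled <- rbind(xa, xb)
  if (nrow(pooled) < 3L) stop("need at least 3 cells in total", call. = FALSE)
  sds <- apply(pooled, 2L, stats::sd)
  drop <- names(sds)[sds == 0]
  if (length(drop)) {
    warning("dropping zero-variance parameter(s): ",
            paste(drop, collapse = ", "), call. = FALSE)
    pars <- setdiff(pars, drop)
    if (length(pars) == 0L)
      stop("all parameters have zero variance", call. = FALSE)
    pooled <- pooled[, pars, drop = FALSE]
  }
  pc <- stats::prcomp(pooled, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| entry of each column positive
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2L, flip, `*`)
  pc$x <- sweep(pc$x, 2L, flip, `*`)
  k <- min(2L, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  model <- list(center = pc$center, scale = pc$scale, loadings = pc$rotation,
                explained_variance = pc$sdev^2, dropped = drop)
  structure(list(model = model,
                 scores_a = scores[seq_len(nrow(xa)), , drop = FALSE],
                 scores_b = scores[nrow(xa) + seq_len(nrow(xb)), ,
                                   drop = FALSE]),
            class = "pairwise_pca")
}

#' Confidence ellipse of a 2-D point cloud
#'
#' The ellipse is centred at the sample mean with shape the sample
#' covariance; its squared Mahalanobis radius is
#' \deqn{r^2 = \frac{2(n-1)}{n-2} F_{level}(2, n-2)} for `method = "t"`
#' (the small-sample construction used by common plotting tools), or
#' \eqn{\chi^2_{level}(2)} for `method = "normal"` (the large-sample
#' Gaussian ellipse). A point `x` is inside iff
#' `(x - center)' shape^{-1} (x - center) <= radius2`.
#'
#' @param scores n x 2 matrix of PC scores, n >= 3.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param method `"t"` (default) or `"normal"`.
#' @return An object of class `confidence_ellipse`: `center`, `shape`,
#'   `radius2`, `level`, `method`, `n`.
#' @export
confidence_ellipse <- function(scores, level = 0.95,
                               method = c("t", "normal")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2L, level > 0, level < 1)
  n <- nrow(scores)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  center <- colMeans(scores)
  shape <- stats::cov(scores)
  if (!is.finite(determinant(shape)$modulus) ||
      det(shape) <= .Machine$double.eps * max(diag(shape))^2)
    stop("degenerate covariance: points are (nearly) collinear",
         call. = FALSE)
  radius2 <- switch(method,
    t = 2 * (n - 1) / (n - 2) * stats::qf(level, 2, n - 2),
    normal = stats::qchisq(level, 2))
  structure(list(center = center, shape = shape, radius2 = radius2,
                 level = level, method = method, n = n),
            class = "confidence_ellipse")
}

#' Test point membership in a confidence ellipse
#'
#' Exact membership via the quadratic form: inside iff the squared
#' Mahalanobis distance to the centre is at most `radius2`.
#'
#' @param ellipse A [confidence_ellipse()].
#' @param points n x 2 matrix.
#' @return Logical vector of length n.
#' @export
ellipse_contains <- function(ellipse, points) {
  stopifnot(inherits(ellipse, "confidence_ellipse"))
  points <- matrix(as.numeric(points), ncol = 2L)
  stats::mahalanobis(points, ellipse$center, ellipse$shape) <= ellipse$radius2
}

#' Boundary polygon of a confidence ellipse (for plotting)
#'
#' @param ellipse A [confidence_ellipse()].
#' @param n_points Number of boundary vertices.
#' @return n x 2 matrix tracing the ellipse boundary.
#' @export
ellipse_boundary <- function(ellipse, n_points = 181L) {
  e <- eigen(ellipse$shape, symmetric = TRUE)
  theta <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(cos(theta), sin(theta))
  axes <- e$vectors %*% diag(sqrt(pmax(e$values, 0) * ellipse$radius2))
  sweep(circ %*% t(axes), 2L, ellipse$center, `+`)
}

#' @export
print.confidence_ellipse <- function(x, ...) {
  cat(sprintf("%g%% confidence ellipse (method=%s, n=%d)\n",
              100 * x$level, x$method, x$n))
  cat("  center: (", paste(sprintf("%.3f", x$center), collapse = ", "),
      ")  radius^2:", sprintf("%.3f", x$radius2), "\n")
  invisible(x)
}

#' Concordance of two treatments' confidence ellipses
#'
#' The fraction of cells (pooled over both treatments) lying inside both
#' treatments' confidence ellipses, among cells lying inside either.
#' Symmetric in the two treatments; 0 when no cell falls in either ellipse
#' (with a warning).
#'
#' @param ellipse_a,ellipse_b Ellipses fitted to `scores_a` / `scores_b`.
#' @param scores_a,scores_b PC1-PC2 scores of the two treatments.
#' @param treatment_a,treatment_b Labels carried into the result.
#' @return An object of class `bcp_concordance`: `treatment_a`,
#'   `treatment_b`, `n_both`, `n_either`, `proportion`,
#'   `n_cells_per_treatment`.
#' @export
concordance <- function(ellipse_a, ellipse_b, scores_a, scores_b,
                        treatment_a = "A", treatment_b = "B") {
  all_scores <- rbind(as.matrix(scores_a), as.matrix(scores_b))
  in_a <- ellipse_contains(ellipse_a, all_scores)
  in_b <- ellipse_contains(ellipse_b, all_scores)
  n_both <- sum(in_a & in_b)
  n_either <- sum(in_a | in_b)
  if (n_either == 0L)
    warning("no cell falls inside either ellipse; concordance set to 0",
            call. = FALSE)
  structure(list(treatment_a = treatment_a, treatment_b = treatment_b,
                 n_both = n_both, n_either = n_either,
                 proportion = if (n_either) n_both / n_either else 0,
                 n_cells_per_treatment = c(nrow(as.matrix(scores_a)),
                                           nrow(as.matrix(scores_b)))),
            class = "bcp_concordance")
}

#' @export
print.bcp_concordance <- function(x, ...) {
  cat(sprintf("Concordance %s vs %s: %d/%d = %.3f\n", x$treatment_a,
              x$treatment_b, x$n_both, x$n_either, x$proportion))
  invisible(x)
}

# One (query, reference) pipeline run: balanced subsample of the combined
# pair, pairwise PCA, per-treatment ellipses, concordance.
pair_concordance <- function(query, reference, level, method, seed,
                             subsample_n = "auto") {
  qtr <- unique(query$treatment)[1L]
  rtr <- unique(reference$treatment)[1L]
  if (identical(qtr, rtr))
    stop("query and reference must carry distinct treatment labels",
         call. = FALSE)
  combined <- rbind(query, reference)
  combined$cell_id <- paste0(combined$treatment, "#", combined$cell_id)
  sub <- balanced_subsample(combined, n = subsample_n, seed = seed)
  qs <- sub[sub$treatment == qtr, , drop = FALSE]
  rs <- sub[sub$treatment == rtr, , drop = FALSE]
  pca <- fit_pairwise_pca(qs, rs)
  ea <- confidence_ellipse(pca$scores_a, level = level, method = method)
  eb <- confidence_ellipse(pca$scores_b, level = level, method = method)
  res <- concordance(ea, eb, pca$scores_a, pca$scores_b,
                     treatment_a = qtr, treatment_b = rtr)
  res$pca <- pca; res$ellipse_a <- ea; res$ellipse_b <- eb
  res$seed <- seed
  res
}

#' Rank reference antibiotics by concordance with a query treatment
#'
#' The package's main fit: for every reference, subsamples the
#' query/reference pair to balanced per-treatment counts, fits the
#' pairwise PCA, builds each treatment's confidence ellipse in PC1-PC2 and
#' computes the concordance statistic; references are returned sorted by
#' descending concordance. References with high concordance are the
#' mechanism-of-action neighbours of the query.
#'
#' @param query Feature table of the query treatment (QC'd, complete).
#' @param references Named list of reference feature tables. Names default
#'   to each table's treatment label.
#' @param level Ellipse confidence level; default 0.95.
#' @param method Ellipse method, `"t"` (default) or `"normal"`.
#' @param seed Integer master seed; each pair's subsample uses a seed
#'   derived deterministically from it.
#' @param subsample_n Per-treatment cell count for each pair
#'   (`"auto"` = the pair's minimum count).
#' @return An object of class `bcp_ranking`: a list with `results` (list
#'   of `bcp_concordance`, best first), `table` (data frame: pair, n_both,
#'   n_either, proportion, rank) and provenance (`level`, `method`,
#'   `seed`, `subsample_n`).
#' @examples
#' specs <- list(treatment_spec("query", 60, rep(0, 5), diag(5)),
#'               treatment_spec("refA", 60, rep(0, 5), diag(5)),
#'               treatment_spec("refB", 60, rep(2, 5), diag(5)))
#' tab <- gen_feature_table(specs, paste0("p", 1:5), seed = 1)
#' split_tabs <- split(tab, tab$treatment)
#' rk <- rank_references(split_tabs$query,
#'                       split_tabs[c("refA", "refB")], seed = 1)
#' rk
#' @export
rank_references <- function(query, references, level = 0.95,
                            method = c("t", "normal"), seed = 1,
                            subsample_n = "auto") {
  method <- match.arg(method)
  check_feature_table(query, require_complete = TRUE)
  stopifnot(is.list(references))
  if (length(references) == 0L) {
    return(structure(list(results = list(),
                          table = data.frame(pair = character(0L),
                                             n_both = integer(0L),
                                             n_either = integer(0L),
                                             proportion = numeric(0L),
                                             rank = integer(0L)),
                          level = level, method = method, seed = seed,
                          subsample_n = subsample_n),
                     class = "bcp_ranking"))
  }
  if (is.null(names(references)))
    names(references) <- vapply(references,
                                function(r) unique(r$treatment)[1L],
                                character(1L))
  results <- vector("list", length(references))
  for (i in seq_along(references)) {
    check_feature_table(references[[i]], require_complete = TRUE)
    results[[i]] <- pair_concordance(query, references[[i]], level = level,
                                     method = method,
                                     seed = child_seed(seed, i),
                                     subsample_n = subsample_n)
  }
  names(results) <- names(references)
  ord <- order(vapply(results, function(r) r$proportion, numeric(1L)),
               decreasing = TRUE)
  results <- results[ord]
  tab <- data.frame(
    pair = vapply(results, function(r)
      paste(r$treatment_a, r$treatment_b, sep = " vs "), character(1L)),
    reference = names(results),
    n_both = vapply(results, function(r) r$n_both, integer(1L)),
    n_either = vapply(results, function(r) r$n_either, integer(1L)),
    proportion = vapply(results, function(r) r$proportion, numeric(1L)),
    rank = seq_along(results), row.names = NULL)
  structure(list(results = results, table = tab, level = level,
                 method = method, seed = seed, subsample_n = subsample_n),
            class = "bcp_ranking")
}

#' @export
print.bcp_ranking <- function(x, digits = 3, ...) {
  cat("Bacterial cytological profiling: concordance ranking\n")
  cat(sprintf("  %d reference(s); %g%% %s-ellipses; seed %s\n",
              nrow(x$table), 100 * x$level, x$method,
              format(x$seed)))
  if (nrow(x$table)) {
    tab <- x$table
    tab$proportion <- round(tab$proportion, digits)
    print(tab[c("rank", "reference", "n_both", "n_either", "proportion")],
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.bcp_ranking <- function(object, ...) {
  cat("Concordance ranking of", nrow(object$table), "reference treatments\n")
  print(object)
  if (nrow(object$table)) {
    best <- object$results[[1L]]
    cat(sprintf("Top match: %s (concordance %.3f, %d/%d cells)\n",
                best$treatment_b, best$proportion, best$n_both,
                best$n_either))
    ev <- best$pca$model$explained_variance
    cat(sprintf("Top pair PC1/PC2 variance explained: %.1f%% / %.1f%%\n",
                100 * ev[1L] / sum(ev), 100 * ev[2L] / sum(ev)))
  }
  invisible(object)
}

#' Plot a concordance ranking
#'
#' Left panel: barplot of concordance by reference. Right panel (optional,
#' `which_pair`): PC1-PC2 scores and both confidence ellipses for one
#' query/reference pair.
#'
#' @param x A `bcp_ranking`.
#' @param which_pair Reference name or rank index for the score panel;
#'   `NULL` for the barplot only.
#' @param ... Passed to [graphics::barplot].
#' @export
plot.bcp_ranking <- function(x, which_pair = 1L, ...) {
  if (nrow(x$table) == 0L) stop("empty ranking", call. = FALSE)
  op <- graphics::par(mfrow = if (is.null(which_pair)) c(1, 1) else c(1, 2),
                      mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$table$proportion, names.arg = x$table$reference,
                    las = 2, ylab = "Proportion of concordance",
                    ylim = c(0, 1), ...)
  if (!is.null(which_pair)) {
    r <- if (is.character(which_pair)) x$results[[which_pair]]
         else x$results[[as.integer(which_pair)]]
    sa <- r$pca$scores_a; sb <- r$pca$scores_b
    ba <- ellipse_boundary(r$ellipse_a); bb <- ellipse_boundary(r$ellipse_b)
    xl <- range(sa[, 1L], sb[, 1L], ba[, 1L], bb[, 1L])
    yl <- range(sa[, 2L], sb[, 2L], ba[, 2L], bb[, 2L])
    graphics::plot(sa, col = "#2166ac55", pch = 16, cex = 0.5,
                   xlim = xl, ylim = yl, xlab = "PC1", ylab = "PC2",
                   main = paste(r$treatment_a, "vs", r$treatment_b))
    graphics::points(sb, col = "#b2182b55", pch = 16, cex = 0.5)
    graphics::lines(ba, col = "#2166ac", lwd = 2)
    graphics::lines(bb, col = "#b2182b", lwd = 2)
  }
  invisible(x)
}
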