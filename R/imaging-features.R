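# Cell segmentation and per-cell feature extraction.
#
# The front end mirrors a standard BCP imaging workflow: cells are found on
# the membrane-stain channel (automatic threshold, 8-connected components),
# optionally expanded under guidance of the phase image, filtered for
# border contact, then gated on nucleoid presence in the DNA channel.
# Intensity features are measured only on channels flagged non-deconvolved.

#' Construct a multi-channel image scene
#'
#' @param channels Named list of 2-D numeric matrices sharing one shape;
#'   recognized names are `membrane`, `dna`, `permeability` and (optional)
#'   `phase`.
#' @param pixel_size Physical pixel size in um/px (metadata only).
#' @param deconvolved Named logical vector flagging channels that hold
#'   deconvolved data; intensity features are refused on those. Defaults to
#'   all `FALSE`.
#' @return An object of class `image_scene`.
#' @export
image_scene <- function(channels, pixel_size = 1,
                        deconvolved = NULL) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  if (!all(vapply(channels, is.matrix, logical(1L))) ||
      length(unique(vapply(dims, paste, character(1L), collapse = "x"))) != 1L)
    stop("all channels must be matrices of one shape", call. = FALSE)
  for (ch in names(channels)) {
    v <- channels[[ch]]
    if (!all(is.finite(v)) || any(v < 0))
      stop("channel ", sQuote(ch), " has non-finite or negative pixels",
           call. = FALSE)
  }
  if (is.null(deconvolved))
    deconvolved <- stats::setNames(rep(FALSE, length(channels)),
                                   names(channels))
  structure(list(channels = channels, pixel_size = pixel_size,
                 deconvolved = deconvolved),
            class = "image_scene")
}

#' @export
print.image_scene <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat("Image scene:", d[1L], "x", d[2L], "px;",
      length(x$channels), "channel(s):",
      paste(names(x$channels), collapse = ", "), "\n")
  if (!is.null(x$truth))
    cat("Synthetic ground truth:", length(x$truth$cells), "cell(s)\n")
  invisible(x)
}

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
# touch only diagonally are merged afterwards with union-find.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]   # down-right diagonal
  a2 <- lab[-1L, -nc]; b2 <- lab[-nr, -1L]   # up-right diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- unique(pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                          pairs[, 1L] != pairs[, 2L], , drop = FALSE])
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1L))
  relabel <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relabel[lab[lab > 0L]]
  out
}

# Pixel coordinates (0-based rows/cols) of a label.
label_pixels <- function(lab, l) {
  idx <- which(lab == l)
  nr <- nrow(lab)
  cbind(row = (idx - 1L) %% nr, col = (idx - 1L) %/% nr)
}

# Normalized second moments (per unit area) of an ideal capsule with axis
# segment length a and cap radius r: along-axis and across-axis variances.
capsule_moments <- function(a, r) {
  W <- 2 * r
  A <- a * W + pi * r^2
  sxx <- W * a^3 / 12 +
    2 * ((a^2 / 8) * pi * r^2 + (2 / 3) * a * r^3 + pi * r^4 / 8)
  syy <- a * W^3 / 12 + pi * r^4 / 4
  c(along = sxx / A, across = syy / A)
}

# Invert the capsule moment equations: find the (length, width) of the
# spherocylinder whose second moments match (l1 >= l2). The moment ratio
# depends only on the aspect a/r (monotone), so a 1-D root solve fixes the
# shape and the across-axis moment fixes the scale. Exact for capsule
# masks; for other shapes it reports the moment-equivalent capsule.
capsule_axes <- function(l1, l2) {
  if (l2 <= 0) return(c(length = 4 * sqrt(max(l1, 0)), width = 0))
  ratio <- l1 / l2
  g <- function(q) { m <- capsule_moments(q, 1); m[["along"]] / m[["across"]] - ratio }
  if (ratio <= 1) q <- 0                      # disk
  else {
    hi <- 4
    while (g(hi) < 0 && hi < 1e6) hi <- hi * 2
    q <- stats::uniroot(g, c(0, hi), tol = 1e-10)$root
  }
  r <- sqrt(l2 / capsule_moments(q, 1)[["across"]])
  c(length = q * r + 2 * r, width = 2 * r)
}

# Shape summaries from a pixel set (0-based coords). Major/minor axis
# lengths are the tip-to-tip length and width of the moment-equivalent
# spherocylinder (the natural convention for rod-shaped bacteria);
# eccentricity uses the usual ellipse-moment definition.
shape_stats <- function(px) {
  n <- nrow(px)
  centroid <- colMeans(px)
  if (n > 1L) {
    cv <- stats::cov(px) * (n - 1) / n      # population moments
    cv <- cv + diag(1 / 12, 2L)             # finite pixel extent
    e <- eigen(cv, symmetric = TRUE)
    l1 <- max(e$values); l2 <- max(min(e$values), 0)
    ax <- capsule_axes(l1, l2)
    v <- e$vectors[, 1L]                    # (row, col) major-axis direction
    orientation <- atan2(v[1L], v[2L])
    if (orientation < -pi / 2) orientation <- orientation + pi
    if (orientation > pi / 2) orientation <- orientation - pi
    ecc <- if (l1 > 0) sqrt(max(1 - l2 / l1, 0)) else 0
    major <- unname(ax["length"]); minor <- unname(ax["width"])
  } else {
    major <- minor <- 1; orientation <- 0; ecc <- 0
  }
  list(centroid = centroid, area = n, major_axis = major,
       minor_axis = minor, eccentricity = ecc, orientation = orientation)
}

# Crack-length perimeter: number of pixel edges facing background.
mask_perimeter <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  sum(core & !pad[1:nr, 2:(nc + 1L)]) + sum(core & !pad[3:(nr + 2L), 2:(nc + 1L)]) +
    sum(core & !pad[2:(nr + 1L), 1:nc]) + sum(core & !pad[2:(nr + 1L), 3:(nc + 2L)])
}

# Convex hull area of pixel centres (shoelace), padded by 0.5 px border to
# approximate pixel extent; returns >= area so solidity <= 1.
hull_area <- function(px) {
  if (nrow(px) < 3L) return(nrow(px))
  h <- grDevices::chull(px[, 2L], px[, 1L])
  x <- px[h, 2L]; y <- px[h, 1L]
  a <- abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
  # add the half-pixel rim around the hull polygon
  per <- sum(sqrt(diff(c(x, x[1L]))^2 + diff(c(y, y[1L]))^2))
  a + 0.5 * per + pi * 0.25
}

# Feret diameters from hull vertices: max pairwise distance, and the
# minimal projection width over hull edge directions (rotating calipers).
feret_diameters <- function(px) {
  pts <- if (nrow(px) > 2L) px[grDevices::chull(px[, 2L], px[, 1L]), , drop = FALSE]
         else px
  n <- nrow(pts)
  if (n == 1L) return(c(max = 1, min = 1))
  d <- as.matrix(stats::dist(pts))
  fmax <- max(d) + 1                     # + pixel extent
  if (n == 2L) return(c(max = fmax, min = 1))
  fmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- pts[j, ] - pts[i, ]
    len <- sqrt(sum(e^2)); if (len == 0) next
    nvec <- c(-e[2L], e[1L]) / len
    w <- diff(range(pts %*% nvec))
    fmin <- min(fmin, w)
  }
  c(max = fmax, min = fmin + 1)
}

#' Segment cells on the membrane channel
#'
#' Foreground is found by automatic (Otsu) thresholding of the membrane
#' channel; 8-connected components become cell objects. When a phase
#' channel is present, each object is grown outward by up to `expansion_px`
#' one-pixel rings, accepting only pixels whose phase intensity lies within
#' 3 SD of the object's interior phase statistics (the phase image guides
#' the expansion); without a phase channel the dilation is unconstrained.
#' Objects touching the image border and objects smaller than `min_area`
#' are discarded.
#'
#' @param scene An [image_scene()] with a `membrane` channel.
#' @param threshold_method Currently `"otsu"`.
#' @param expansion_px Maximum expansion distance in pixels.
#' @param min_area Minimum object area in px^2.
#' @return List of `cell_object`s: each has `label`, `pixels` (0-based
#'   row/col matrix), `centroid`, `area`, `major_axis`, `minor_axis`,
#'   `eccentricity`, `orientation`, `perimeter` and (initially empty)
#'   `nucleoids`.
#' @export
segment_cells <- function(scene, threshold_method = "otsu",
                          expansion_px = 0L, min_area = 5L) {
  stopifnot(inherits(scene, "image_scene"))
  if (is.null(scene$channels$membrane))
    stop("scene has no membrane channel", call. = FALSE)
  threshold_method <- match.arg(threshold_method, "otsu")
  img <- scene$channels$membrane
  rng <- range(img)
  if (diff(rng) <= 0) return(list())       # flat image: nothing to segment
  norm <- (img - rng[1L]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  if (!any(mask)) return(list())
  lab <- label_components(mask)
  nr <- nrow(img); nc <- ncol(img)
  phase <- scene$channels$phase
  cells <- list()
  for (l in seq_len(max(lab))) {
    obj <- lab == l
    if (sum(obj) < min_area) next
    if (expansion_px > 0L)
      obj <- expand_object(obj, lab != 0L & !obj, phase, expansion_px)
    px <- which(obj, arr.ind = TRUE) - 1L
    if (any(px[, 1L] == 0L) || any(px[, 1L] == nr - 1L) ||
        any(px[, 2L] == 0L) || any(px[, 2L] == nc - 1L)) next  # border
    ss <- shape_stats(px)
    cells[[length(cells) + 1L]] <- structure(
      c(list(label = length(cells) + 1L, pixels = px, mask = obj,
             perimeter = mask_perimeter(obj), nucleoids = integer(0L)), ss),
      class = "cell_object")
  }
  cells
}

# Grow `obj` by up to `k` one-pixel 8-neighbour rings, never into other
# objects; with a phase image, only into pixels whose phase value is within
# 3 SD of the object's interior phase mean.
expand_object <- function(obj, forbidden, phase, k) {
  nr <- nrow(obj); nc <- ncol(obj)
  if (!is.null(phase)) {
    inside <- phase[obj]
    mu <- mean(inside); sd0 <- stats::sd(inside)
    if (!is.finite(sd0) || sd0 == 0) sd0 <- max(abs(mu), 1) * 0.05
    ok <- abs(phase - mu) <= 3 * sd0
  } else ok <- matrix(TRUE, nr, nc)
  brush <- EBImage::makeBrush(3L, "box")
  for (i in seq_len(k)) {
    grown <- EBImage::dilate(EBImage::Image(obj * 1), brush) > 0
    cand <- grown & !obj & !forbidden & ok
    if (!any(cand)) break
    obj <- obj | cand
  }
  obj
}

#' Detect nucleoids and associate them with cells
#'
#' Connected components of the thresholded DNA channel; each nucleoid is
#' assigned to the cell whose mask contains its centroid (rounded to the
#' nearest pixel), or left unassigned.
#'
#' @param scene An [image_scene()] with a `dna` channel.
#' @param cells Cell list from [segment_cells()].
#' @return List of `nucleoid_object`s: `label`, `pixels`, `centroid`,
#'   `area`, `parent` (cell label or `NA`).
#' @export
detect_nucleoids <- function(scene, cells) {
  stopifnot(inherits(scene, "image_scene"))
  img <- scene$channels$dna
  if (is.null(img)) stop("scene has no dna channel", call. = FALSE)
  rng <- range(img)
  if (diff(rng) <= 0) return(list())
  norm <- (img - rng[1L]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  lab <- label_components(norm > thr)
  out <- list()
  for (l in seq_len(max(lab))) {
    px <- label_pixels(lab, l)
    centroid <- colMeans(px)
    cpix <- round(centroid)
    parent <- NA_integer_
    for (cell in cells) {
      r <- cpix[1L] + 1L; c <- cpix[2L] + 1L
      if (r >= 1L && r <= nrow(cell$mask) && c >= 1L && c <= ncol(cell$mask) &&
          cell$mask[r, c]) { parent <- cell$label; break }
    }
    out[[length(out) + 1L]] <- structure(
      list(label = l, pixels = px, centroid = centroid, area = nrow(px),
           parent = parent),
      class = "nucleoid_object")
  }
  out
}

#' Keep only cells with at least one associated nucleoid
#'
#' The DNA-presence gate: cells without DNA-stain fluorescence are excluded
#' from downstream profiling.
#'
#' @param cells Cell list from [segment_cells()].
#' @param nucleoids Nucleoid list from [detect_nucleoids()].
#' @return Filtered cell list, each with its `nucleoids` field filled in.
#' @export
filter_cells_by_nucleoid <- function(cells, nucleoids) {
  parents <- vapply(nucleoids, function(n) n$parent, integer(1L))
  keep <- list()
  for (cell in cells) {
    linked <- which(parents == cell$label)
    if (length(linked)) {
      cell$nucleoids <- vapply(nucleoids[linked], function(n) n$label,
                               integer(1L))
      keep[[length(keep) + 1L]] <- cell
    }
  }
  keep
}
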