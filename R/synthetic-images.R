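# Synthetic rod-cell image scenes. Cells are capsules (spherocylinders):
# a rectangle with semicircular caps, the idealized footprint of a rod-
# shaped bacterium such as B. subtilis. Each scene carries its ground truth
# so segmentation and feature extraction can be tested against it.
#
# Pixel convention: 0-based (row, col), origin top-left; geometry is
# evaluated at integer pixel centres, i.e. pixel (0, 0) is the point (0, 0).

#' Ground truth for one synthetic cell
#'
#' @param center Numeric length-2 vector `(row, col)`, 0-based pixel
#'   coordinates of the capsule centre.
#' @param length_px Total capsule length (tip to tip) in pixels.
#' @param width_px Capsule width (diameter of the caps) in pixels; must not
#'   exceed `length_px`.
#' @param orientation Angle of the long axis in radians, measured from the
#'   column (x) axis toward the row (y) axis.
#' @param channel_intensities Named nonnegative vector of per-channel
#'   intensities, e.g. `c(membrane = 100, dna = 80, permeability = 5)`.
#' @param has_nucleoid Logical; if `FALSE` the DNA channel is not rendered
#'   for this cell.
#' @return An object of class `cell_truth`.
#' @export
cell_truth <- function(center, length_px, width_px, orientation = 0,
                       channel_intensities = c(membrane = 100, dna = 80,
                                               permeability = 5),
                       has_nucleoid = TRUE) {
  stopifnot(length(center) == 2L, is.finite(center),
            length_px >= width_px, width_px > 0,
            is.finite(channel_intensities), all(channel_intensities >= 0),
            !is.null(names(channel_intensities)),
            is.logical(has_nucleoid), length(has_nucleoid) == 1L)
  structure(list(center = as.numeric(center), length_px = length_px,
                 width_px = width_px, orientation = orientation,
                 channel_intensities = channel_intensities,
                 has_nucleoid = has_nucleoid),
            class = "cell_truth")
}

# Distance from pixel centres to the capsule's axis segment; the footprint
# is all pixels within width/2 of the segment. `shrink` scales the capsule
# (used for the nucleoid region).
capsule_mask <- function(cell, image_shape, shrink = 1) {
  nr <- image_shape[1L]; nc <- image_shape[2L]
  len <- cell$length_px * shrink
  wid <- cell$width_px * shrink
  h <- max((len - wid) / 2, 0)           # half-length of the axis segment
  dx <- cos(cell$orientation)            # col direction
  dy <- sin(cell$orientation)            # row direction
  rows <- matrix(rep(0:(nr - 1L), nc), nrow = nr)
  cols <- matrix(rep(0:(nc - 1L), each = nr), nrow = nr)
  py <- rows - cell$center[1L]
  px <- cols - cell$center[2L]
  t <- pmin(pmax(px * dx + py * dy, -h), h)  # clamp to segment
  d2 <- (px - t * dx)^2 + (py - t * dy)^2
  # small tolerance keeps boundary pixels stable under rotation round-off
  d2 <= (wid / 2)^2 + 1e-9
}

# Tip-to-tip extent of the capsule, to reject cells leaving the frame.
capsule_extent <- function(cell) {
  h <- max((cell$length_px - cell$width_px) / 2, 0)
  r <- cell$width_px / 2
  dx <- cos(cell$orientation); dy <- sin(cell$orientation)
  rows <- cell$center[1L] + c(-1, 1) * (abs(h * dy) + r)
  cols <- cell$center[2L] + c(-1, 1) * (abs(h * dx) + r)
  list(rows = rows, cols = cols)
}

#' Render a synthetic multi-channel scene of capsule cells
#'
#' Renders each cell as an oriented capsule of uniform per-channel
#' intensity added onto a constant background, plus optional Gaussian
#' noise. The DNA channel is rendered only for cells with a nucleoid, over
#' a centred sub-capsule (60% of the cell's length and width). Overlapping
#' cells are allowed (intensities add) but flagged; cells extending beyond
#' the frame are rejected.
#'
#' @param cells List of [cell_truth()] objects (may be empty).
#' @param image_shape Integer `(rows, cols)` of every channel.
#' @param background Constant background level added to every channel.
#' @param noise_sd SD of i.i.d. Gaussian noise added per pixel (0 = none).
#' @param channels Channel names to render; `dna` gets the nucleoid
#'   treatment, all others use the cell's full footprint.
#' @param seed Integer seed for the noise.
#' @return An `image_scene` (see [image_scene()]) whose `truth` field keeps
#'   the cell list, the per-cell footprint masks and an `overlap` flag.
#' @export
gen_image_scene <- function(cells, image_shape = c(128L, 128L),
                            background = 0, noise_sd = 0,
                            channels = c("membrane", "dna", "permeability"),
                            seed = 1) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 4),
            background >= 0, noise_sd >= 0)
  nr <- as.integer(image_shape[1L]); nc <- as.integer(image_shape[2L])
  for (cell in cells) {
    stopifnot(inherits(cell, "cell_truth"))
    ext <- capsule_extent(cell)
    if (ext$rows[1L] < 0 || ext$rows[2L] > nr - 1L ||
        ext$cols[1L] < 0 || ext$cols[2L] > nc - 1L)
      stop("cell extends beyond the image frame", call. = FALSE)
  }
  imgs <- stats::setNames(
    replicate(length(channels), matrix(background, nr, nc), simplify = FALSE),
    channels)
  masks <- vector("list", length(cells))
  cover <- matrix(0L, nr, nc)
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    mask <- capsule_mask(cell, c(nr, nc))
    masks[[i]] <- mask
    cover <- cover + mask
    for (ch in channels) {
      inten <- cell$channel_intensities[ch]
      if (is.na(inten) || inten == 0) next
      if (ch == "dna") {
        if (!cell$has_nucleoid) next
        nm <- capsule_mask(cell, c(nr, nc), shrink = 0.6)
        imgs[[ch]][nm] <- imgs[[ch]][nm] + inten
      } else {
        imgs[[ch]][mask] <- imgs[[ch]][mask] + inten
      }
    }
  }
  overlap <- any(cover > 1L)
  if (overlap) warning("scene contains overlapping cells", call. = FALSE)
  if (noise_sd > 0) {
    imgs <- with_seed(seed, lapply(imgs, function(img)
      pmax(img + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 0)))
  }
  scene <- image_scene(imgs)
  scene$truth <- list(cells = cells, masks = masks, overlap = overlap)
  scene
}
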