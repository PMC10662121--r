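# Per-cell feature extraction against a configurable parameter registry.
#
# The default registry emits 39 parameters: 12 shape descriptors plus 9
# intensity statistics on each of the three fluorescence channels
# (membrane, dna, permeability). The exact parameter list is configurable;
# the default is a reconstruction of a standard CellProfiler-style BCP
# measurement set, and the count of 39 -- not the identity of each entry --
# is the stable contract. Intensity statistics are only computed on
# channels flagged non-deconvolved.

SHAPE_FEATURES <- c("area", "perimeter", "major_axis", "minor_axis",
                    "eccentricity", "orientation", "solidity", "form_factor",
                    "compactness", "extent", "feret_max", "feret_min")

INTENSITY_STATS <- c("mean", "median", "sd", "min", "max", "integrated",
                     "q1", "q3", "mass_displacement")

#' Default per-cell parameter registry
#'
#' @param channels Fluorescence channels to measure intensity statistics
#'   on; with the default three channels the registry has
#'   `12 + 9 * 3 = 39` entries.
#' @return Data frame with columns `name`, `kind` (`"shape"` or
#'   `"intensity"`), `channel` (`NA` for shape) and `stat`.
#' @export
default_parameter_registry <- function(channels = c("membrane", "dna",
                                                    "permeability")) {
  shape <- data.frame(name = SHAPE_FEATURES, kind = "shape",
                      channel = NA_character_, stat = SHAPE_FEATURES,
                      stringsAsFactors = FALSE)
  inten <- expand.grid(stat = INTENSITY_STATS, channel = channels,
                       stringsAsFactors = FALSE)
  inten <- data.frame(name = paste(inten$channel, inten$stat, sep = "_"),
                      kind = "intensity", channel = inten$channel,
                      stat = inten$stat, stringsAsFactors = FALSE)
  rbind(shape, inten)
}

shape_feature_values <- function(cell) {
  px <- cell$pixels
  area <- cell$area
  perim <- cell$perimeter
  hull <- hull_area(px)
  fer <- feret_diameters(px)
  bbox <- (diff(range(px[, 1L])) + 1) * (diff(range(px[, 2L])) + 1)
  c(area = area,
    perimeter = perim,
    major_axis = cell$major_axis,
    minor_axis = cell$minor_axis,
    eccentricity = cell$eccentricity,
    orientation = cell$orientation,
    solidity = min(area / hull, 1),
    form_factor = 4 * pi * area / perim^2,
    compactness = perim^2 / (4 * pi * area),
    extent = area / bbox,
    feret_max = unname(fer["max"]),
    feret_min = unname(fer["min"]))
}

intensity_feature_values <- function(cell, img) {
  v <- img[cell$pixels + 1L]
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  total <- sum(v)
  md <- if (total > 0) {
    wc <- colSums(cell$pixels * v) / total
    sqrt(sum((wc - cell$centroid)^2))
  } else 0
  c(mean = mean(v), median = q[2L],
    sd = if (length(v) > 1L) stats::sd(v) else 0,
    min = min(v), max = max(v), integrated = total,
    q1 = q[1L], q3 = q[3L], mass_displacement = md)
}

#' Extract per-cell features from a scene
#'
#' Computes every parameter in the registry for every (nucleoid-filtered)
#' cell: shape descriptors from the cell mask, intensity statistics from
#' the named channel restricted to the mask. Intensity parameters are
#' refused on channels flagged deconvolved (fluorescence quantification
#' must use raw data) and on absent channels. The scene is never modified.
#'
#' @param scene An [image_scene()].
#' @param cells Cell list, typically from [filter_cells_by_nucleoid()].
#' @param parameter_set Registry data frame as produced by
#'   [default_parameter_registry()] (the default).
#' @param treatment,replicate Metadata labels stamped onto every row.
#' @return A feature table (`cell_id`, `treatment`, `replicate`, then one
#'   numeric column per registry entry).
#' @export
extract_features <- function(scene, cells,
                             parameter_set = default_parameter_registry(),
                             treatment = "unknown", replicate = "rep1") {
  stopifnot(inherits(scene, "image_scene"), is.data.frame(parameter_set),
            all(c("name", "kind", "channel", "stat") %in% names(parameter_set)))
  needed <- unique(parameter_set$channel[parameter_set$kind == "intensity"])
  for (ch in needed) {
    if (is.null(scene$channels[[ch]]))
      stop("intensity parameter requested for absent channel ", sQuote(ch),
           call. = FALSE)
    if (isTRUE(scene$deconvolved[[ch]]))
      stop("intensity parameter requested for deconvolved channel ",
           sQuote(ch), "; use non-deconvolved data", call. = FALSE)
  }
  rows <- lapply(cells, function(cell) {
    sh <- shape_feature_values(cell)
    ints <- lapply(needed, function(ch)
      intensity_feature_values(cell, scene$channels[[ch]]))
    names(ints) <- needed
    vals <- vapply(seq_len(nrow(parameter_set)), function(i) {
      p <- parameter_set[i, ]
      if (p$kind == "shape") sh[[p$stat]] else ints[[p$channel]][[p$stat]]
    }, numeric(1L))
    stats::setNames(vals, parameter_set$name)
  })
  mat <- do.call(rbind, rows)
  out <- data.frame(cell_id = paste0(treatment, "_", replicate, "_",
                                     seq_along(cells)),
                    treatment = treatment, replicate = replicate,
                    stringsAsFactors = FALSE)
  if (length(cells) == 0L) {
    out <- out[0L, , drop = FALSE]
    mat <- matrix(numeric(0L), 0L, nrow(parameter_set),
                  dimnames = list(NULL, parameter_set$name))
  }
  cbind(out, as.data.frame(mat, optional = TRUE))
}
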