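# Segmentation, nucleoid gating and feature extraction against synthetic
# ground truth.

test_that("segmentation recovers non-overlapping capsules exactly at zero noise", {
  sc <- make_scene()
  cells <- segment_cells(sc)
  expect_length(cells, 3L)
  truth_masks <- lapply(sc$truth$cells, function(cell)
    oracle_capsule_mask(cell$center, cell$length_px, cell$width_px,
                        cell$orientation, c(128L, 128L)))
  # match each segmented cell to the truth mask containing its centroid
  for (cell in cells) {
    hit <- which(vapply(truth_masks, function(m)
      m[round(cell$centroid[1L]) + 1L, round(cell$centroid[2L]) + 1L],
      logical(1L)))
    expect_length(hit, 1L)
    expect_identical(unname(cell$mask), unname(truth_masks[[hit]]))
  }
})

test_that("blank scenes yield no cells and a missing membrane channel errors", {
  blank <- image_scene(list(membrane = matrix(0, 32, 32),
                            dna = matrix(0, 32, 32)))
  expect_length(segment_cells(blank), 0L)
  no_mem <- image_scene(list(dna = matrix(0, 32, 32)))
  expect_error(segment_cells(no_mem), "membrane")
})

test_that("cells touching the image border are discarded", {
  # capsule ending exactly on the last row survives the frame check but
  # touches the border, so segmentation must drop it
  edge <- cell_truth(c(26, 16), 10, 6, pi / 2)
  inner <- cell_truth(c(15.5, 15.5), 12, 6, 0)
  sc <- gen_image_scene(list(edge, inner), c(32L, 32L))
  cells <- segment_cells(sc)
  expect_length(cells, 1L)
  expect_lt(abs(cells[[1L]]$centroid[1L] - 15.5), 1)
})

test_that("nucleoids are detected and associated by centroid containment", {
  sc <- make_scene()
  cells <- segment_cells(sc)
  nucs <- detect_nucleoids(sc, cells)
  expect_length(nucs, 2L)   # third truth cell has no nucleoid
  parents <- vapply(nucs, function(n) n$parent, integer(1L))
  expect_true(all(!is.na(parents)))
  # each nucleoid lies inside its parent cell's mask
  for (n in nucs) {
    parent <- cells[[n$parent]]
    expect_true(all(parent$mask[n$pixels + 1L]))
  }
  # blank DNA channel: no nucleoids
  sc0 <- image_scene(list(membrane = sc$channels$membrane,
                          dna = matrix(0, 128, 128)))
  expect_length(detect_nucleoids(sc0, cells), 0L)
})

test_that("a DNA spot outside every cell gets no parent", {
  cell <- cell_truth(c(15.5, 15.5), 12, 6, 0,
                     c(membrane = 100, dna = 0, permeability = 0))
  sc <- gen_image_scene(list(cell), c(48L, 48L))
  dna <- matrix(0, 48, 48); dna[38:41, 38:41] <- 50
  sc$channels$dna <- dna
  cells <- segment_cells(sc)
  nucs <- detect_nucleoids(sc, cells)
  expect_length(nucs, 1L)
  expect_true(is.na(nucs[[1L]]$parent))
  expect_length(filter_cells_by_nucleoid(cells, nucs), 0L)
})

test_that("the nucleoid-presence gate keeps exactly the flagged cells", {
  flags <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  centers <- list(c(20.5, 20.5), c(20.5, 60.5), c(20.5, 100.5),
                  c(70.5, 30.5), c(70.5, 80.5))
  cells_truth <- lapply(seq_along(flags), function(i)
    cell_truth(centers[[i]], 16, 7, 0, has_nucleoid = flags[i]))
  sc <- gen_image_scene(cells_truth, c(100L, 128L))
  cells <- segment_cells(sc)
  expect_length(cells, 5L)
  kept <- filter_cells_by_nucleoid(cells, detect_nucleoids(sc, cells))
  expect_length(kept, sum(flags))
})

test_that("the default registry emits 39 parameters with correct values", {
  sc <- make_scene()
  cells <- filter_cells_by_nucleoid(segment_cells(sc),
                                    detect_nucleoids(sc, segment_cells(sc)))
  ft <- extract_features(sc, cells, treatment = "tx", replicate = "rep1")
  expect_equal(length(parameter_names(ft)), 39L)
  expect_equal(nrow(ft), 2L)
  # membrane is uniform inside each cell: constant-image statistics
  truth_int <- c(100, 120)  # cells 1 and 2 carry nucleoids
  expect_equal(ft$membrane_mean, truth_int)
  expect_equal(ft$membrane_median, truth_int)
  expect_equal(ft$membrane_min, truth_int)
  expect_equal(ft$membrane_max, truth_int)
  expect_equal(ft$membrane_sd, c(0, 0))
  expect_equal(ft$membrane_integrated, truth_int * ft$area)
})

test_that("axis lengths recover capsule geometry within 10%", {
  sc <- make_scene()
  cells <- segment_cells(sc)
  truth <- sc$truth$cells
  for (cell in cells) {
    hit <- which.min(vapply(truth, function(tc)
      sum((tc$center - cell$centroid)^2), numeric(1L)))
    expect_lt(abs(cell$major_axis - truth[[hit]]$length_px),
              0.1 * truth[[hit]]$length_px)
    expect_lt(abs(cell$minor_axis - truth[[hit]]$width_px),
              0.1 * truth[[hit]]$width_px)
  }
})

test_that("intensity features are refused on absent or deconvolved channels", {
  sc <- make_scene()
  cells <- segment_cells(sc)
  reg <- default_parameter_registry(channels = c("membrane", "sytox"))
  expect_error(extract_features(sc, cells, reg), "sytox")
  sc$deconvolved[["membrane"]] <- TRUE
  expect_error(extract_features(sc, cells), "deconvolved")
})

test_that("shape and intensity features are invariant to whole-pixel translation", {
  base <- cell_truth(c(20.5, 20.5), 18, 8, 0.5)
  shifted <- cell_truth(c(25.5, 31.5), 18, 8, 0.5)
  f <- function(cell) {
    sc <- gen_image_scene(list(cell), c(64L, 64L))
    cs <- segment_cells(sc)
    kept <- filter_cells_by_nucleoid(cs, detect_nucleoids(sc, cs))
    extract_features(sc, kept)
  }
  fa <- f(base); fb <- f(shifted)
  pars <- parameter_names(fa)
  expect_equal(as.numeric(fa[1, pars]), as.numeric(fb[1, pars]),
               tolerance = 1e-10)
})

test_that("90-degree rotation preserves area, perimeter and intensity totals", {
  horiz <- cell_truth(c(30.5, 30.5), 20, 8, 0)
  vert <- cell_truth(c(30.5, 30.5), 20, 8, pi / 2)
  f <- function(cell) {
    sc <- gen_image_scene(list(cell), c(64L, 64L))
    cs <- segment_cells(sc)
    kept <- filter_cells_by_nucleoid(cs, detect_nucleoids(sc, cs))
    extract_features(sc, kept)
  }
  fa <- f(horiz); fb <- f(vert)
  expect_equal(fa$area, fb$area)
  expect_equal(fa$perimeter, fb$perimeter)
  expect_equal(fa$membrane_mean, fb$membrane_mean)
  expect_equal(fa$membrane_integrated, fb$membrane_integrated)
})

test_that("feature extraction does not mutate the scene", {
  sc <- make_scene()
  before <- sc$channels
  cs <- segment_cells(sc)
  kept <- filter_cells_by_nucleoid(cs, detect_nucleoids(sc, cs))
  invisible(extract_features(sc, kept))
  expect_identical(sc$channels, before)
})

test_that("known intensity ratios between treatments survive the pipeline", {
  mk <- function(inten, trt) {
    cells <- list(cell_truth(c(20.5, 20.5), 18, 8, 0,
                             c(membrane = inten, dna = 50, permeability = 2)),
                  cell_truth(c(45.5, 45.5), 18, 8, 0,
                             c(membrane = inten, dna = 50, permeability = 2)))
    sc <- gen_image_scene(cells, c(72L, 72L), noise_sd = 1, seed = 9)
    cs <- segment_cells(sc)
    kept <- filter_cells_by_nucleoid(cs, detect_nucleoids(sc, cs))
    extract_features(sc, kept, treatment = trt)
  }
  fa <- mk(100, "lo"); fb <- mk(200, "hi")
  ratio <- mean(fb$membrane_mean) / mean(fa$membrane_mean)
  expect_lt(abs(ratio - 2), 0.1)
})
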