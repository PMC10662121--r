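# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: scalar loops instead of vectorized geometry,
# direct eigen-decompositions instead of prcomp, analytic ellipses instead
# of fitted ones.

# Brute-force capsule rasterization: scalar double loop, point-to-segment
# distance computed from first principles at each pixel centre.
oracle_capsule_mask <- function(center, length_px, width_px, orientation,
                                image_shape) {
  nr <- image_shape[1L]; nc <- image_shape[2L]
  h <- max((length_px - width_px) / 2, 0)
  ax <- c(cos(orientation), sin(orientation))   # (col, row)
  p1 <- c(center[2L], center[1L]) - h * ax
  p2 <- c(center[2L], center[1L]) + h * ax
  mask <- matrix(FALSE, nr, nc)
  for (r in 0:(nr - 1L)) for (c in 0:(nc - 1L)) {
    p <- c(c, r)
    seg <- p2 - p1
    len2 <- sum(seg^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((p - p1) * seg) / len2))
    d2 <- sum((p - (p1 + t * seg))^2)
    mask[r + 1L, c + 1L] <- d2 <= (width_px / 2)^2 + 1e-9
  }
  mask
}

# Membership of 2-D points in an analytic ellipse by explicit quadratic
# form with a hand-inverted 2x2 matrix.
oracle_in_ellipse <- function(points, center, shape, radius2) {
  a <- shape[1, 1]; b <- shape[1, 2]; d <- shape[2, 2]
  det <- a * d - b^2
  inv <- matrix(c(d, -b, -b, a), 2) / det
  apply(points, 1L, function(p) {
    v <- p - center
    drop(t(v) %*% inv %*% v) <= radius2
  })
}

# Build a small complete feature table by hand.
make_table <- function(n_per = 10L, treatments = c("A", "B"), p = 3L,
                       seed = 42L) {
  set.seed(seed)
  rows <- do.call(rbind, lapply(treatments, function(tr)
    data.frame(treatment = tr, matrix(rnorm(n_per * p), n_per, p,
                                      dimnames = list(NULL, paste0("p", 1:p))),
               check.names = FALSE)))
  cbind(cell_id = paste0("c", seq_len(nrow(rows))),
        rows[1L],
        replicate = rep_len(paste0("rep", 1:2), nrow(rows)),
        rows[-1L])
}

# A standard three-cell synthetic scene used by several imaging tests.
# Centres are chosen so capsules rasterize at their nominal width
# (half-integer centres for even widths, integer centres for odd).
make_scene <- function(noise_sd = 0, seed = 1) {
  cells <- list(
    cell_truth(c(25.5, 30.5), 20, 8, 0,
               c(membrane = 100, dna = 80, permeability = 5)),
    cell_truth(c(70.5, 65.5), 24, 9, pi / 4,
               c(membrane = 120, dna = 60, permeability = 8)),
    cell_truth(c(100, 30), 18, 7, pi / 2,
               c(membrane = 90, dna = 70, permeability = 4),
               has_nucleoid = FALSE))
  gen_image_scene(cells, c(128L, 128L), background = 0, noise_sd = noise_sd,
                  seed = seed)
}
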