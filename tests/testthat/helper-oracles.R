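# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# 4-connected component count via queue-based flood fill.
brute_count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  for (r0 in seq_len(nrow(mask))) {
    for (c0 in seq_len(ncol(mask))) {
      if (mask[r0, c0] && lab[r0, c0] == 0L) {
        n <- n + 1L
        queue <- list(c(r0, c0))
        lab[r0, c0] <- n
        while (length(queue) > 0) {
          p <- queue[[1]]; queue <- queue[-1]
          for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
            rr <- p[1] + d[1]; cc <- p[2] + d[2]
            if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
                mask[rr, cc] && lab[rr, cc] == 0L) {
              lab[rr, cc] <- n
              queue <- c(queue, list(c(rr, cc)))
            }
          }
        }
      }
    }
  }
  n
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
iou_coef <- function(a, b) sum(a & b) / sum(a | b)

# Pixel-center rasterization of a disc, independent of the phantom renderer.
brute_disc_mask <- function(radius_mm, pixel_mm, canvas) {
  ctr <- (canvas + 1) / 2
  x <- (matrix(rep(seq_len(canvas), each = canvas), canvas, canvas) - ctr) * pixel_mm
  y <- (matrix(rep(seq_len(canvas), times = canvas), canvas, canvas) - ctr) * pixel_mm
  x^2 + y^2 <= radius_mm^2
}

# Shared small phantom fixtures (kept small so the whole suite stays fast).
small_phantom <- function(seed, name = "well_posed", n_sections = 8) {
  p <- phantom_preset(name, seed = seed, n_sections = n_sections)
  generate_phantom(p$config, p$geometry)
}
small_geometry <- function() stack_geometry(pixel_size_mm = 0.05)

# Error of an estimated rigid transform against an injected truth,
# reported as (shift in px at the rotation center, rotation in deg).
transform_error <- function(estimate, truth) {
  e <- compose_rigid(invert_rigid(truth), estimate)
  c(shift = sqrt(e$dx_px^2 + e$dy_px^2), theta = abs(e$theta_deg))
}
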