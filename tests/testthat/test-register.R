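test_that("rigid transforms compose and invert exactly", {
  a <- rigid_transform(3.2, -1.5, 12)
  b <- rigid_transform(-7, 2.4, -5)
  ab <- compose_rigid(a, b)
  pts <- cbind(c(10, 55, 100), c(20, 80, 5))
  d <- c(100, 100)
  via <- map_coords(map_coords(pts, b, d), a, d)
  direct <- map_coords(pts, ab, d)
  expect_equal(via, direct)
  back <- map_coords(map_coords(pts, a, d), invert_rigid(a), d)
  expect_equal(back, pts)
})

test_that("applying the identity transform returns the raster unchanged", {
  set.seed(1)
  m <- matrix(runif(400) < 0.3, 20, 20)
  expect_identical(apply_rigid(m, rigid_transform()), m)
})

test_that("a 90-degree rotation matches a direct index permutation", {
  m <- matrix(FALSE, 21, 21)
  m[3:8, 5:15] <- TRUE
  m[4, 6] <- FALSE  # asymmetric
  got <- apply_rigid(m, rigid_transform(0, 0, 90))
  oracle <- matrix(FALSE, 21, 21)
  ctr <- 11
  for (rr in 1:21) {
    for (cc in 1:21) {
      if (m[rr, cc]) {
        oracle[(cc - ctr) + ctr, -(rr - ctr) + ctr] <- TRUE
      }
    }
  }
  expect_identical(got, oracle)
})

test_that("nearest-neighbor resampling preserves mask area within 1%", {
  ph <- small_phantom(2, "noise_free", n_sections = 3)
  m <- ph$ground_truth$masks[[2]]$tissue  # ~100 mm^2 silhouette
  set.seed(99)
  for (i in 1:20) {
    tr <- rigid_transform(runif(1, -15, 15), runif(1, -15, 15),
                          runif(1, -15, 15))
    moved <- apply_rigid(m, tr, "nearest")
    expect_lt(abs(sum(moved) - sum(m)) / sum(m), 0.01)
  }
})

test_that("self-registration returns the identity", {
  ph <- small_phantom(1, "noise_free", n_sections = 3)
  m <- ph$ground_truth$masks[[2]]$tissue
  fit <- estimate_rigid(m, m)
  expect_lt(abs(fit$transform$dx_px), 0.5)
  expect_lt(abs(fit$transform$dy_px), 0.5)
  expect_lt(abs(fit$transform$theta_deg), 0.1)
  expect_equal(fit$iou, 1)
})

test_that("known injected transforms are recovered within 1 px and 1 degree", {
  ph <- small_phantom(3, "noise_free", n_sections = 3)
  m <- ph$ground_truth$masks[[2]]$tissue
  truth <- rigid_transform(12, -7, 9)
  moved <- apply_rigid(m, truth, "nearest")
  # the estimate maps `moved` back onto `m`, i.e. the inverse of the
  # injected transform
  fit <- estimate_rigid(m, moved)
  err <- transform_error(fit$transform, invert_rigid(truth))
  expect_lt(err[["shift"]], 1)
  expect_lt(err[["theta"]], 1)
  # and across 20 random draws spanning the slide-placement jitter envelope
  set.seed(123)
  for (i in 1:20) {
    tr <- rigid_transform(runif(1, -15, 15), runif(1, -15, 15),
                          runif(1, -10, 10))
    fit_i <- estimate_rigid(m, apply_rigid(m, tr, "nearest"))
    err_i <- transform_error(fit_i$transform, invert_rigid(tr))
    expect_lt(err_i[["shift"]], 1)
    expect_lt(err_i[["theta"]], 1)
  }
})

test_that("forward and reverse estimates compose to the identity", {
  ph <- small_phantom(7, "noise_free", n_sections = 3)
  m <- ph$ground_truth$masks[[2]]$tissue
  tr <- rigid_transform(9, 6, -7)
  moved <- apply_rigid(m, tr, "nearest")
  f1 <- estimate_rigid(m, moved)
  f2 <- estimate_rigid(moved, m)
  rt <- compose_rigid(f1$transform, f2$transform)
  expect_lt(sqrt(rt$dx_px^2 + rt$dy_px^2), 1)
  expect_lt(abs(rt$theta_deg), 1)
})

test_that("registration rejects empty masks but alignment flags them", {
  empty <- matrix(FALSE, 30, 30)
  full <- matrix(FALSE, 30, 30); full[10:20, 10:20] <- TRUE
  expect_error(estimate_rigid(empty, full), "empty")
  expect_error(estimate_rigid(full, matrix(FALSE, 20, 20)), "dimensions")
  lm_full <- label_masks(full, full & FALSE, full)
  lm_empty <- label_masks(empty, empty, empty)
  al <- align_stack(list(lm_full, lm_empty, lm_full), reference = 1)
  expect_true(al$qc_empty[2])
  expect_equal(al$transforms[[2]]$theta_deg, 0)
})

test_that("an already-aligned stack yields near-identity transforms", {
  ph <- small_phantom(5, "noise_free", n_sections = 5)
  masks <- ph$ground_truth$masks
  al <- align_stack(masks)
  for (tr in al$transforms) {
    expect_lt(sqrt(tr$dx_px^2 + tr$dy_px^2), 1)
    expect_lt(abs(tr$theta_deg), 0.5)
  }
  # single-slice stack: identity, no error
  one <- align_stack(masks[3])
  expect_equal(one$transforms[[1]]$dx_px, 0)
})

test_that("aligning a jittered phantom restores the ground-truth frame", {
  ph <- small_phantom(6, "well_posed", n_sections = 8)
  g <- small_geometry()
  gt <- ph$ground_truth
  masks <- segment_stack(ph$images, seg_params(), g, edits = gt$edits)
  al <- align_stack(masks)
  # aligned frame = the reference slice's rendered frame: compare against
  # ground-truth masks carried into that frame
  jref <- gt$transforms[[al$reference]]
  ious <- vapply(seq_along(masks), function(j) {
    truth <- apply_rigid(gt$masks[[j]]$tissue, jref, "nearest")
    iou_coef(truth, al$masks[[j]]$tissue)
  }, numeric(1))
  expect_gte(mean(ious), 0.97)
  # quantification is preserved by alignment within 1%
  before <- measure_stack(masks, g)$necrotic_area_mm2
  after <- measure_stack(al$masks, g)$necrotic_area_mm2
  keep <- before > 1
  expect_true(all(abs(after[keep] - before[keep]) / before[keep] < 0.01))
})
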