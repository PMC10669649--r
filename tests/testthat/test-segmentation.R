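make_rgb <- function(h, w, rgb) {
  a <- array(0, c(h, w, 3))
  for (ch in 1:3) a[, , ch] <- rgb[ch]
  a
}

# Render label masks back to clean stain colors (for idempotence checks).
masks_to_rgb <- function(m) {
  img <- make_rgb(nrow(m$tissue), ncol(m$tissue), c(250, 250, 250))
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[m$viable] <- c(62, 78, 168)[ch]
    plane[m$necrosis] <- c(202, 200, 206)[ch]
    img[, , ch] <- plane
  }
  img
}

test_that("a uniform white image segments to an empty tissue mask", {
  img <- make_rgb(50, 60, c(250, 250, 250))
  m <- segment_tissue(img, seg_params(), stack_geometry(pixel_size_mm = 0.05))
  expect_true(is.logical(m))
  expect_false(any(m))
  expect_error(segment_tissue(matrix(1, 5, 5)), "RGB")
})

test_that("noise-free phantom slices are recovered almost exactly", {
  ph <- small_phantom(4, "noise_free", n_sections = 6)
  g <- small_geometry()
  gt <- ph$ground_truth
  for (k in c(2, 4)) {
    tissue <- segment_tissue(ph$images[[k]], seg_params(), g)
    expect_gte(dice_coef(tissue, gt$masks[[k]]$tissue), 0.99)
    m <- separate_necrosis(ph$images[[k]], tissue, seg_params())
    if (any(gt$masks[[k]]$necrosis)) {
      expect_gte(dice_coef(m$necrosis, gt$masks[[k]]$necrosis), 0.98)
    }
  }
})

test_that("background specks below the minimum component area are removed", {
  g <- stack_geometry(pixel_size_mm = 0.05)
  ph <- small_phantom(6, "noise_free", n_sections = 3)
  img <- ph$images[[2]]$pixels
  # paint 5 dark specks (each 4 px = 0.01 mm^2 < 0.05 mm^2) on the background
  for (pos in list(c(5, 5), c(5, 300), c(300, 5), c(10, 150), c(310, 310))) {
    for (ch in 1:3) img[pos[1] + 0:1, pos[2] + 0:1, ch] <- 100
  }
  m <- segment_tissue(img, seg_params(), g)
  expect_equal(brute_count_components(m), 1)
})

test_that("necrosis and viable pixel counts always sum to the tissue count", {
  ph <- small_phantom(8, n_sections = 4)
  g <- small_geometry()
  for (k in c(1, 4)) {
    tissue <- segment_tissue(ph$images[[k]], seg_params(), g)
    m <- separate_necrosis(ph$images[[k]], tissue, seg_params())
    expect_equal(sum(m$necrosis) + sum(m$viable), sum(m$tissue))
    expect_identical(m$necrosis | m$viable, m$tissue)
  }
  # empty tissue gives empty class masks
  img <- make_rgb(30, 30, c(250, 250, 250))
  empty <- segment_tissue(img, seg_params(), g)
  m0 <- separate_necrosis(img, empty, seg_params())
  expect_false(any(m0$necrosis) || any(m0$viable))
})

test_that("segmentation is idempotent on its own clean rendering", {
  ph <- small_phantom(4, "noise_free", n_sections = 5)
  g <- small_geometry()
  tissue <- segment_tissue(ph$images[[3]], seg_params(), g)
  m <- separate_necrosis(ph$images[[3]], tissue, seg_params())
  re_img <- masks_to_rgb(m)
  tissue2 <- segment_tissue(re_img, seg_params(), g)
  m2 <- separate_necrosis(re_img, tissue2, seg_params())
  expect_identical(m2$tissue, m$tissue)
  expect_identical(m2$necrosis, m$necrosis)
})

test_that("raising the minimum component area never grows the tissue mask", {
  ph <- small_phantom(10, n_sections = 3)
  g <- small_geometry()
  img <- ph$images[[2]]
  sizes <- c(0.01, 0.05, 0.2, 1)
  counts <- vapply(sizes, function(s) {
    sum(segment_tissue(img, seg_params(min_component_area_mm2 = s), g))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-slice necrotic areas on the moderate-noise preset are within 2%", {
  ph <- small_phantom(12, "well_posed", n_sections = 8)
  g <- small_geometry()
  gt <- ph$ground_truth
  masks <- segment_stack(ph$images, seg_params(), g, edits = gt$edits)
  lesion <- which(gt$necrotic_area_mm2 > 0)
  for (k in lesion) {
    a <- slice_areas(masks[[k]], g)$necrotic_area_mm2
    expect_lt(abs(a - gt$necrotic_area_mm2[k]) / gt$necrotic_area_mm2[k], 0.02)
  }
})

test_that("declarative edits behave like the manual corrections they replace", {
  ph <- small_phantom(5, "noise_free", n_sections = 4)
  g <- small_geometry()
  tissue <- segment_tissue(ph$images[[3]], seg_params(), g)
  m <- separate_necrosis(ph$images[[3]], tissue, seg_params())
  h <- nrow(m$tissue); w <- ncol(m$tissue)

  # empty edit list: identity
  expect_identical(apply_edits(m, list()), m)

  # absorbing edit: reassign the whole frame to viable
  all_poly <- rbind(c(1, 1), c(w, 1), c(w, h), c(1, h))
  m_v <- apply_edits(m, list(edit_op("reassign_to_viable", all_poly, 3)), 3)
  expect_false(any(m_v$necrosis))
  expect_identical(m_v$viable, m_v$tissue)

  # rectangle reassigned to necrosis grows the count by the exact
  # rasterized pixel count (axis-aligned rectangle oracle)
  rect <- rbind(c(100.5, 200.5), c(140.5, 200.5), c(140.5, 230.5), c(100.5, 230.5))
  in_tissue <- sum(m$tissue[201:230, 101:140] & !m$necrosis[201:230, 101:140])
  m_n <- apply_edits(m, list(edit_op("reassign_to_necrosis", rect, 3)), 3)
  expect_equal(sum(m_n$necrosis), sum(m$necrosis) + in_tissue)

  # fill_hole adds non-tissue pixels as viable
  bg_rect <- rbind(c(2.5, 2.5), c(20.5, 2.5), c(20.5, 20.5), c(2.5, 20.5))
  m_f <- apply_edits(m, list(edit_op("fill_hole", bg_rect, 3)), 3)
  expect_gt(sum(m_f$tissue), sum(m$tissue))
  expect_identical(m_f$necrosis, m$necrosis)

  # remove_region empties the polygon
  m_r <- apply_edits(m, list(edit_op("remove_region", all_poly, 3)), 3)
  expect_false(any(m_r$tissue))

  # out-of-bounds polygons are rejected with the offending index
  bad <- rbind(c(-5, 1), c(10, 1), c(10, 10))
  expect_error(apply_edits(m, list(edit_op("reassign_to_viable", bad, 3)), 3),
               "edit 1")
  # edits for other slices are skipped
  expect_identical(apply_edits(m, list(edit_op("remove_region", all_poly, 7)), 3), m)
  # partition invariant holds after every edit
  for (mm in list(m_v, m_n, m_f, m_r)) {
    expect_identical(mm$necrosis | mm$viable, mm$tissue)
    expect_false(any(mm$necrosis & mm$viable))
  }
})
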