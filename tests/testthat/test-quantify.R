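test_that("stack geometry validates and converts units", {
  g <- stack_geometry()
  expect_equal(slice_increment(g), 0.52)
  expect_equal(pixel_area_mm2(stack_geometry(pixel_size_mm = 0.01)), 1e-4)
  expect_error(stack_geometry(section_thickness_mm = 0), "positive")
  expect_error(stack_geometry(pixel_size_mm = -1), "positive")
})

test_that("necrotic volume weights all but the last section by the full increment", {
  g <- stack_geometry()
  expect_equal(necrosis_volume(rep(10, 10), g), 47.0)
  expect_equal(necrosis_volume(1, g), 0.02)
  expect_equal(necrosis_volume(numeric(0), g), 0)
  expect_error(necrosis_volume(c(1, -1), g), "non-negative")
  # linearity in the areas
  set.seed(42)
  for (i in 1:5) {
    a <- runif(sample(2:20, 1), 0, 50)
    c0 <- runif(1, 0.1, 5)
    expect_equal(necrosis_volume(c0 * a, g), c0 * necrosis_volume(a, g))
  }
})

test_that("necrotic depth follows N x thickness + (N-1) x spacing", {
  g <- stack_geometry()
  expect_identical(necrosis_depth(50, g), 25.5)
  expect_identical(necrosis_depth(25, g), 12.5)
  expect_equal(necrosis_depth(34, g), 17.18)
  expect_equal(round(necrosis_depth(34, g), 1), 17.2)
  expect_equal(necrosis_depth(1, g), 0.02)
  expect_identical(necrosis_depth(0, g), 0)
  expect_error(necrosis_depth(2.5, g), "integer")
  # strictly increasing with constant increment for N >= 1
  d <- vapply(1:60, necrosis_depth, numeric(1), geometry = g)
  expect_true(all(abs(diff(d) - slice_increment(g)) < 1e-12))
})

test_that("summaries apply the inclusion threshold in sectioning order", {
  g <- stack_geometry()
  s <- summarize_necrosis(c(0, 0.005, 5, 10, 0.002), g, min_area_mm2 = 0.01)
  expect_equal(s$n_sections, 2)
  expect_equal(s$volume_uL, 5 * 0.52 + 10 * 0.02)
  expect_equal(s$depth_mm, necrosis_depth(2, g))
  empty <- summarize_necrosis(numeric(0), g)
  expect_equal(empty$n_sections, 0)
  expect_equal(empty$volume_uL, 0)
  expect_equal(empty$depth_mm, 0)
})

test_that("slice areas equal pixel counts times the pixel area", {
  g <- stack_geometry(pixel_size_mm = 0.01)
  set.seed(7)
  tissue <- matrix(runif(100 * 120) < 0.4, 100, 120)
  necrosis <- tissue & matrix(runif(100 * 120) < 0.3, 100, 120)
  m <- label_masks(tissue, necrosis, tissue & !necrosis)
  a <- slice_areas(m, g)
  expect_equal(a$necrotic_area_mm2, sum(necrosis) * 1e-4)
  expect_equal(a$viable_area_mm2, sum(tissue & !necrosis) * 1e-4)
  # 10,000 pixels at 0.01 mm -> 1 mm^2
  big <- matrix(FALSE, 200, 200); big[1:100, 1:100] <- TRUE
  mb <- label_masks(big, big, big & FALSE)
  expect_equal(slice_areas(mb, g)$necrotic_area_mm2, 1.0)
  empty <- label_masks(big & FALSE, big & FALSE, big & FALSE)
  expect_equal(slice_areas(empty, g)$necrotic_area_mm2, 0)
})

test_that("top-half split uses the tissue centroid row", {
  g <- stack_geometry(pixel_size_mm = 0.1)
  # mirror-symmetric necrosis about the centroid: halves agree within one row
  tissue <- matrix(FALSE, 40, 40); tissue[10:30, 10:30] <- TRUE
  necrosis <- matrix(FALSE, 40, 40); necrosis[15:25, 15:25] <- TRUE
  m <- label_masks(tissue, necrosis, tissue & !necrosis)
  h <- top_half_areas(m, g)
  row_area <- sum(necrosis[20, ]) * pixel_area_mm2(g)
  expect_lt(abs(h$top_half_necrotic_area_mm2 - sum(necrosis) *
                  pixel_area_mm2(g) / 2), row_area + 1e-12)
  # necrosis entirely above the split -> top half equals the whole
  nec_top <- matrix(FALSE, 40, 40); nec_top[10:14, 12:20] <- TRUE
  m2 <- label_masks(tissue, nec_top, tissue & !nec_top)
  h2 <- top_half_areas(m2, g)
  expect_equal(h2$top_half_necrotic_area_mm2,
               sum(nec_top) * pixel_area_mm2(g))
  # brute-force row-count oracle on a phantom slice (lesion at 12 o'clock)
  ph <- small_phantom(11, "noise_free", n_sections = 6)
  mk <- ph$ground_truth$masks[[4]]
  hh <- top_half_areas(mk, small_geometry())
  rows <- row(mk$tissue)[mk$tissue]
  cr <- mean(rows)
  oracle <- sum(row(mk$necrosis)[mk$necrosis] < cr) *
    pixel_area_mm2(small_geometry())
  expect_equal(hh$top_half_necrotic_area_mm2, oracle)
  # empty tissue is flagged, not an error
  e <- label_masks(tissue & FALSE, tissue & FALSE, tissue & FALSE)
  he <- top_half_areas(e, g)
  expect_true(he$qc_empty_tissue)
  expect_equal(he$top_half_necrotic_area_mm2, 0)
})

test_that("whole-slice necrotic area equals top plus bottom half exactly", {
  ph <- small_phantom(13, "well_posed", n_sections = 6)
  g <- small_geometry()
  for (k in c(4, 5)) {
    m <- ph$ground_truth$masks[[k]]
    a <- slice_areas(m, g)
    h <- top_half_areas(m, g)
    expect_equal(h$top_half_necrotic_area_mm2 + h$bottom_half_necrotic_area_mm2,
                 a$necrotic_area_mm2)
  }
})

test_that("group comparison matches a closed-form oracle and handles summaries", {
  # identical groups with nonzero variance: t = 0, p = 1
  x <- c(1, 2, 3, 4, 5)
  r0 <- compare_groups(x, x)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # fixed 2x5 dataset against a from-scratch pooled t and incomplete-beta tail
  a <- c(3.1, 4.5, 2.2, 5.0, 3.8)
  b <- c(6.0, 5.5, 7.1, 6.6, 5.9)
  r <- compare_groups(a, b)
  sp2 <- ((5 - 1) * var(a) + (5 - 1) * var(b)) / 8
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 5))
  df <- 8
  p_oracle <- pbeta(df / (df + t_oracle^2), df / 2, 0.5)  # regularized I_x
  expect_equal(r$t, t_oracle)
  expect_equal(r$df, 8)
  expect_equal(r$p, p_oracle, tolerance = 1e-12)
  # summary-statistic input reproduces the vector route
  rs <- compare_groups(list(mean = mean(a), sd = sd(a), n = 5),
                       list(mean = mean(b), sd = sd(b), n = 5))
  expect_equal(rs$t, r$t)
  expect_equal(rs$p, r$p)
  # welch variant agrees with stats::t.test
  rw <- compare_groups(a, b, variant = "welch")
  tw <- t.test(a, b)
  expect_equal(rw$t, unname(tw$statistic))
  expect_equal(rw$df, unname(tw$parameter))
  # errors
  expect_error(compare_groups(c(1), c(1, 2)), "at least 2")
  expect_error(compare_groups(c(1, 1), c(2, 2)), "variance")
})
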