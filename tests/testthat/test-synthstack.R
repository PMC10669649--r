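test_that("phantom generation is deterministic under config + seed", {
  a <- small_phantom(21, n_sections = 3)
  b <- small_phantom(21, n_sections = 3)
  expect_identical(lapply(a$images, `[[`, "pixels"),
                   lapply(b$images, `[[`, "pixels"))
  expect_identical(a$ground_truth$necrotic_area_mm2,
                   b$ground_truth$necrotic_area_mm2)
  expect_identical(lapply(a$ground_truth$transforms, unclass),
                   lapply(b$ground_truth$transforms, unclass))
  c2 <- small_phantom(22, n_sections = 3)
  expect_false(identical(a$images[[1]]$pixels, c2$images[[1]]$pixels))
})

test_that("ground-truth masks partition the tissue and match pixel counts", {
  ph <- small_phantom(5, n_sections = 6)
  g <- small_geometry()
  gt <- ph$ground_truth
  for (k in seq_along(gt$masks)) {
    m <- gt$masks[[k]]
    expect_identical(m$necrosis | m$viable, m$tissue)
    expect_false(any(m$necrosis & m$viable))
    expect_equal(gt$necrotic_area_mm2[k], sum(m$necrosis) * pixel_area_mm2(g))
    expect_equal(gt$viable_area_mm2[k], sum(m$viable) * pixel_area_mm2(g))
  }
})

test_that("a zero-extent lesion yields no necrosis anywhere", {
  p <- phantom_preset("noise_free", seed = 1, n_sections = 4)
  p$config$lesion$semi_axes_mm <- c(0, 0)
  ph <- generate_phantom(p$config, p$geometry)
  expect_true(all(ph$ground_truth$necrotic_area_mm2 == 0))
  expect_equal(ph$ground_truth$summary$volume_uL, 0)
  expect_equal(ph$ground_truth$summary$depth_mm, 0)
})

test_that("rasterized lesion areas converge to the analytic cross-section", {
  # cylindrical lesion, radius 1 mm: slice area ~ pi, checked against an
  # independent pixel-counting disc oracle, at two resolutions
  errs <- vapply(c(0.02, 0.01), function(px) {
    p <- phantom_preset("noise_free", seed = 1, n_sections = 3)
    p$config$canvas_px <- as.integer(rep(round(16 / px), 2))
    p$config$lesion <- list(shape = "cylinder", center_mm = c(0, -3.2),
                            semi_axes_mm = c(1, 1), z_range = c(1, 3))
    g <- stack_geometry(pixel_size_mm = px)
    ph <- generate_phantom(p$config, g)
    area <- ph$ground_truth$necrotic_area_mm2[2]
    oracle <- sum(brute_disc_mask(1, px, 401)) * px^2
    expect_lt(abs(area - pi) / pi, 0.01)
    expect_lt(abs(oracle - pi) / pi, 0.01)
    abs(area - pi) / pi
  }, numeric(1))
  expect_lt(errs[2], errs[1])  # finer pixels, smaller rasterization error
})

test_that("injected jitter transforms are exactly invertible", {
  ph <- small_phantom(9, n_sections = 5)
  for (tr in ph$ground_truth$transforms) {
    rt <- compose_rigid(invert_rigid(tr), tr)
    expect_lt(abs(rt$dx_px), 1e-10)
    expect_lt(abs(rt$dy_px), 1e-10)
    expect_lt(abs(rt$theta_deg), 1e-10)
  }
})

test_that("phantom configuration rejects impossible geometry", {
  expect_error(phantom_config(canal_radius_mm = 7, cervix_outer_radius_mm = 6),
               "smaller")
  expect_error(phantom_config(n_sections = 0), "positive")
  p <- phantom_preset("noise_free", seed = 1, n_sections = 3)
  p$config$lesion$center_mm <- c(40, 0)  # far outside a 16 mm canvas
  expect_error(generate_phantom(p$config, p$geometry), "geometry error")
})

test_that("ground-truth summary applies the printed formulas to true areas", {
  g <- stack_geometry()
  gt10 <- list(necrotic_area_mm2 = rep(10, 10))
  s <- ground_truth_summary(gt10, g)
  expect_equal(s$volume_uL, 47.0)
  s1 <- ground_truth_summary(list(necrotic_area_mm2 = 1), g)
  expect_equal(s1$volume_uL, 0.02)
  expect_equal(s1$depth_mm, 0.02)
  s0 <- ground_truth_summary(list(necrotic_area_mm2 = numeric(0)), g)
  expect_equal(s0$volume_uL, 0)
  expect_equal(s0$depth_mm, 0)
  expect_error(ground_truth_summary(list(), g), "areas")
  # a generated phantom reproduces its own stored summary
  ph <- small_phantom(3, n_sections = 5)
  re <- ground_truth_summary(ph$ground_truth, small_geometry())
  expect_identical(unclass(re), unclass(ph$ground_truth$summary))
})

test_that("phantom stacks round-trip through disk", {
  ph <- small_phantom(2, "noise_free", n_sections = 3)
  d <- withr::local_tempdir()
  write_phantom_stack(ph, d)
  imgs <- read_stack(d, small_geometry())
  expect_length(imgs, 3)
  expect_equal(imgs[[2]]$pixels, ph$images[[2]]$pixels)
  sidecar <- jsonlite::read_json(file.path(d, "stack.json"))
  expect_equal(sidecar$n_sections, 3)
  nec <- read_mask_png(file.path(d, "truth", "necrosis_002.png"))
  expect_identical(nec, ph$ground_truth$masks[[2]]$necrosis)
})
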