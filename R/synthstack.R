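#' Configuration for a synthetic serial-section phantom
#'
#' Describes a synthetic stack of NADH-diaphorase-like stained cervical
#' cross-sections: a star-shaped (non-circular) outer boundary so rotation is
#' identifiable, a central canal hole, a solid necrotic lesion (cylinder or
#' ellipsoid) placed at a clock position, stain colors with per-channel
#' Gaussian noise, small unstained voids ("holes") inside viable tissue,
#' background artifacts, and per-slice rigid jitter emulating arbitrary
#' placement on the microscope slide. Viable tissue is rendered blue-dominant,
#' necrosis low-saturation light gray, background near-white.
#'
#' @param canvas_px Canvas size `c(width, height)` in pixels.
#' @param n_sections Number of serial sections.
#' @param cervix_outer_radius_mm Mean outer radius of the cross-section, mm.
#' @param canal_radius_mm Radius of the central canal hole, mm (must be
#'   smaller than the outer radius).
#' @param outer_shape List of boundary perturbations: `ellipticity` and
#'   `lobe3` harmonic amplitudes, their phases `phase2`/`phase3` (radians),
#'   and a quadratic axial `taper`.
#' @param lesion List: `shape` ("cylinder" or "ellipsoid"), `center_mm`
#'   `c(x, y)` offset from the cervix center (y negative towards 12 o'clock,
#'   i.e. the top image rows), in-plane `semi_axes_mm` `c(ax, ay)`, and
#'   `z_range` `c(first, last)` slice indices spanned. For an ellipsoid the
#'   in-plane cross-section shrinks towards the ends of `z_range`.
#' @param stain List of `viable_rgb`, `necrotic_rgb`, `background_rgb`,
#'   `artifact_rgb` (0-255 vectors) and `noise_sd` (per-channel Gaussian SD).
#' @param hole_count,hole_area_mm2 Number and area range of unstained voids
#'   rendered inside viable tissue on each slice. Voids are rendered in the
#'   image but are counted as viable in the ground truth, mirroring the
#'   manual hole-filling step of the semi-automated workflow.
#' @param artifact_count,artifact_area_mm2 Number and area range of dark
#'   specks rendered on the background of each slice.
#' @param jitter List `max_shift_px`, `max_theta_deg`: per-slice rigid jitter
#'   bounds (uniform draws).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `phantom_config` object.
#' @seealso [generate_phantom()], [phantom_preset()]
#' @export
phantom_config <- function(canvas_px = c(360, 360),
                           n_sections = 30,
                           cervix_outer_radius_mm = 6.5,
                           canal_radius_mm = 1.2,
                           outer_shape = list(ellipticity = 0.12, lobe3 = 0.06,
                                              phase2 = 0.4, phase3 = 1.1,
                                              taper = 0.06),
                           lesion = list(shape = "cylinder",
                                         center_mm = c(0, -3.2),
                                         semi_axes_mm = c(2.2, 1.8),
                                         z_range = c(4, 25)),
                           stain = list(viable_rgb = c(62, 78, 168),
                                        necrotic_rgb = c(202, 200, 206),
                                        background_rgb = c(250, 250, 250),
                                        artifact_rgb = c(120, 110, 115),
                                        noise_sd = 8),
                           hole_count = 1,
                           hole_area_mm2 = c(0.02, 0.06),
                           artifact_count = 6,
                           artifact_area_mm2 = c(0.01, 0.04),
                           jitter = list(max_shift_px = 15, max_theta_deg = 8),
                           seed = 1L) {
  if (any(canvas_px <= 0) || n_sections < 1) {
    stop("canvas and section count must be positive", call. = FALSE)
  }
  if (cervix_outer_radius_mm <= 0 || canal_radius_mm <= 0) {
    stop("radii must be strictly positive", call. = FALSE)
  }
  if (canal_radius_mm >= cervix_outer_radius_mm) {
    stop("canal_radius_mm must be smaller than cervix_outer_radius_mm",
         call. = FALSE)
  }
  lesion$shape <- match.arg(lesion$shape, c("cylinder", "ellipsoid"))
  if (any(lesion$semi_axes_mm < 0)) {
    stop("lesion semi-axes must be non-negative", call. = FALSE)
  }
  structure(
    list(canvas_px = as.integer(canvas_px), n_sections = as.integer(n_sections),
         cervix_outer_radius_mm = cervix_outer_radius_mm,
         canal_radius_mm = canal_radius_mm,
         outer_shape = outer_shape, lesion = lesion, stain = stain,
         hole_count = hole_count, hole_area_mm2 = hole_area_mm2,
         artifact_count = artifact_count, artifact_area_mm2 = artifact_area_mm2,
         jitter = jitter, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Named phantom presets
#'
#' `"well_posed"` is the reference test condition: a 30-section stack with a
#' cylindrical lesion at the 12 o'clock position, moderate staining noise,
#' small voids and background specks, and rigid jitter up to 15 px / 8
#' degrees. `"noise_free"` is the same geometry with noise, voids, artifacts
#' and jitter all switched off. Both use a 0.05 mm working pixel size so a
#' full stack stays small; rasterization-convergence behavior is covered by
#' dedicated resolution tests.
#'
#' @param name `"well_posed"` or `"noise_free"`.
#' @param seed Integer seed.
#' @param n_sections Number of sections.
#' @return A list with elements `config` ([phantom_config()]) and
#'   `geometry` ([stack_geometry()]).
#' @export
phantom_preset <- function(name = c("well_posed", "noise_free"), seed = 1L,
                           n_sections = 30) {
  name <- match.arg(name)
  geometry <- stack_geometry(pixel_size_mm = 0.05)
  config <- phantom_config(seed = seed, n_sections = n_sections)
  if (name == "noise_free") {
    config$stain$noise_sd <- 0
    config$hole_count <- 0
    config$artifact_count <- 0
    config$jitter <- list(max_shift_px = 0, max_theta_deg = 0)
  }
  list(config = config, geometry = geometry)
}

# Outer boundary radius at polar angle phi for slice k (star-shaped, tapered).
outer_radius <- function(phi, k, config) {
  os <- config$outer_shape
  n <- config$n_sections
  taper <- 1 - os$taper * ((k - (n + 1) / 2) / max(1, n / 2))^2
  config$cervix_outer_radius_mm * taper *
    (1 + os$ellipticity * cos(2 * (phi - os$phase2)) +
       os$lobe3 * cos(3 * (phi - os$phase3)))
}

# In-plane lesion semi-axes on slice k (0,0 when the slice is outside the
# lesion's z range or the lesion has zero extent).
lesion_semi_axes <- function(k, config) {
  les <- config$lesion
  zr <- les$z_range
  if (k < zr[1] || k > zr[2] || any(les$semi_axes_mm <= 0)) return(c(0, 0))
  if (les$shape == "cylinder") return(les$semi_axes_mm)
  zc <- mean(zr)
  za <- max((zr[2] - zr[1]) / 2, 0.5)
  s <- sqrt(max(0, 1 - ((k - zc) / za)^2))
  les$semi_axes_mm * s
}

# Class codes for pixel coordinates (mm, relative to canvas center):
# 0 background, 1 viable, 2 necrotic. Vectorized over x/y.
classify_pixels <- function(x_mm, y_mm, k, config) {
  r <- sqrt(x_mm^2 + y_mm^2)
  phi <- atan2(y_mm, x_mm)
  tissue <- r <= outer_radius(phi, k, config) & r > config$canal_radius_mm
  cls <- ifelse(tissue, 1L, 0L)
  sa <- lesion_semi_axes(k, config)
  if (all(sa > 0)) {
    ctr <- config$lesion$center_mm
    inside <- ((x_mm - ctr[1]) / sa[1])^2 + ((y_mm - ctr[2]) / sa[2])^2 <= 1
    cls[tissue & inside] <- 2L
  }
  cls
}

in_any_ellipse <- function(x_mm, y_mm, ellipses) {
  hit <- rep(FALSE, length(x_mm))
  for (e in ellipses) {
    hit <- hit | (((x_mm - e$center[1]) / e$semi[1])^2 +
                    ((y_mm - e$center[2]) / e$semi[2])^2 <= 1)
  }
  hit
}

# Draw a random small ellipse with the given area range (axis-aligned,
# aspect ratio 1..2).
sample_ellipse <- function(center, area_range) {
  area <- stats::runif(1, area_range[1], area_range[2])
  aspect <- stats::runif(1, 1, 2)
  b <- sqrt(area / (pi * aspect))
  list(center = center, semi = c(aspect * b, b))
}

#' Generate a synthetic serial-section stack with exact ground truth
#'
#' Renders `config$n_sections` RGB section images plus the exact per-slice
#' label masks, areas and rigid jitter transforms used to produce them.
#' Ground-truth masks are rasterized in the unjittered frame; each rendered
#' image is rasterized directly in its jittered frame (the analytic shapes
#' are evaluated at back-transformed pixel coordinates), so truth and image
#' differ only by the recorded rigid transform and the staining noise.
#'
#' @param config A [phantom_config()].
#' @param geometry A [stack_geometry()].
#' @return A list with:
#'   \describe{
#'     \item{images}{List of `section_image` objects (8-bit RGB arrays).}
#'     \item{ground_truth}{A `phantom_ground_truth` object: per-slice
#'       [label_masks()], `necrotic_area_mm2` / `viable_area_mm2` vectors,
#'       per-slice injected [rigid_transform()]s, the formula-true
#'       `summary` (see [ground_truth_summary()]), and `edits` — replayable
#'       [edit_op()] cleanup polygons for the rendered voids, standing in
#'       for the manual corrections of the semi-automated workflow.}
#'   }
#' @export
generate_phantom <- function(config, geometry = stack_geometry(pixel_size_mm = 0.05)) {
  stopifnot(inherits(config, "phantom_config"), inherits(geometry, "stack_geometry"))
  w <- config$canvas_px[1]; h <- config$canvas_px[2]
  px <- geometry$pixel_size_mm
  half_w <- w * px / 2; half_h <- h * px / 2
  les <- config$lesion
  if (any(les$semi_axes_mm > 0)) {
    reach <- abs(les$center_mm) + les$semi_axes_mm
    if (reach[1] > half_w || reach[2] > half_h) {
      stop("phantom geometry error: lesion extends outside the canvas",
           call. = FALSE)
    }
  }
  max_boundary <- config$cervix_outer_radius_mm *
    (1 + abs(config$outer_shape$ellipticity) + abs(config$outer_shape$lobe3))
  jitter_reach <- sqrt(2) * config$jitter$max_shift_px * px
  if (max_boundary + jitter_reach > min(half_w, half_h)) {
    stop(paste("phantom geometry error: cervix outer boundary (plus jitter)",
               "exceeds the canvas"), call. = FALSE)
  }

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  cxp <- (w + 1) / 2; cyp <- (h + 1) / 2
  xs <- (seq_len(w) - cxp) * px
  ys <- (seq_len(h) - cyp) * px
  x_id <- matrix(rep(xs, each = h), h, w)
  y_id <- matrix(rep(ys, times = w), h, w)
  grid_px <- cbind(rep(seq_len(w), each = h), rep(seq_len(h), times = w))

  colors <- rbind(config$stain$background_rgb, config$stain$viable_rgb,
                  config$stain$necrotic_rgb, config$stain$background_rgb,
                  config$stain$artifact_rgb)  # classes 0,1,2,hole,artifact

  images <- vector("list", config$n_sections)
  masks <- vector("list", config$n_sections)
  transforms <- vector("list", config$n_sections)
  nec_area <- viab_area <- numeric(config$n_sections)
  edits <- list()

  for (k in seq_len(config$n_sections)) {
    # --- ground truth in the unjittered frame ---
    cls <- classify_pixels(as.vector(x_id), as.vector(y_id), k, config)
    cls <- matrix(cls, h, w)
    tissue <- cls > 0L
    necrosis <- cls == 2L
    masks[[k]] <- label_masks(tissue, necrosis, tissue & !necrosis)
    nec_area[k] <- sum(necrosis) * px^2
    viab_area[k] <- sum(tissue & !necrosis) * px^2

    # --- random slice features (order fixed for determinism) ---
    jit <- config$jitter
    transforms[[k]] <- rigid_transform(
      dx_px = stats::runif(1, -jit$max_shift_px, jit$max_shift_px),
      dy_px = stats::runif(1, -jit$max_shift_px, jit$max_shift_px),
      theta_deg = stats::runif(1, -jit$max_theta_deg, jit$max_theta_deg))

    holes <- list()
    sa <- lesion_semi_axes(k, config)
    n_try <- 0
    while (length(holes) < config$hole_count && n_try < 200) {
      n_try <- n_try + 1
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, config$canal_radius_mm + 0.5,
                          config$cervix_outer_radius_mm * 0.85)
      ctr <- c(rad * cos(ang), rad * sin(ang))
      e <- sample_ellipse(ctr, config$hole_area_mm2)
      margin <- max(e$semi) + 0.2
      clear_lesion <- all(sa == 0) ||
        (((ctr[1] - les$center_mm[1]) / (sa[1] + margin))^2 +
           ((ctr[2] - les$center_mm[2]) / (sa[2] + margin))^2 > 1)
      inside_viable <- sqrt(sum(ctr^2)) + max(e$semi) <
        outer_radius(atan2(ctr[2], ctr[1]), k, config) - 0.2 &&
        sqrt(sum(ctr^2)) - max(e$semi) > config$canal_radius_mm + 0.2
      if (clear_lesion && inside_viable) holes <- c(holes, list(e))
    }

    artifacts <- list()
    n_try <- 0
    while (length(artifacts) < config$artifact_count && n_try < 200) {
      n_try <- n_try + 1
      ctr <- c(stats::runif(1, -half_w + 0.5, half_w - 0.5),
               stats::runif(1, -half_h + 0.5, half_h - 0.5))
      e <- sample_ellipse(ctr, config$artifact_area_mm2)
      ang <- atan2(ctr[2], ctr[1])
      if (sqrt(sum(ctr^2)) - max(e$semi) >
            outer_radius(ang, k, config) + 0.3) {
        artifacts <- c(artifacts, list(e))
      }
    }

    # --- rendered image in the jittered frame ---
    src <- map_coords(grid_px, transforms[[k]], c(h, w), inverse = TRUE)
    xr <- (src[, 1] - cxp) * px
    yr <- (src[, 2] - cyp) * px
    cls_r <- classify_pixels(xr, yr, k, config)
    if (length(holes) > 0) {
      cls_r[cls_r == 1L & in_any_ellipse(xr, yr, holes)] <- 3L
    }
    if (length(artifacts) > 0) {
      cls_r[cls_r == 0L & in_any_ellipse(xr, yr, artifacts)] <- 4L
    }
    # replayable cleanup edits for the rendered voids: a hole is unstained,
    # so color separation calls it necrotic; the scripted stand-in for the
    # manual correction reassigns it to viable. Polygons live in the
    # rendered (jittered) frame, where segmentation output sits.
    for (e in holes) {
      ang <- seq(0, 2 * pi, length.out = 17)[-17]
      vx <- (e$center[1] + (e$semi[1] + 2 * px) * cos(ang)) / px + cxp
      vy <- (e$center[2] + (e$semi[2] + 2 * px) * sin(ang)) / px + cyp
      poly <- map_coords(cbind(vx, vy), transforms[[k]], c(h, w))
      poly[, 1] <- pmin(pmax(poly[, 1], 1), w)
      poly[, 2] <- pmin(pmax(poly[, 2], 1), h)
      edits <- c(edits, list(edit_op("reassign_to_viable", poly, k)))
    }

    img <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) {
      vals <- colors[cls_r + 1L, ch]
      if (config$stain$noise_sd > 0) {
        vals <- vals + stats::rnorm(length(vals), 0, config$stain$noise_sd)
      }
      img[, , ch] <- matrix(pmin(255, pmax(0, round(vals))), h, w)
    }
    images[[k]] <- section_image(img, index = k, geometry = geometry)
  }

  gt <- structure(
    list(masks = masks,
         necrotic_area_mm2 = nec_area,
         viable_area_mm2 = viab_area,
         transforms = transforms,
         edits = edits,
         config = config, geometry = geometry),
    class = "phantom_ground_truth")
  gt$summary <- ground_truth_summary(gt, geometry)
  list(images = images, ground_truth = gt)
}

#' Formula-true summary of a phantom's ground truth
#'
#' Applies the depth and volume formulas directly to the exact per-slice
#' necrotic areas of the ground truth. This is the recovery target the full
#' image pipeline is scored against.
#'
#' @param gt A `phantom_ground_truth` (or any list with a
#'   `necrotic_area_mm2` vector in sectioning order).
#' @param geometry A [stack_geometry()].
#' @param min_area_mm2 Inclusion threshold passed to [summarize_necrosis()].
#' @return A `necrosis_summary`.
#' @export
ground_truth_summary <- function(gt, geometry, min_area_mm2 = 0.01) {
  if (is.null(gt$necrotic_area_mm2)) {
    stop("ground truth must contain per-slice necrotic areas", call. = FALSE)
  }
  summarize_necrosis(gt$necrotic_area_mm2, geometry, min_area_mm2)
}

#' @export
print.phantom_ground_truth <- function(x, ...) {
  cat("phantom_ground_truth:", length(x$masks), "slices;",
      sum(x$necrotic_area_mm2 > 0), "with necrosis\n")
  print(x$summary)
  invisible(x)
}
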