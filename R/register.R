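#' Registration search parameters
#'
#' @param theta_range_deg Half-width of the coarse rotation sweep.
#' @param theta_step_deg Coarse rotation step.
#' @param theta_refine_deg Fine rotation step around the coarse optimum.
#' @param shift_refine_px Half-width of the local translation refinement.
#' @param shift_step_px Step of the local translation refinement.
#' @param downsample Decimation factor for the coarse rotation sweep.
#' @return A `reg_params` list.
#' @export
reg_params <- function(theta_range_deg = 20, theta_step_deg = 1,
                       theta_refine_deg = 0.1, shift_refine_px = 1,
                       shift_step_px = 0.5, downsample = 4) {
  structure(list(theta_range_deg = theta_range_deg,
                 theta_step_deg = theta_step_deg,
                 theta_refine_deg = theta_refine_deg,
                 shift_refine_px = shift_refine_px,
                 shift_step_px = shift_step_px,
                 downsample = downsample),
            class = "reg_params")
}

mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

mask_centroid <- function(mask) {
  c(mean(col(mask)[mask]), mean(row(mask)[mask]))  # (x, y)
}

as_tissue_mask <- function(x, params = seg_params()) {
  if (inherits(x, "label_masks")) return(x$tissue)
  if (is.logical(x) && is.matrix(x)) return(x)
  if (inherits(x, "section_image") ||
      (is.array(x) && length(dim(x)) == 3)) {
    return(segment_tissue(x, params))
  }
  stop("expected a logical mask, label_masks, or RGB image", call. = FALSE)
}

# Candidate transform for rotation theta: rotate about the image center,
# then translate so the rotated moving centroid lands on the fixed centroid.
centroid_candidate <- function(theta, cen_fixed, cen_moving, dim_hw) {
  ctr <- c((dim_hw[2] + 1) / 2, (dim_hw[1] + 1) / 2)
  rot_cen <- rot_mat(theta) %*% (cen_moving - ctr) + ctr
  rigid_transform(cen_fixed[1] - rot_cen[1], cen_fixed[2] - rot_cen[2], theta)
}

# Principal-axis orientation of a mask (degrees, in (-90, 90]), from central
# second moments; insensitive to isotropic size changes between sections.
mask_orientation <- function(mask) {
  x <- col(mask)[mask]; y <- row(mask)[mask]
  x <- x - mean(x); y <- y - mean(y)
  0.5 * atan2(2 * mean(x * y), mean(x * x) - mean(y * y)) * 180 / pi
}

#' Estimate the rigid transform aligning one section onto another
#'
#' Mask-driven registration of tissue silhouettes: for each candidate
#' rotation the translation is initialized from the centroid difference and
#' scored by tissue-mask overlap (IoU). A coarse sweep on decimated masks
#' brackets the rotation; the rotation is then refined at full resolution,
#' followed by a local translation grid search. Silhouette-based scoring is
#' robust to staining differences between adjacent sections.
#'
#' @param fixed,moving Logical tissue masks (or [label_masks()] /
#'   [section_image()] / RGB arrays, segmented with default parameters).
#' @param search A [reg_params()].
#' @return A `rigid_fit` list: `transform` (mapping `moving` onto `fixed`)
#'   and `iou` (overlap achieved at full resolution).
#' @export
estimate_rigid <- function(fixed, moving, search = reg_params()) {
  fixed <- as_tissue_mask(fixed)
  moving <- as_tissue_mask(moving)
  if (!identical(dim(fixed), dim(moving))) {
    stop("fixed and moving rasters must share dimensions", call. = FALSE)
  }
  if (!any(fixed) || !any(moving)) {
    stop("registration error: empty tissue mask", call. = FALSE)
  }
  dim_hw <- dim(fixed)

  # fast approximate IoU: forward-map the moving mask's pixel coordinates
  # and count hits in the fixed mask (rigid maps are near-bijective on the
  # pixel lattice, so rounding collisions are negligible for scoring)
  h <- dim_hw[1]; w <- dim_hw[2]
  fixed_vec <- as.vector(fixed)
  nf <- sum(fixed)
  mv_pts <- cbind(col(moving)[moving], row(moving)[moving])
  score <- function(tr) {
    p <- map_coords(mv_pts, tr, dim_hw)
    xi <- round(p[, 1]); yi <- round(p[, 2])
    ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    inter <- sum(fixed_vec[(xi[ok] - 1) * h + yi[ok]])
    inter / (nf + sum(ok) - inter)
  }

  # coarse rotation sweep on a decimated point set
  ds <- max(1L, as.integer(search$downsample))
  mv_pts_full <- mv_pts
  mv_pts <- mv_pts_full[seq(1, nrow(mv_pts_full), by = ds), , drop = FALSE]
  cen_f <- mask_centroid(fixed); cen_m <- mask_centroid(moving)
  thetas <- seq(-search$theta_range_deg, search$theta_range_deg,
                by = search$theta_step_deg)
  coarse <- vapply(thetas, function(th) {
    score(centroid_candidate(th, cen_f, cen_m, dim_hw))
  }, numeric(1))
  theta_coarse <- thetas[which.max(coarse)]
  mv_pts <- mv_pts_full

  # principal-axis initializer: sections that differ slightly in size give
  # a flat IoU-vs-rotation plateau, while the second-moment orientation
  # difference stays sharp; prefer it unless the sweep clearly beats it
  theta_pca <- mask_orientation(fixed) - mask_orientation(moving)
  theta_pca <- ((theta_pca + 90) %% 180) - 90
  plateau_eps <- 2e-4
  theta0 <- theta_coarse
  if (abs(theta_pca) <= search$theta_range_deg) {
    s_pca <- score(centroid_candidate(theta_pca, cen_f, cen_m, dim_hw))
    s_coarse <- score(centroid_candidate(theta_coarse, cen_f, cen_m, dim_hw))
    if (s_pca >= s_coarse - 10 * plateau_eps) theta0 <- theta_pca
  }

  # local rotation refinement, kept only if it clearly leaves the plateau
  fine <- seq(theta0 - search$theta_step_deg, theta0 + search$theta_step_deg,
              by = search$theta_refine_deg)
  fine_scores <- vapply(fine, function(th) {
    score(centroid_candidate(th, cen_f, cen_m, dim_hw))
  }, numeric(1))
  s0 <- score(centroid_candidate(theta0, cen_f, cen_m, dim_hw))
  theta <- if (max(fine_scores) > s0 + plateau_eps) {
    fine[which.max(fine_scores)]
  } else theta0

  # local translation refinement around the centroid initializer
  base <- centroid_candidate(theta, cen_f, cen_m, dim_hw)
  offs <- seq(-search$shift_refine_px, search$shift_refine_px,
              by = search$shift_step_px)
  best <- list(transform = base, score = score(base) + plateau_eps)
  for (ox in offs) {
    for (oy in offs) {
      if (ox == 0 && oy == 0) next
      tr <- rigid_transform(base$dx_px + ox, base$dy_px + oy, theta)
      sc <- score(tr)
      if (sc > best$score) best <- list(transform = tr, score = sc)
    }
  }
  structure(list(transform = best$transform,
                 iou = mask_iou(fixed, apply_rigid(moving, best$transform))),
            class = "rigid_fit")
}

#' @export
print.rigid_fit <- function(x, ...) {
  print(x$transform)
  cat(sprintf("  tissue IoU = %.4f\n", x$iou))
  invisible(x)
}

#' Align a stack of sections to a common reference frame
#'
#' Rigid transforms are estimated between consecutive neighbors (adjacent
#' sections are most similar) and chained to bring every slice into the
#' reference slice's frame. Slices with empty tissue are passed through with
#' an identity transform and flagged. Masks are resampled with
#' nearest-neighbor interpolation so labels stay binary; images (if given)
#' with bilinear.
#'
#' @param masks_list List of [label_masks()] in sectioning order.
#' @param reference Index of the reference slice (default: middle).
#' @param images Optional list of [section_image()] to resample alongside.
#' @param search A [reg_params()].
#' @return A list: `masks` (aligned), `images` (aligned or NULL),
#'   `transforms` (per-slice [rigid_transform()] into the reference frame),
#'   `pairwise` (neighbor `rigid_fit`s, named "i->i+1"), `iou` (per-slice
#'   IoU against the reference-frame neighbor estimate), `qc_empty` flags.
#' @export
align_stack <- function(masks_list, reference = NULL, images = NULL,
                        search = reg_params()) {
  n <- length(masks_list)
  stopifnot(n >= 1)
  if (is.null(reference)) reference <- ceiling(n / 2)
  stopifnot(reference >= 1, reference <= n)
  qc_empty <- !vapply(masks_list, function(m) any(m$tissue), logical(1))

  pairwise <- vector("list", max(0, n - 1))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (qc_empty[i] || qc_empty[i + 1]) {
        pairwise[[i]] <- structure(list(transform = rigid_transform(),
                                        iou = NA_real_), class = "rigid_fit")
      } else {
        pairwise[[i]] <- estimate_rigid(masks_list[[i]]$tissue,
                                        masks_list[[i + 1]]$tissue, search)
      }
    }
    names(pairwise) <- paste0(seq_len(n - 1), "->", seq_len(n - 1) + 1)
  }

  transforms <- vector("list", n)
  transforms[[reference]] <- rigid_transform()
  if (reference < n) {
    for (j in seq(reference + 1, n)) {
      transforms[[j]] <- compose_rigid(transforms[[j - 1]],
                                       pairwise[[j - 1]]$transform)
    }
  }
  if (reference > 1) {
    for (j in seq(reference - 1, 1)) {
      transforms[[j]] <- compose_rigid(transforms[[j + 1]],
                                       invert_rigid(pairwise[[j]]$transform))
    }
  }

  aligned <- lapply(seq_len(n), function(j) {
    tr <- transforms[[j]]
    label_masks(apply_rigid(masks_list[[j]]$tissue, tr, "nearest"),
                apply_rigid(masks_list[[j]]$necrosis, tr, "nearest"),
                apply_rigid(masks_list[[j]]$viable, tr, "nearest"))
  })
  aligned_images <- NULL
  if (!is.null(images)) {
    aligned_images <- lapply(seq_len(n), function(j) {
      img <- images[[j]]
      px <- apply_rigid(img$pixels, transforms[[j]], "linear", fill = 255)
      section_image(px, index = img$index, geometry = img$geometry)
    })
  }
  iou <- vapply(seq_len(n), function(j) {
    if (qc_empty[j] || qc_empty[reference]) return(NA_real_)
    mask_iou(aligned[[j]]$tissue, aligned[[reference]]$tissue)
  }, numeric(1))

  list(masks = aligned, images = aligned_images, transforms = transforms,
       pairwise = pairwise, iou = iou, qc_empty = qc_empty,
       reference = reference)
}
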