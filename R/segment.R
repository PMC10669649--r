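#' A single section image
#'
#' @param pixels Numeric array `[rows, cols, 3]` with 8-bit RGB values
#'   (0-255).
#' @param index Ordinal position in sectioning order.
#' @param geometry The [stack_geometry()] the image was acquired under.
#' @return A `section_image` object.
#' @export
section_image <- function(pixels, index = 1L, geometry = stack_geometry()) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop("section image must be an RGB array [rows, cols, 3]", call. = FALSE)
  }
  structure(list(index = as.integer(index), pixels = pixels,
                 geometry = geometry),
            class = "section_image")
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("section_image #%d: %d x %d px\n", x$index, d[1], d[2]))
  invisible(x)
}

#' Per-slice label masks (tissue / necrosis / viable)
#'
#' The three binary masks form an exact partition: necrosis and viable are
#' disjoint and their union is the tissue mask. The constructor enforces the
#' invariant, so it holds after every operation that rebuilds masks
#' through it.
#'
#' @param tissue,necrosis,viable Logical matrices of identical shape.
#' @return A `label_masks` object.
#' @export
label_masks <- function(tissue, necrosis, viable) {
  stopifnot(is.logical(tissue), is.logical(necrosis), is.logical(viable))
  if (!identical(dim(tissue), dim(necrosis)) ||
      !identical(dim(tissue), dim(viable))) {
    stop("masks must share dimensions", call. = FALSE)
  }
  if (any(necrosis & viable)) {
    stop("necrosis and viable masks overlap", call. = FALSE)
  }
  if (!identical(necrosis | viable, tissue)) {
    stop("necrosis and viable masks must partition the tissue mask",
         call. = FALSE)
  }
  structure(list(tissue = tissue, necrosis = necrosis, viable = viable),
            class = "label_masks")
}

#' @export
print.label_masks <- function(x, ...) {
  cat(sprintf("label_masks %d x %d: tissue %d px, necrosis %d px, viable %d px\n",
              nrow(x$tissue), ncol(x$tissue), sum(x$tissue), sum(x$necrosis),
              sum(x$viable)))
  invisible(x)
}

#' Segmentation parameters
#'
#' Background is classified as near-white: low saturation and brighter than
#' a luminance threshold. Hole filling and small-component removal are
#' calibrated in physical area so behavior is resolution independent.
#' Within tissue, a pixel is called viable when it is sufficiently saturated
#' and blue-dominant (blue exceeding red by a margin), matching the blue
#' viability stain against unstained white/gray necrosis.
#'
#' @param bg_luminance_min Minimum mean-channel luminance (0-255) for
#'   background.
#' @param bg_saturation_max Maximum HSV-style saturation for background.
#' @param max_hole_area_mm2 Interior holes up to this area are filled into
#'   the tissue mask (larger openings, e.g. the endocervical canal, are kept).
#' @param min_component_area_mm2 Connected tissue components below this area
#'   are removed as noise.
#' @param viable_saturation_min Minimum saturation for the viable class.
#' @param viable_blue_margin Minimum blue-minus-red excess (0-255) for the
#'   viable class.
#' @return A `seg_params` list.
#' @export
seg_params <- function(bg_luminance_min = 230,
                       bg_saturation_max = 0.15,
                       max_hole_area_mm2 = 0.5,
                       min_component_area_mm2 = 0.05,
                       viable_saturation_min = 0.15,
                       viable_blue_margin = 10) {
  structure(list(bg_luminance_min = bg_luminance_min,
                 bg_saturation_max = bg_saturation_max,
                 max_hole_area_mm2 = max_hole_area_mm2,
                 min_component_area_mm2 = min_component_area_mm2,
                 viable_saturation_min = viable_saturation_min,
                 viable_blue_margin = viable_blue_margin),
            class = "seg_params")
}

rgb_channels <- function(image) {
  px <- if (inherits(image, "section_image")) image$pixels else image
  if (!is.array(px) || length(dim(px)) != 3 || dim(px)[3] != 3) {
    stop("expected an RGB image array [rows, cols, 3]", call. = FALSE)
  }
  list(r = px[, , 1], g = px[, , 2], b = px[, , 3])
}

saturation_luminance <- function(ch) {
  mx <- pmax(ch$r, ch$g, ch$b)
  mn <- pmin(ch$r, ch$g, ch$b)
  list(s = (mx - mn) / pmax(mx, 1), l = (ch$r + ch$g + ch$b) / 3)
}

#' Segment the tissue region of a section image
#'
#' Three steps reproduce the automated part of the workflow: (1) background
#' classification (near-white: low saturation and bright), (2) filling of
#' interior holes up to `max_hole_area_mm2`, (3) removal of connected
#' components smaller than `min_component_area_mm2` (dust, specks). A blank
#' image yields an empty mask. Components are 4-connected.
#'
#' @param image A [section_image()] or RGB array (0-255).
#' @param params A [seg_params()].
#' @param geometry A [stack_geometry()] (defaults to the image's own).
#' @return A logical tissue mask.
#' @export
segment_tissue <- function(image, params = seg_params(), geometry = NULL) {
  if (is.null(geometry)) {
    geometry <- if (inherits(image, "section_image")) image$geometry
                else stack_geometry()
  }
  ch <- rgb_channels(image)
  sl <- saturation_luminance(ch)
  tissue <- !(sl$s <= params$bg_saturation_max & sl$l >= params$bg_luminance_min)

  max_hole_px <- mm2_to_px(params$max_hole_area_mm2, geometry)
  tissue <- fill_small_holes(tissue, max_hole_px)

  min_comp_px <- mm2_to_px(params$min_component_area_mm2, geometry)
  remove_small_components(tissue, min_comp_px)
}

# Fill connected components of the complement that do not touch the image
# border and are at most max_px pixels.
fill_small_holes <- function(mask, max_px) {
  lab <- EBImage::bwlabel((!mask) * 1L)
  if (max(lab) == 0) return(mask)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  fill_ids <- setdiff(which(sizes <= max_px), border)
  if (length(fill_ids) > 0) mask[lab %in% fill_ids] <- TRUE
  mask
}

# Drop connected components smaller than min_px pixels.
remove_small_components <- function(mask, min_px) {
  lab <- EBImage::bwlabel(mask * 1L)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep & mask, nrow(mask), ncol(mask))
}

#' Separate necrotic from viable tissue by color
#'
#' Within the tissue mask, pixels that are sufficiently saturated and
#' blue-dominant (blue stain of metabolically active tissue) are classified
#' viable; all remaining tissue pixels (unstained white/gray) are classified
#' necrotic. The partition invariant holds by construction.
#'
#' @param image A [section_image()] or RGB array.
#' @param tissue Logical tissue mask from [segment_tissue()].
#' @param params A [seg_params()].
#' @return A [label_masks()] object.
#' @export
separate_necrosis <- function(image, tissue, params = seg_params()) {
  ch <- rgb_channels(image)
  sl <- saturation_luminance(ch)
  viable <- tissue & sl$s >= params$viable_saturation_min &
    (ch$b - ch$r) >= params$viable_blue_margin
  label_masks(tissue, tissue & !viable, viable)
}

#' A declarative mask edit
#'
#' Replayable stand-in for the manual corrections of the semi-automated
#' workflow: each edit names an action and a closed polygon (pixel
#' coordinates, columns `x` then `y`).
#'
#' @param action One of `"fill_hole"`, `"remove_region"`,
#'   `"reassign_to_necrosis"`, `"reassign_to_viable"`.
#' @param polygon Numeric matrix (>= 3 rows, 2 columns) of vertices.
#' @param slice_index Slice the edit applies to.
#' @return An `edit_op` object.
#' @export
edit_op <- function(action = c("fill_hole", "remove_region",
                               "reassign_to_necrosis", "reassign_to_viable"),
                    polygon, slice_index = 1L) {
  action <- match.arg(action)
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3 || ncol(polygon) != 2) {
    stop("polygon must have at least 3 vertices (x, y)", call. = FALSE)
  }
  structure(list(action = action, polygon = polygon,
                 slice_index = as.integer(slice_index)),
            class = "edit_op")
}

#' Rasterize a closed polygon to a pixel mask (even-odd rule)
#'
#' Pixel centers inside the polygon are set TRUE.
#'
#' @param polygon Numeric matrix of vertices `(x = col, y = row)`.
#' @param dim_hw Raster dimensions `c(nrow, ncol)`.
#' @return A logical matrix.
#' @export
polygon_mask <- function(polygon, dim_hw) {
  h <- dim_hw[1]; w <- dim_hw[2]
  xs <- polygon[, 1]; ys <- polygon[, 2]
  n <- nrow(polygon)
  px <- rep(seq_len(w), each = h)
  py <- rep(seq_len(h), times = w)
  inside <- rep(FALSE, h * w)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, h, w)
}

#' Apply a list of declarative edits to label masks
#'
#' Edits are applied in order; the tissue/necrosis/viable partition is
#' re-established after every edit. Actions: `fill_hole` adds non-tissue
#' pixels inside the polygon to the tissue mask as viable (holes sit inside
#' viable tissue); `remove_region` removes the polygon from all masks;
#' `reassign_to_necrosis` / `reassign_to_viable` relabel tissue pixels
#' inside the polygon.
#'
#' @param masks A [label_masks()] object.
#' @param edits List of [edit_op()] objects (edits for other slices are
#'   ignored when `slice_index` is given).
#' @param slice_index Slice these masks belong to, matched against each
#'   edit's `slice_index`; `NULL` applies all edits.
#' @return The edited [label_masks()].
#' @export
apply_edits <- function(masks, edits, slice_index = NULL) {
  stopifnot(inherits(masks, "label_masks"))
  if (length(edits) == 0) return(masks)
  dim_hw <- dim(masks$tissue)
  for (i in seq_along(edits)) {
    e <- edits[[i]]
    stopifnot(inherits(e, "edit_op"))
    if (!is.null(slice_index) && e$slice_index != slice_index) next
    if (any(e$polygon[, 1] < 0.5) || any(e$polygon[, 1] > dim_hw[2] + 0.5) ||
        any(e$polygon[, 2] < 0.5) || any(e$polygon[, 2] > dim_hw[1] + 0.5)) {
      stop(sprintf("edit %d: polygon out of image bounds", i), call. = FALSE)
    }
    region <- polygon_mask(e$polygon, dim_hw)
    tissue <- masks$tissue; necrosis <- masks$necrosis; viable <- masks$viable
    if (e$action == "fill_hole") {
      add <- region & !tissue
      tissue <- tissue | add
      viable <- viable | add
    } else if (e$action == "remove_region") {
      tissue <- tissue & !region
      necrosis <- necrosis & !region
      viable <- viable & !region
    } else if (e$action == "reassign_to_necrosis") {
      necrosis <- necrosis | (tissue & region)
      viable <- viable & !region
    } else if (e$action == "reassign_to_viable") {
      viable <- viable | (tissue & region)
      necrosis <- necrosis & !region
    }
    masks <- label_masks(tissue, necrosis, viable)
  }
  masks
}

#' Segment a whole stack of section images
#'
#' @param images List of [section_image()] objects.
#' @param params A [seg_params()].
#' @param geometry A [stack_geometry()].
#' @param edits Optional list of [edit_op()] applied per slice.
#' @return A list of [label_masks()].
#' @export
segment_stack <- function(images, params = seg_params(),
                          geometry = NULL, edits = NULL) {
  lapply(seq_along(images), function(i) {
    tissue <- segment_tissue(images[[i]], params, geometry)
    masks <- separate_necrosis(images[[i]], tissue, params)
    if (!is.null(edits)) masks <- apply_edits(masks, edits, slice_index = i)
    masks
  })
}
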