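#' Necrotic volume from per-section areas
#'
#' Converts ordered per-section necrotic areas into a volume by weighting
#' every section but the last with the full axial increment
#' (thickness + spacing) and the last section with its thickness only:
#' \deqn{V = \sum_{i=1}^{N-1} A_i (t + s) + A_N t}
#' which at the default 20 µm / 500 µm sectioning reads
#' \eqn{\sum_{i=1}^{N-1} A_i \times 0.52 + A_N \times 0.02}. Since
#' 1 mm^3 = 1 µL, areas in mm^2 times lengths in mm give µL directly.
#'
#' Only sections considered to contain necrosis should be passed (see
#' [summarize_necrosis()] for the thresholded convenience wrapper).
#'
#' @param areas_mm2 Necrotic areas in mm^2, in sectioning order.
#' @param geometry A [stack_geometry()].
#' @return Volume in µL.
#' @examples
#' g <- stack_geometry()
#' necrosis_volume(rep(10, 10), g)  # 47.0
#' necrosis_volume(1, g)            # 0.02
#' @export
necrosis_volume <- function(areas_mm2, geometry = stack_geometry()) {
  stopifnot(inherits(geometry, "stack_geometry"))
  if (length(areas_mm2) == 0) return(0)
  if (!is.numeric(areas_mm2) || any(!is.finite(areas_mm2)) || any(areas_mm2 < 0)) {
    stop("necrotic areas must be finite and non-negative", call. = FALSE)
  }
  n <- length(areas_mm2)
  inc <- slice_increment(geometry)
  thick <- geometry$section_thickness_mm
  if (n == 1) return(areas_mm2 * thick)
  sum(areas_mm2[seq_len(n - 1)]) * inc + areas_mm2[n] * thick
}

#' Necrotic depth from the number of affected sections
#'
#' Depth along the sectioning axis spanned by `N` sections containing
#' necrosis: \eqn{N t + (N-1) s}, i.e. `N x 0.02 + (N - 1) x 0.5` mm at the
#' default geometry (equivalently `0.52 N - 0.5`). `N = 0` gives 0.
#'
#' @param n_sections Integer count of sections containing necrosis.
#' @param geometry A [stack_geometry()].
#' @return Depth in mm.
#' @examples
#' necrosis_depth(50)  # 25.5
#' necrosis_depth(25)  # 12.5
#' @export
necrosis_depth <- function(n_sections, geometry = stack_geometry()) {
  stopifnot(inherits(geometry, "stack_geometry"))
  if (length(n_sections) != 1 || !is.finite(n_sections) ||
      n_sections < 0 || n_sections != round(n_sections)) {
    stop("n_sections must be a single non-negative integer", call. = FALSE)
  }
  if (n_sections == 0) return(0)
  n_sections * geometry$section_thickness_mm +
    (n_sections - 1) * geometry$section_spacing_mm
}

#' Summarize a stack of per-section necrotic areas
#'
#' Applies the inclusion rule (a section "contains necrosis" when its
#' measured necrotic area exceeds `min_area_mm2`, a small threshold that
#' suppresses speck noise) and returns the three endpoints: the count N of
#' affected sections, the necrotic depth and the necrotic volume.
#'
#' @param areas_mm2 Per-section necrotic areas in mm^2, in sectioning order
#'   (all sections, included or not).
#' @param geometry A [stack_geometry()].
#' @param min_area_mm2 Inclusion threshold, mm^2.
#' @return A `necrosis_summary` list: `n_sections`, `depth_mm`, `volume_uL`.
#' @export
summarize_necrosis <- function(areas_mm2, geometry = stack_geometry(),
                               min_area_mm2 = 0.01) {
  keep <- areas_mm2 > min_area_mm2
  inc <- areas_mm2[keep]
  structure(
    list(n_sections = sum(keep),
         depth_mm = necrosis_depth(sum(keep), geometry),
         volume_uL = necrosis_volume(inc, geometry)),
    class = "necrosis_summary"
  )
}

#' @export
print.necrosis_summary <- function(x, ...) {
  cat(sprintf("necrosis_summary: N = %d sections, depth = %.1f mm, volume = %.1f uL\n",
              x$n_sections, x$depth_mm, x$volume_uL))
  invisible(x)
}

#' Per-slice areas from label masks
#'
#' @param masks A [label_masks()] object.
#' @param geometry A [stack_geometry()].
#' @return A list with `necrotic_area_mm2`, `viable_area_mm2`,
#'   `tissue_area_mm2`.
#' @export
slice_areas <- function(masks, geometry) {
  stopifnot(inherits(masks, "label_masks"), inherits(geometry, "stack_geometry"))
  pa <- pixel_area_mm2(geometry)
  list(necrotic_area_mm2 = sum(masks$necrosis) * pa,
       viable_area_mm2 = sum(masks$viable) * pa,
       tissue_area_mm2 = sum(masks$tissue) * pa)
}

#' Top-half (hemi-section) necrotic area
#'
#' Finds the area centroid of the slice's tissue mask, draws a horizontal
#' line through the centroid row, and returns the necrotic area strictly
#' above that line (rows with smaller index; row 1 is rendered as the
#' 12 o'clock side). Used to compare a one-sided ablation against the upper
#' half of a whole-organ ablation.
#'
#' @param masks A [label_masks()] object.
#' @param geometry A [stack_geometry()].
#' @return A list with `top_half_necrotic_area_mm2`, `bottom_half_necrotic_area_mm2`,
#'   `centroid_row` (fractional pixel row) and `qc_empty_tissue` flag.
#' @export
top_half_areas <- function(masks, geometry) {
  stopifnot(inherits(masks, "label_masks"), inherits(geometry, "stack_geometry"))
  pa <- pixel_area_mm2(geometry)
  if (!any(masks$tissue)) {
    return(list(top_half_necrotic_area_mm2 = 0,
                bottom_half_necrotic_area_mm2 = 0,
                centroid_row = NA_real_, qc_empty_tissue = TRUE))
  }
  rows <- row(masks$tissue)[masks$tissue]
  cr <- mean(rows)
  nec_rows <- row(masks$necrosis)[masks$necrosis]
  list(top_half_necrotic_area_mm2 = sum(nec_rows < cr) * pa,
       bottom_half_necrotic_area_mm2 = sum(nec_rows >= cr) * pa,
       centroid_row = cr,
       qc_empty_tissue = FALSE)
}

#' Measure a whole stack of label masks
#'
#' @param masks_list List of [label_masks()], in sectioning order.
#' @param geometry A [stack_geometry()].
#' @return A data.frame with one row per slice: `slice_index`,
#'   `necrotic_area_mm2`, `viable_area_mm2`, `tissue_area_mm2`,
#'   `top_half_necrotic_area_mm2`, `centroid_row`, `qc_empty_tissue`.
#' @export
measure_stack <- function(masks_list, geometry) {
  rows <- lapply(seq_along(masks_list), function(i) {
    a <- slice_areas(masks_list[[i]], geometry)
    h <- top_half_areas(masks_list[[i]], geometry)
    data.frame(slice_index = i,
               necrotic_area_mm2 = a$necrotic_area_mm2,
               viable_area_mm2 = a$viable_area_mm2,
               tissue_area_mm2 = a$tissue_area_mm2,
               top_half_necrotic_area_mm2 = h$top_half_necrotic_area_mm2,
               centroid_row = h$centroid_row,
               qc_empty_tissue = h$qc_empty_tissue)
  })
  do.call(rbind, rows)
}

#' Unpaired two-tailed t-test between two treatment groups
#'
#' Compares two groups of endpoint values (e.g. necrotic volumes per animal)
#' with an unpaired two-tailed t-test, either pooled-variance Student's
#' (default) or Welch. Accepts raw per-subject values, or summary statistics
#' (mean, SD, n per group) when only published summaries are available.
#'
#' @param a,b Numeric vectors of per-subject values, or lists
#'   `list(mean =, sd =, n =)` of summary statistics.
#' @param variant `"pooled"` (Student's) or `"welch"`.
#' @return A `group_comparison` list: group means/sds/ns, `t`, `df`,
#'   `p` (two-tailed), `variant`.
#' @examples
#' compare_groups(list(mean = 626.2, sd = 122.8, n = 10),
#'                list(mean = 1292.9, sd = 242.3, n = 10))
#' @export
compare_groups <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stats_a <- as_group_stats(a)
  stats_b <- as_group_stats(b)
  if (stats_a$n < 2 || stats_b$n < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats_a$sd == 0 && stats_b$sd == 0) {
    stop("zero variance in both groups: t statistic undefined", call. = FALSE)
  }
  if (is.numeric(a) && is.numeric(b)) {
    ht <- stats::t.test(a, b, var.equal = (variant == "pooled"),
                        alternative = "two.sided")
    t_stat <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  } else {
    res <- t_from_summary(stats_a, stats_b, pooled = (variant == "pooled"))
    t_stat <- res$t
    df <- res$df
    p <- res$p
  }
  structure(
    list(mean_a = stats_a$mean, sd_a = stats_a$sd, n_a = stats_a$n,
         mean_b = stats_b$mean, sd_b = stats_b$sd, n_b = stats_b$n,
         t = t_stat, df = df, p = p, variant = variant),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group_comparison (%s): %.1f +/- %.1f (n=%d) vs %.1f +/- %.1f (n=%d)\n",
              x$variant, x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b))
  cat(sprintf("  t = %.4f, df = %.2f, two-tailed p = %.3g\n", x$t, x$df, x$p))
  invisible(x)
}

as_group_stats <- function(x) {
  if (is.numeric(x)) {
    list(mean = mean(x), sd = stats::sd(x), n = length(x))
  } else if (is.list(x) && all(c("mean", "sd", "n") %in% names(x))) {
    list(mean = x$mean, sd = x$sd, n = x$n)
  } else {
    stop("group must be a numeric vector or list(mean, sd, n)", call. = FALSE)
  }
}

# Two-sample t from summary statistics; p from the t distribution.
t_from_summary <- function(a, b, pooled = TRUE) {
  if (pooled) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t_stat <- (a$mean - b$mean) / se
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}
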