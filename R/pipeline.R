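#' Configuration for a full analysis run
#'
#' Exactly one input source must be given: either a [phantom_config()] (the
#' stack is simulated) or an input directory of section images.
#'
#' @param phantom A [phantom_config()], or NULL.
#' @param input_dir Directory with numbered section images, or NULL.
#' @param geometry A [stack_geometry()].
#' @param seg A [seg_params()].
#' @param edits Optional list of [edit_op()] (or a JSON edit-log path
#'   written by [write_edit_log()]).
#' @param align Run rigid alignment before quantification.
#' @param reference Reference slice for alignment (default: middle).
#' @param search A [reg_params()].
#' @param min_area_mm2 Necrosis inclusion threshold for the summary.
#' @param mesh Reconstruct and export a necrosis surface mesh.
#' @param mesh_refine Supersampling factor passed to [extract_mesh()];
#'   full-resolution stacks are already finely sampled in-plane, so the
#'   pipeline meshes at native grid resolution by default.
#' @param out_dir Output directory.
#' @param seed Optional integer overriding the phantom config seed.
#' @param force Re-run even if a report already exists in `out_dir`.
#' @return A `run_config` object.
#' @export
run_config <- function(phantom = NULL, input_dir = NULL,
                       geometry = stack_geometry(),
                       seg = seg_params(), edits = NULL,
                       align = TRUE, reference = NULL,
                       search = reg_params(),
                       min_area_mm2 = 0.01, mesh = TRUE, mesh_refine = 1L,
                       out_dir = tempfile("necrovol_run_"),
                       seed = NULL, force = FALSE) {
  if (is.null(phantom) == is.null(input_dir)) {
    stop("exactly one input source required: phantom or input_dir",
         call. = FALSE)
  }
  if (!is.null(input_dir) && !dir.exists(input_dir)) {
    stop("input_dir does not exist: ", input_dir, call. = FALSE)
  }
  if (is.character(edits)) edits <- read_edit_log(edits)
  structure(list(phantom = phantom, input_dir = input_dir,
                 geometry = geometry, seg = seg, edits = edits,
                 align = align, reference = reference, search = search,
                 min_area_mm2 = min_area_mm2, mesh = mesh,
                 mesh_refine = mesh_refine,
                 out_dir = out_dir, seed = seed, force = force),
            class = "run_config")
}

#' Write / read a replayable edit log (JSON)
#'
#' @param edits List of [edit_op()] objects.
#' @param path JSON file path.
#' @export
write_edit_log <- function(edits, path) {
  payload <- lapply(edits, function(e) {
    list(action = e$action, slice_index = e$slice_index,
         polygon = unname(apply(e$polygon, 1, function(r) list(r[1], r[2]),
                                simplify = FALSE)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_edit_log
#' @export
read_edit_log <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(e) {
    poly <- do.call(rbind, lapply(e$polygon, function(p) {
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))
    }))
    edit_op(e$action, poly, e$slice_index)
  })
}

run_stage <- function(name, slice = NA, expr) {
  tryCatch(expr, error = function(err) {
    stop(sprintf("pipeline stage '%s'%s failed: %s", name,
                 if (is.na(slice)) "" else sprintf(" (slice %s)", slice),
                 conditionMessage(err)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' simulate/load -> segment -> (edits) -> align -> quantify -> reconstruct.
#' All stage artifacts are written under `config$out_dir`: section images
#' (for a simulated stack), per-slice masks, the transform log, a per-slice
#' CSV, the summary JSON, and a PLY surface mesh. Every reported number is
#' recomputable from the persisted per-slice CSV with the quantification
#' formulas. Deterministic given the seed. If a report already exists in
#' `out_dir` and `force` is FALSE, the cached report is returned.
#'
#' @param config A [run_config()].
#' @return A `run_report` list: `slices` (per-slice data.frame), `summary`
#'   and `top_summary` ([summarize_necrosis()] of the whole and top-half
#'   areas), `transforms`, `mean_iou`, `qc`, paths of all artifacts,
#'   `ground_truth` (phantom runs only) and a config echo.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  report_path <- file.path(out, "report.json")
  if (file.exists(report_path) && !config$force) {
    rep <- jsonlite::read_json(report_path)
    rep$cached <- TRUE
    class(rep) <- "run_report"
    return(rep)
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  geometry <- config$geometry
  gt <- NULL

  if (!is.null(config$phantom)) {
    pconf <- config$phantom
    if (!is.null(config$seed)) pconf$seed <- as.integer(config$seed)
    sim <- run_stage("simulate", NA, generate_phantom(pconf, geometry))
    images <- sim$images
    gt <- sim$ground_truth
    run_stage("simulate", NA, write_phantom_stack(sim, file.path(out, "images")))
  } else {
    images <- run_stage("load", NA, read_stack(config$input_dir, geometry))
  }
  n <- length(images)

  masks <- vector("list", n)
  for (i in seq_len(n)) {
    masks[[i]] <- run_stage("segment", i, {
      tissue <- segment_tissue(images[[i]], config$seg, geometry)
      m <- separate_necrosis(images[[i]], tissue, config$seg)
      if (!is.null(config$edits)) m <- apply_edits(m, config$edits, i)
      m
    })
  }

  transforms <- replicate(n, rigid_transform(), simplify = FALSE)
  mean_iou <- NA_real_
  qc_empty <- !vapply(masks, function(m) any(m$tissue), logical(1))
  if (config$align && n > 1) {
    al <- run_stage("align", NA,
                    align_stack(masks, reference = config$reference,
                                search = config$search))
    masks <- al$masks
    transforms <- al$transforms
    qc_empty <- al$qc_empty
    mean_iou <- mean(al$iou, na.rm = TRUE)
  }
  dir.create(file.path(out, "masks"), showWarnings = FALSE)
  for (i in seq_len(n)) {
    run_stage("write_masks", i, {
      write_mask_png(masks[[i]]$necrosis,
                     file.path(out, sprintf("masks/necrosis_%03d.png", i)))
      write_mask_png(masks[[i]]$viable,
                     file.path(out, sprintf("masks/viable_%03d.png", i)))
    })
  }
  tr_path <- file.path(out, "transforms.json")
  jsonlite::write_json(lapply(transforms, unclass), tr_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  slices <- run_stage("quantify", NA, measure_stack(masks, geometry))
  csv_path <- file.path(out, "slices.csv")
  utils::write.csv(slices, csv_path, row.names = FALSE)
  summary <- summarize_necrosis(slices$necrotic_area_mm2, geometry,
                                config$min_area_mm2)
  top_summary <- summarize_necrosis(slices$top_half_necrotic_area_mm2,
                                    geometry, config$min_area_mm2)

  mesh_path <- NULL
  if (isTRUE(config$mesh)) {
    mesh_path <- file.path(out, "necrosis.ply")
    run_stage("reconstruct", NA, {
      grid <- build_volume(masks, geometry)
      export_mesh(extract_mesh(grid, refine = config$mesh_refine), mesh_path)
    })
  }

  report <- structure(
    list(n_sections = n,
         summary = unclass(summary),
         top_summary = unclass(top_summary),
         mean_iou = mean_iou,
         qc_empty_slices = which(qc_empty),
         paths = list(out_dir = out, slices_csv = csv_path,
                      transforms = tr_path, mesh = mesh_path,
                      report = report_path),
         aligned = config$align,
         min_area_mm2 = config$min_area_mm2,
         version = as.character(utils::packageVersion("necrovol")),
         cached = FALSE),
    class = "run_report")
  json_report <- report
  json_report$qc_empty_slices <- as.integer(report$qc_empty_slices)
  jsonlite::write_json(unclass(json_report), report_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  report$slices <- slices
  report$transforms <- transforms
  report$masks <- masks
  report$ground_truth <- gt
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("necrovol run report:", x$n_sections, "sections",
      if (isTRUE(x$cached)) "(cached)" else "", "\n")
  cat(sprintf("  whole:    N = %s, depth = %.1f mm, volume = %.1f uL\n",
              x$summary$n_sections, x$summary$depth_mm, x$summary$volume_uL))
  cat(sprintf("  top half: N = %s, depth = %.1f mm, volume = %.1f uL\n",
              x$top_summary$n_sections, x$top_summary$depth_mm,
              x$top_summary$volume_uL))
  invisible(x)
}
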