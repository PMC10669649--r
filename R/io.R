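#' Read an RGB section image (PNG or TIFF)
#'
#' @param path File path; format chosen by extension.
#' @return Numeric array `[rows, cols, 3]`, 0-255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = tiff::readTIFF(path),
              stop("unsupported image format: ", ext,
                   " (supported: png, tif/tiff)", call. = FALSE))
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  a * 255
}

#' Write an RGB section image (PNG or TIFF)
#'
#' @param image A [section_image()] or 0-255 RGB array.
#' @param path File path; format chosen by extension.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "section_image")) image$pixels else image
  a <- px / 255
  a[a < 0] <- 0
  a[a > 1] <- 1
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(a, path),
         tif = , tiff = tiff::writeTIFF(a, path),
         stop("unsupported image format: ", ext,
              " (supported: png, tif/tiff)", call. = FALSE))
  invisible(path)
}

#' Read/write a binary mask as single-channel PNG
#' @param mask Logical matrix.
#' @param path File path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a >= 0.5
}

#' Write a phantom stack to disk
#'
#' Numbered PNG images plus a JSON sidecar holding the geometry, the
#' configuration echo, the per-slice injected transforms and the true
#' per-slice areas; ground-truth masks as single-channel PNGs. The sidecar
#' is labelled synthetic.
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_stack <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  gt <- phantom$ground_truth
  for (k in seq_along(phantom$images)) {
    write_image(phantom$images[[k]],
                file.path(dir, sprintf("section_%03d.png", k)))
    write_mask_png(gt$masks[[k]]$necrosis,
                   file.path(dir, sprintf("truth/necrosis_%03d.png", k)))
    write_mask_png(gt$masks[[k]]$tissue,
                   file.path(dir, sprintf("truth/tissue_%03d.png", k)))
  }
  sidecar <- list(
    type = "synthetic_phantom_stack",
    n_sections = length(phantom$images),
    geometry = unclass(gt$geometry),
    config = unclass(gt$config),
    transforms = lapply(gt$transforms, unclass),
    necrotic_area_mm2 = gt$necrotic_area_mm2,
    viable_area_mm2 = gt$viable_area_mm2,
    summary = unclass(gt$summary))
  jsonlite::write_json(sidecar, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a directory of numbered section images
#'
#' @param dir Directory containing `section_*.png` (or `.tif`) files; other
#'   image files are read in lexicographic order if no numbered files exist.
#' @param geometry A [stack_geometry()].
#' @return A list of [section_image()] objects.
#' @export
read_stack <- function(dir, geometry = stack_geometry()) {
  files <- sort(list.files(dir, pattern = "^section_.*\\.(png|tif|tiff)$",
                           full.names = TRUE))
  if (length(files) == 0) {
    files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                             full.names = TRUE))
  }
  if (length(files) == 0) stop("no section images found in ", dir, call. = FALSE)
  lapply(seq_along(files), function(i) {
    section_image(read_image(files[i]), index = i, geometry = geometry)
  })
}

# ---- mesh IO ----------------------------------------------------------------

#' Export a surface mesh to PLY, STL or OBJ
#'
#' Vertex coordinates are stored as 32-bit floats in PLY and STL (so the two
#' binary formats encode identical geometry); OBJ is plain text. The default
#' is binary little-endian PLY, readable by standard mesh viewers.
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path.
#' @param format `"ply"`, `"stl"` or `"obj"`; default from the extension.
#' @param binary Write binary PLY/STL (OBJ is always text).
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path, format = NULL, binary = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  if (!format %in% c("ply", "stl", "obj")) {
    stop("unsupported mesh format: '", format,
         "' (supported: ply, stl, obj)", call. = FALSE)
  }
  switch(format,
         ply = write_ply(mesh, path, binary = binary),
         stl = write_stl(mesh, path),
         obj = write_obj(mesh, path))
  invisible(path)
}

#' Read a surface mesh written by [export_mesh()]
#'
#' @param path Mesh file (.ply ascii/binary-little-endian, .stl binary,
#'   .obj).
#' @param format Override the extension-derived format.
#' @return A [surface_mesh()]. STL yields an un-merged triangle soup
#'   (3 vertices per face).
#' @export
read_mesh <- function(path, format = NULL) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  switch(format,
         ply = read_ply(path),
         stl = read_stl(path),
         obj = read_obj(path),
         stop("unsupported mesh format: '", format,
              "' (supported: ply, stl, obj)", call. = FALSE))
}

write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  header <- c("ply", paste("format", fmt, "1.0"),
              paste("element vertex", nv),
              "property float x", "property float y", "property float z",
              paste("element face", nf),
              "property list uchar int vertex_indices",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    if (nv > 0) {
      writeBin(as.numeric(t(mesh$vertices)), con, size = 4,
               endian = "little")
    }
    if (nf > 0) {
      ints <- writeBin(as.integer(t(mesh$faces) - 1L), raw(), size = 4,
                       endian = "little")
      per_face <- rbind(matrix(as.raw(3), 1, nf), matrix(ints, 12, nf))
      writeBin(as.vector(per_face), con)
    }
  } else {
    v32 <- float32_round(mesh$vertices)
    if (nv > 0) {
      writeLines(sprintf("%.9g %.9g %.9g", v32[, 1], v32[, 2], v32[, 3]), con)
    }
    if (nf > 0) {
      writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                         mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
    }
  }
  invisible(path)
}

float32_round <- function(x) {
  matrix(readBin(writeBin(as.numeric(x), raw(), size = 4), "numeric",
                 size = 4, n = length(x)), nrow = nrow(x))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(line) == 0) stop("malformed PLY header", call. = FALSE)
  }
  fmt <- sub("^format ([a-z_]+).*$", "\\1", grep("^format", header, value = TRUE))
  nv <- as.integer(sub("^element vertex (\\d+)$", "\\1",
                       grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("^element face (\\d+)$", "\\1",
                       grep("^element face", header, value = TRUE)))
  if (fmt == "binary_little_endian") {
    verts <- if (nv > 0) {
      matrix(readBin(con, "numeric", n = 3 * nv, size = 4,
                     endian = "little"), ncol = 3, byrow = TRUE)
    } else matrix(numeric(0), 0, 3)
    faces <- matrix(integer(0), 0, 3)
    if (nf > 0) {
      raw_faces <- readBin(con, "raw", n = 13 * nf)
      mat <- matrix(raw_faces, 13, nf)
      idx <- readBin(as.vector(mat[2:13, ]), "integer", n = 3 * nf, size = 4,
                     endian = "little")
      faces <- matrix(idx, ncol = 3, byrow = TRUE) + 1L
    }
  } else {
    lines <- readLines(con)
    verts <- if (nv > 0) {
      do.call(rbind, lapply(strsplit(lines[seq_len(nv)], " "),
                            function(p) as.numeric(p[1:3])))
    } else matrix(numeric(0), 0, 3)
    faces <- if (nf > 0) {
      do.call(rbind, lapply(strsplit(lines[nv + seq_len(nf)], " "),
                            function(p) as.integer(p[2:4]) + 1L))
    } else matrix(integer(0), 0, 3)
  }
  surface_mesh(verts, faces)
}

write_stl <- function(mesh, path) {
  nf <- nrow(mesh$faces)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 80), con)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  if (nf > 0) {
    v1 <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
    v2 <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
    v3 <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
    e1 <- v2 - v1; e2 <- v3 - v1
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    len <- sqrt(rowSums(nrm^2))
    nrm <- nrm / ifelse(len > 0, len, 1)
    floats <- t(cbind(nrm, v1, v2, v3))  # 12 floats per face
    fb <- writeBin(as.numeric(floats), raw(), size = 4, endian = "little")
    per_face <- rbind(matrix(fb, 48, nf), matrix(as.raw(0), 2, nf))
    writeBin(as.vector(per_face), con)
  }
  invisible(path)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  nf <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (nf == 0) return(surface_mesh())
  raw_all <- readBin(con, "raw", n = 50 * nf)
  mat <- matrix(raw_all, 50, nf)
  floats <- readBin(as.vector(mat[1:48, ]), "numeric", n = 12 * nf, size = 4,
                    endian = "little")
  fm <- matrix(floats, 12, nf)
  verts <- matrix(0, 3 * nf, 3)
  verts[seq(1, 3 * nf, by = 3), ] <- t(fm[4:6, , drop = FALSE])
  verts[seq(2, 3 * nf, by = 3), ] <- t(fm[7:9, , drop = FALSE])
  verts[seq(3, 3 * nf, by = 3), ] <- t(fm[10:12, , drop = FALSE])
  faces <- matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE)
  surface_mesh(verts, faces)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(mesh$vertices) > 0) {
    writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
  }
  if (nrow(mesh$faces) > 0) {
    writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                       mesh$faces[, 3]), con)
  }
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path)
  vlines <- grep("^v ", lines, value = TRUE)
  flines <- grep("^f ", lines, value = TRUE)
  verts <- if (length(vlines) > 0) {
    do.call(rbind, lapply(strsplit(vlines, "\\s+"),
                          function(p) as.numeric(p[2:4])))
  } else matrix(numeric(0), 0, 3)
  faces <- if (length(flines) > 0) {
    do.call(rbind, lapply(strsplit(flines, "\\s+"), function(p) {
      as.integer(sub("/.*$", "", p[2:4]))
    }))
  } else matrix(integer(0), 0, 3)
  surface_mesh(verts, faces)
}
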