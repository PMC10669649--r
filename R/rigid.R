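#' In-plane rigid transform (translation + rotation about the image center)
#'
#' Serial sections land on the microscope slide at arbitrary positions and
#' orientations; a rigid transform (no scaling or shear, so areas and
#' distances are preserved) is enough to bring them into a common frame.
#' The transform maps a pixel coordinate p = (x, y) (x = column, y = row) to
#' `R(theta) (p - c) + c + (dx, dy)` where c is the image center. Positive
#' theta rotates from the +x axis towards the +y (row) axis.
#'
#' @param dx_px,dy_px Translation in pixels.
#' @param theta_deg Rotation in degrees about the image center.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx_px = 0, dy_px = 0, theta_deg = 0) {
  stopifnot(is.finite(dx_px), is.finite(dy_px), is.finite(theta_deg))
  structure(list(dx_px = dx_px, dy_px = dy_px, theta_deg = theta_deg),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: dx = %.3f px, dy = %.3f px, theta = %.3f deg\n",
              x$dx_px, x$dy_px, x$theta_deg))
  invisible(x)
}

rot_mat <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Compose two rigid transforms
#'
#' `compose_rigid(a, b)` is the transform equivalent to applying `b` first
#' and then `a` (function composition a o b), for a shared image center.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_rigid <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  Ra <- rot_mat(a$theta_deg)
  t_new <- Ra %*% c(b$dx_px, b$dy_px) + c(a$dx_px, a$dy_px)
  rigid_transform(t_new[1], t_new[2], a$theta_deg + b$theta_deg)
}

#' Invert a rigid transform
#' @param x A [rigid_transform()].
#' @return The exact inverse transform.
#' @export
invert_rigid <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  Rinv <- rot_mat(-x$theta_deg)
  t_new <- -Rinv %*% c(x$dx_px, x$dy_px)
  rigid_transform(t_new[1], t_new[2], -x$theta_deg)
}

#' Map pixel coordinates through a rigid transform
#'
#' @param xy A 2-column matrix of (x = col, y = row) coordinates.
#' @param transform A [rigid_transform()].
#' @param dim_hw Image dimensions `c(nrow, ncol)` defining the rotation center.
#' @param inverse Map through the inverse transform instead.
#' @return A 2-column matrix of mapped coordinates.
#' @export
map_coords <- function(xy, transform, dim_hw, inverse = FALSE) {
  cx <- (dim_hw[2] + 1) / 2
  cy <- (dim_hw[1] + 1) / 2
  if (inverse) transform <- invert_rigid(transform)
  R <- rot_mat(transform$theta_deg)
  out <- sweep(xy, 2, c(cx, cy)) %*% t(R)
  sweep(out, 2, c(cx + transform$dx_px, cy + transform$dy_px), `+`)
}

#' Resample a raster under a rigid transform
#'
#' Moves the raster content by the transform: output pixel q takes the input
#' value at the inverse-mapped location. Binary masks should use
#' nearest-neighbor interpolation so labels stay binary; RGB images may use
#' bilinear. Pixels mapped from outside the canvas become `fill`
#' (FALSE / 0 by default).
#'
#' @param raster A logical/numeric matrix, or an array `[rows, cols, channels]`.
#' @param transform A [rigid_transform()].
#' @param interpolation `"nearest"` or `"linear"`.
#' @param fill Value used outside the canvas.
#' @return The resampled raster, same type and shape.
#' @export
apply_rigid <- function(raster, transform,
                        interpolation = c("nearest", "linear"), fill = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(transform, "rigid_transform"))
  if (is.array(raster) && length(dim(raster)) == 3) {
    out <- raster
    for (k in seq_len(dim(raster)[3])) {
      out[, , k] <- apply_rigid(raster[, , k], transform, interpolation, fill)
    }
    return(out)
  }
  stopifnot(is.matrix(raster))
  is_logical <- is.logical(raster)
  if (identical(transform$dx_px, 0) && identical(transform$dy_px, 0) &&
      identical(transform$theta_deg, 0)) {
    return(raster)
  }
  h <- nrow(raster); w <- ncol(raster)
  grid <- cbind(rep(seq_len(w), each = h), rep(seq_len(h), times = w))
  src <- map_coords(grid, transform, c(h, w), inverse = TRUE)
  vals <- if (interpolation == "nearest") {
    xi <- round(src[, 1]); yi <- round(src[, 2])
    ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    v <- rep(as.numeric(fill), h * w)
    v[ok] <- raster[cbind(yi[ok], xi[ok])]
    v
  } else {
    x0 <- floor(src[, 1]); y0 <- floor(src[, 2])
    fx <- src[, 1] - x0; fy <- src[, 2] - y0
    v <- rep(as.numeric(fill), h * w)
    ok <- x0 >= 1 & (x0 + 1) <= w & y0 >= 1 & (y0 + 1) <= h
    if (any(ok)) {
      r <- as.numeric(raster)
      idx <- function(yy, xx) (xx - 1) * h + yy
      v[ok] <- r[idx(y0[ok], x0[ok])] * (1 - fx[ok]) * (1 - fy[ok]) +
        r[idx(y0[ok], x0[ok] + 1)] * fx[ok] * (1 - fy[ok]) +
        r[idx(y0[ok] + 1, x0[ok])] * (1 - fx[ok]) * fy[ok] +
        r[idx(y0[ok] + 1, x0[ok] + 1)] * fx[ok] * fy[ok]
    }
    v
  }
  out <- matrix(vals, h, w)
  if (is_logical) out <- out >= 0.5
  out
}
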