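# Orthographic camera and the world <-> image mappings.
#
# A camera owns an orthonormal frame (right, down, view): `right` maps to +x
# on the image, `down` to +y (pixel y grows downward), `view` points from the
# viewer into the scene.  Depth of a world point p is
# dot(p - center, view) + ez, in [0, 2*ez] inside the camera box.  The
# projection matrix M_prj maps world points to normalized device coordinates
# with the usual y-up convention; the viewport mapping then flips y.

#' Construct an orthographic camera
#'
#' @param world_box 2x3 matrix (min corner / max corner, micrometers) the
#'   camera should frame, e.g. [channel_world_box()] or an `fv_scene`'s
#'   bounds; extents are padded slightly so boundary voxels project inside.
#' @param view_direction direction the viewer looks along (into the scene);
#'   normalized internally.
#' @param viewport `(width, height)` in pixels; `NULL` picks roughly one
#'   pixel per voxel-sized micrometer (capped at 256).
#' @param down world direction that should run down the image; defaults to
#'   +y (or +z when the view is along y).
#' @return an object of class `fv_camera`.
#' @export
ortho_camera <- function(world_box, view_direction = c(0, 0, 1),
                         viewport = NULL, down = NULL) {
  if (sqrt(sum(view_direction^2)) < 1e-12) stop("degenerate camera: zero view direction")
  d <- vnorm(view_direction)
  if (is.null(down)) {
    down <- if (abs(d[2]) > 0.9) c(0, 0, 1) else c(0, 1, 0)
  }
  dn <- down - d * sum(down * d)
  if (sqrt(sum(dn^2)) < 1e-9) stop("'down' direction is parallel to the view direction")
  dn <- vnorm(dn)
  r <- vnorm(cross3(dn, d))
  center <- colMeans(world_box)
  corners <- as.matrix(expand.grid(world_box[, 1], world_box[, 2], world_box[, 3]))
  rel <- sweep(corners, 2, center)
  pad <- 1e-6
  ex <- max(abs(rel %*% r)) + pad
  ey <- max(abs(rel %*% dn)) + pad
  ez <- max(abs(rel %*% d)) + pad
  if (is.null(viewport)) {
    viewport <- pmin(256L, pmax(16L, round(c(2 * ex, 2 * ey))))
  }
  viewport <- as.integer(viewport)
  stopifnot(length(viewport) == 2, all(viewport >= 1))
  # world -> NDC (y up): rows scale the frame axes by the half extents
  M <- rbind(c(r / ex, -sum(r * center) / ex),
             c(-dn / ey, sum(dn * center) / ey),
             c(d / ez, -sum(d * center) / ez),
             c(0, 0, 0, 1))
  structure(list(M_prj = M, viewport = viewport, view_direction = d,
                 right = r, down = dn, center = center,
                 half_extents = c(ex, ey, ez), type = "ortho"),
            class = "fv_camera")
}

#' @export
print.fv_camera <- function(x, ...) {
  cat(sprintf("<fv_camera %s> viewport %dx%d, view (%.3g, %.3g, %.3g)\n",
              x$type, x$viewport[1], x$viewport[2],
              x$view_direction[1], x$view_direction[2], x$view_direction[3]))
  invisible(x)
}

#' Project world points to 2D pixel coordinates
#'
#' The forward projection `p' = M_prj . p` (homogeneous multiply, divide by
#' w) followed by the viewport mapping from NDC `[-1, 1]^2` to pixels
#' (x right, y down).  Voxel membership in a painted 2D region is decided by
#' forward-projecting every voxel and testing its pixel, never by inverting
#' the projection: one image point corresponds to infinitely many 3D points.
#'
#' @param p world point(s), length-3 vector or n x 3 matrix (micrometers).
#' @param camera an `fv_camera`.
#' @return n x 3 matrix with columns `px`, `py` (pixels, fractional) and
#'   `projectable` (0/1; 0 flags points behind a perspective camera,
#'   `w <= 0`).
#' @export
project_voxel <- function(p, camera) {
  stopifnot(inherits(camera, "fv_camera"))
  m <- if (is.matrix(p)) p else matrix(p, nrow = 1)
  ph <- cbind(m, 1) %*% t(camera$M_prj)
  w <- ph[, 4]
  ok <- w > 0
  w[!ok] <- 1
  ndc_x <- ph[, 1] / w
  ndc_y <- ph[, 2] / w
  W <- camera$viewport[1]
  H <- camera$viewport[2]
  cbind(px = (ndc_x + 1) / 2 * W,
        py = (1 - ndc_y) / 2 * H,
        projectable = as.numeric(ok))
}

# Depth (distance along the view direction from the camera near plane) of
# world points; 0 at the near plane, 2*ez at the far plane.
camera_depth <- function(p, camera) {
  m <- if (is.matrix(p)) p else matrix(p, nrow = 1)
  drop(sweep(m, 2, camera$center) %*% camera$view_direction) + camera$half_extents[3]
}

# Per-pixel world positions on the plane at absolute depth `depth`.
# Returns a list of three H x W matrices (x, y, z world coordinates).
pixel_world_grid <- function(camera, depth) {
  W <- camera$viewport[1]
  H <- camera$viewport[2]
  ax <- (((seq_len(W) - 0.5) / W) * 2 - 1) * camera$half_extents[1]
  by <- (((seq_len(H) - 0.5) / H) * 2 - 1) * camera$half_extents[2]
  A <- matrix(ax, H, W, byrow = TRUE)
  B <- matrix(by, H, W)
  td <- depth - camera$half_extents[3]
  lapply(1:3, function(k) {
    camera$center[k] + A * camera$right[k] + B * camera$down[k] + td * camera$view_direction[k]
  })
}
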