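# View-aligned slicing of bricks and per-sample transfer/shading for one
# channel.  Slices are the finest streamed unit: every slice faces the
# observer, so slice-based rendering and ray marching sample the same
# positions along each pixel's ray.

#' Decompose a brick into view-aligned slices
#'
#' Slices are planes perpendicular to the camera view direction, uniformly
#' spaced by `sample_spacing`, ordered front to back, with the first slice at
#' the depth of the brick's nearest corner.  Each slice's polygon is the
#' (convex, 3--6 vertex) intersection of the brick box with the slice plane.
#' Slicing depends only on geometry, never on volume content.
#'
#' @param brick an `fv_brick` from [make_bricks()].
#' @param camera an `fv_camera`.
#' @param sample_spacing slice spacing in micrometers (> 0).
#' @return list of `fv_slice` objects with fields `depth` (absolute camera
#'   depth), `polygon` (k x 3 world vertices), `plane_normal`,
#'   `sample_spacing` and `brick`.
#' @export
compute_view_slices <- function(brick, camera, sample_spacing) {
  stopifnot(inherits(camera, "fv_camera"))
  if (sample_spacing <= 0) stop("sample_spacing must be positive")
  box <- brick$world_box
  corners <- as.matrix(expand.grid(box[, 1], box[, 2], box[, 3]))
  depths_c <- camera_depth(corners, camera)
  dmin <- min(depths_c)
  dmax <- max(depths_c)
  n <- floor((dmax - dmin) / sample_spacing + 1e-9)
  depths <- dmin + sample_spacing * (0:n)
  lapply(depths, function(dep) {
    poly <- box_plane_polygon(box, camera, dep)
    structure(list(depth = dep, polygon = poly,
                   plane_normal = camera$view_direction,
                   sample_spacing = sample_spacing, brick = brick),
              class = "fv_slice")
  })
}

# Convex polygon (3-6 vertices; 4 when the plane coincides with a box face)
# where the plane at absolute camera depth `dep` cuts the axis-aligned box.
box_plane_polygon <- function(box, camera, dep) {
  d <- camera$view_direction
  corners <- as.matrix(expand.grid(box[, 1], box[, 2], box[, 3]))
  f <- camera_depth(corners, camera) - dep
  eps <- 1e-9 * max(1, max(abs(box)))
  verts <- corners[abs(f) <= eps, , drop = FALSE]
  edges <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8),
                 c(1, 3), c(2, 4), c(5, 7), c(6, 8),
                 c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    if (f[a] * f[b] < -eps^2 && abs(f[a]) > eps && abs(f[b]) > eps) {
      t <- f[a] / (f[a] - f[b])
      verts <- rbind(verts, corners[a, ] + t * (corners[b, ] - corners[a, ]))
    }
  }
  if (nrow(verts) == 0) return(matrix(numeric(0), 0, 3))
  verts <- unique(round(verts / eps) * eps)
  if (nrow(verts) < 3) return(verts)
  ctr <- colMeans(verts)
  rel <- sweep(verts, 2, ctr)
  ang <- atan2(rel %*% camera$down, rel %*% camera$right)
  verts[order(ang), , drop = FALSE]
}

# Windowed, gamma-corrected transferred intensity v in [0, 1].
transfer_v <- function(intensity, settings) {
  t <- clamp01((intensity - settings$low_threshold) /
                 (settings$high_threshold - settings$low_threshold))
  t^(1 / settings$gamma)
}

#' Apply a channel's transfer function to one intensity sample
#'
#' The transfer maps intensity through the linear window
#' `[low_threshold, high_threshold]` and the power `1/gamma` to obtain
#' `v`, then `alpha = alpha_scale * v` and premultiplied color
#' `C = alpha * (colormap(v)` or `v * color)`.  In MIP mode the renderer
#' takes the per-ray maximum of `v` and colors it afterward, bypassing
#' opacity accumulation.
#'
#' @param intensity scalar or vector of intensities in `[0, 1]`.
#' @param settings a [render_settings()] object.
#' @return list with components `C` (n x 3 premultiplied color), `alpha`
#'   (length n) and `v` (transferred intensity).
#' @export
apply_transfer <- function(intensity, settings) {
  stopifnot(all(intensity >= 0), all(intensity <= 1))
  v <- transfer_v(intensity, settings)
  alpha <- settings$alpha_scale * v
  base <- if (settings$colormap_enabled) {
    rainbow_colormap(v)
  } else {
    outer(v, settings$color)
  }
  list(C = base * alpha, alpha = alpha, v = v)
}

#' Built-in rainbow colormap
#'
#' Maps `v` in `[0, 1]` from blue (low) through green to red (high); the
#' palette used when a channel's `colormap_enabled` flag is set, giving a
#' quantitative reading of intensity values.
#'
#' @param v numeric vector in `[0, 1]`.
#' @return n x 3 RGB matrix.
#' @export
rainbow_colormap <- function(v) {
  h <- (1 - clamp01(v)) * 2 / 3  # 2/3 = blue, 0 = red
  t(grDevices::col2rgb(grDevices::hsv(h, 1, 1))) / 255
}

#' Depth attenuation factor
#'
#' Darkens samples farther from the viewer: `1 - coefficient *
#' depth_fraction`, multiplied into the sample color (not its opacity).
#'
#' @param depth_fraction relative depth in `[0, 1]` (0 = front of the box).
#' @param coefficient channel `depth_attenuation` setting in `[0, 1]`.
#' @return attenuation factor in `[0, 1]`.
#' @export
depth_attenuation_factor <- function(depth_fraction, coefficient) {
  stopifnot(all(depth_fraction >= 0), all(depth_fraction <= 1),
            coefficient >= 0, coefficient <= 1)
  1 - coefficient * depth_fraction
}

#' Lambertian shading factor at a voxel
#'
#' The normal is the normalized central-difference gradient of the intensity
#' field (pointing out of bright structures); the factor is
#' `ambient + (1 - ambient) * max(0, N . L)`.  With `shadow_strength > 0` the
#' factor is further multiplied by `1 - shadow_strength * A`, where `A` is
#' the opacity accumulated along the ray from the voxel toward the light --
#' a simplified one-ray shadow term.  Flat regions (zero gradient) receive
#' the ambient value only.
#'
#' @param ch an `fv_channel` (with `shading_enabled` in its settings).
#' @param index zero-based voxel index `(i, j, k)`.
#' @param light_direction unit vector pointing from the surface toward the
#'   light.
#' @param settings render settings; defaults to the channel's own.
#' @return scalar factor in `[0, 1]`.
#' @export
shading_factor <- function(ch, index, light_direction, settings = ch$settings) {
  stopifnot(inherits(ch, "fv_channel"))
  if (!settings$shading_enabled) stop("shading_enabled is FALSE for this channel")
  L <- vnorm(light_direction)
  g <- grid_gradient(ch, index)
  gn <- sqrt(sum(g^2))
  lambert <- if (gn < 1e-12) 0 else max(0, sum((-g / gn) * L))
  f <- settings$ambient + (1 - settings$ambient) * lambert
  if (settings$shadow_strength > 0) {
    A <- light_ray_opacity(ch, index, L, settings)
    f <- f * (1 - settings$shadow_strength * A)
  }
  f
}

# Central-difference gradient (per-micrometer) at a grid voxel, one-sided at
# the volume faces.
grid_gradient <- function(ch, index) {
  d <- dim(ch$data)
  i <- index[1] + 1L; j <- index[2] + 1L; k <- index[3] + 1L
  gx <- (ch$data[min(i + 1L, d[1]), j, k] - ch$data[max(i - 1L, 1L), j, k]) /
    ((min(i + 1L, d[1]) - max(i - 1L, 1L)) * ch$spacing[1])
  gy <- (ch$data[i, min(j + 1L, d[2]), k] - ch$data[i, max(j - 1L, 1L), k]) /
    ((min(j + 1L, d[2]) - max(j - 1L, 1L)) * ch$spacing[2])
  gz <- (ch$data[i, j, min(k + 1L, d[3])] - ch$data[i, j, max(k - 1L, 1L)]) /
    ((min(k + 1L, d[3]) - max(k - 1L, 1L)) * ch$spacing[3])
  c(gx, gy, gz)
}

# Accumulated opacity marching from a voxel toward the light.
light_ray_opacity <- function(ch, index, L, settings) {
  step <- min(ch$spacing)
  p <- voxel_to_world(index, ch)
  box <- channel_world_box(ch)
  trans <- 1
  k <- 1
  repeat {
    q <- p + k * step * L
    if (any(q < box[1, ]) || any(q > box[2, ])) break
    vi <- q / ch$spacing - 0.5
    val <- trilinear(ch$data, vi[1], vi[2], vi[3])
    a <- settings$alpha_scale * transfer_v(val, settings)
    trans <- trans * (1 - a)
    k <- k + 1
    if (k > 4 * max(dim(ch$data))) break
  }
  1 - trans
}

# Per-sample shading factors for a whole slice (vectorized analogue of
# shading_factor, without the shadow term unless shadow_strength > 0, in
# which case shadows are sampled per pixel -- the slow path).
slice_shading <- function(ch, xs, ys, zs, settings, light) {
  h <- 0.5
  gx <- (trilinear(ch$data, xs + h, ys, zs) - trilinear(ch$data, xs - h, ys, zs)) /
    (2 * h * ch$spacing[1])
  gy <- (trilinear(ch$data, xs, ys + h, zs) - trilinear(ch$data, xs, ys - h, zs)) /
    (2 * h * ch$spacing[2])
  gz <- (trilinear(ch$data, xs, ys, zs + h) - trilinear(ch$data, xs, ys, zs - h)) /
    (2 * h * ch$spacing[3])
  gn <- sqrt(gx^2 + gy^2 + gz^2)
  nl <- ifelse(gn < 1e-12, 0,
               pmax(0, -(gx * light[1] + gy * light[2] + gz * light[3]) / gn))
  settings$ambient + (1 - settings$ambient) * nl
}

#' Sample one slice of a channel into a viewport-aligned RGBA slab
#'
#' For every viewport pixel whose ray pierces the slice polygon (equivalently
#' whose sample point falls in the brick at the slice depth), the intensity
#' is interpolated trilinearly, passed through the transfer function, depth
#' attenuation and (optionally) shading; pixels outside the polygon are fully
#' transparent.  Sample opacity is corrected for the slice spacing,
#' `alpha' = 1 - (1 - alpha)^(spacing / reference_spacing)`, so renders at
#' different spacings agree.
#'
#' @param ch the `fv_channel` the slice's brick belongs to.
#' @param slice an `fv_slice` from [compute_view_slices()].
#' @param camera the `fv_camera` the slice was computed for.
#' @param reference_spacing spacing at which `alpha` needs no correction;
#'   defaults to the slice's own spacing.
#' @param depth_range absolute depth range (c(front, back)) used to normalize
#'   the depth-attenuation fraction; defaults to the channel box's range.
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @param light_direction light direction for shading; defaults to the
#'   headlight `-view_direction`.
#' @return H x W x 4 premultiplied RGBA array.
#' @export
sample_slice <- function(ch, slice, camera, reference_spacing = slice$sample_spacing,
                         depth_range = NULL, interpolation = c("trilinear", "nearest"),
                         light_direction = NULL) {
  interpolation <- match.arg(interpolation)
  sv <- slice_scalar(ch, slice, camera, interpolation)
  slab_from_values(ch, sv, slice, camera, reference_spacing, depth_range,
                   light_direction)
}

# Interpolated raw intensity over the viewport for one slice.
# Returns list(value = H x W (0 outside the brick), inside = logical H x W,
#              xs, ys, zs = continuous voxel coords of the inside samples).
slice_scalar <- function(ch, slice, camera, interpolation = "trilinear") {
  W <- camera$viewport[1]; H <- camera$viewport[2]
  g <- pixel_world_grid(camera, slice$depth)
  sp <- ch$spacing
  vx <- g[[1]] / sp[1] - 0.5
  vy <- g[[2]] / sp[2] - 0.5
  vz <- g[[3]] / sp[3] - 0.5
  rng <- slice$brick$index_range
  d <- dim(ch$data)
  eps <- 1e-7
  ins <- function(v, lo, hi, n) {
    upper <- if (hi >= n) v <= hi - 0.5 + eps else v < hi - 0.5
    v >= lo - 0.5 - (if (lo <= 0) eps else 0) & upper
  }
  inside <- ins(vx, rng[1, 1], rng[2, 1], d[1]) &
    ins(vy, rng[1, 2], rng[2, 2], d[2]) &
    ins(vz, rng[1, 3], rng[2, 3], d[3])
  value <- matrix(0, H, W)
  if (any(inside)) {
    xs <- vx[inside]; ys <- vy[inside]; zs <- vz[inside]
    if (interpolation == "nearest") {
      xs <- round(xs); ys <- round(ys); zs <- round(zs)
    }
    value[inside] <- trilinear(ch$data, xs, ys, zs)
  } else {
    xs <- ys <- zs <- numeric(0)
  }
  list(value = value, inside = inside, xs = xs, ys = ys, zs = zs)
}

slab_from_values <- function(ch, sv, slice, camera, reference_spacing,
                             depth_range, light_direction) {
  W <- camera$viewport[1]; H <- camera$viewport[2]
  slab <- array(0, c(H, W, 4))
  if (!any(sv$inside)) return(slab)
  st <- ch$settings
  tr <- apply_transfer(sv$value[sv$inside], st)
  a <- tr$alpha
  ratio <- slice$sample_spacing / reference_spacing
  ac <- 1 - (1 - pmin(a, 1 - 1e-12))^ratio
  scale <- ifelse(a > 0, ac / a, 0)
  C <- tr$C * scale
  a <- ac
  if (st$depth_attenuation > 0) {
    if (is.null(depth_range)) {
      box <- channel_world_box(ch)
      corners <- as.matrix(expand.grid(box[, 1], box[, 2], box[, 3]))
      dc <- camera_depth(corners, camera)
      depth_range <- range(dc)
    }
    frac <- clamp01((slice$depth - depth_range[1]) /
                      max(depth_range[2] - depth_range[1], 1e-12))
    C <- C * depth_attenuation_factor(frac, st$depth_attenuation)
  }
  if (st$shading_enabled) {
    light <- if (is.null(light_direction)) -camera$view_direction else vnorm(light_direction)
    f <- slice_shading(ch, sv$xs, sv$ys, sv$zs, st, light)
    C <- C * f
  }
  for (k in 1:3) {
    plane <- matrix(0, H, W)
    plane[sv$inside] <- C[, k]
    slab[, , k] <- plane
  }
  plane <- matrix(0, H, W)
  plane[sv$inside] <- a
  slab[, , 4] <- plane
  slab
}
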