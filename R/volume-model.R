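# Core data model: channels, render settings, bricks, groups, scenes.
#
# Conventions used throughout the package:
#   * volumes are 3D arrays with dim = c(nx, ny, nz); the first array axis is
#     the x axis (fastest-varying in memory), the third is z;
#   * voxel indices are zero-based in all public contracts;
#   * the center of voxel (i, j, k) sits at world position
#     ((i, j, k) + 0.5) * spacing micrometers (voxel-center convention);
#   * brick index ranges are half-open: [x0, x1) x [y0, y1) x [z0, z1).

#' Normalize a raw integer volume to the [0, 1] intensity range
#'
#' Fluorescence microscopy stacks store 8-, 12- or 16-bit counts; 12-bit data
#' (range 0--4095) commonly travels in 16-bit containers, so the bit depth is
#' declared rather than inferred from the data maximum.  Normalization divides
#' by the full-scale value `2^bit_depth - 1` and is exactly reversible via
#' [denormalize_intensity()].
#'
#' @param raw_volume integer-valued array (any shape).
#' @param bit_depth one of 8, 12, 16.
#' @return numeric array of the same shape with values in `[0, 1]`.
#' @examples
#' normalize_intensity(array(4095, c(1, 1, 1)), 12)  # -> 1
#' @export
normalize_intensity <- function(raw_volume, bit_depth) {
  bit_depth <- check_bit_depth(bit_depth)
  full <- 2^bit_depth - 1
  if (any(raw_volume < 0)) stop("raw intensities must be non-negative")
  mx <- max(raw_volume)
  if (mx > full) {
    stop(sprintf("raw value %d exceeds the %d-bit maximum %d", mx, bit_depth, full))
  }
  raw_volume / full
}

#' @rdname normalize_intensity
#' @param volume normalized array in `[0, 1]`.
#' @export
denormalize_intensity <- function(volume, bit_depth) {
  bit_depth <- check_bit_depth(bit_depth)
  round(volume * (2^bit_depth - 1))
}

check_bit_depth <- function(bit_depth) {
  if (!bit_depth %in% c(8, 12, 16)) stop("bit_depth must be 8, 12 or 16")
  as.integer(bit_depth)
}

#' Per-channel render settings
#'
#' Each channel carries its own transfer-function and shading configuration,
#' applied independently of every other channel.
#'
#' @param mode `"DVR"` (semi-transparent direct volume rendering) or `"MIP"`
#'   (per-ray maximum intensity projection).
#' @param color RGB triple in `[0, 1]`; the channel's display color.
#' @param colormap_enabled map transferred intensity through the built-in
#'   rainbow colormap instead of `color`.
#' @param gamma positive; mid-tone contrast, applied as `v^(1/gamma)`.
#' @param low_threshold,high_threshold intensity window in `[0, 1]`,
#'   `low < high`; intensities are windowed linearly before the gamma map
#'   ("contrast" is the window width).
#' @param alpha_scale transparency control in `[0, 1]`; scales sample opacity.
#' @param depth_attenuation coefficient in `[0, 1]` darkening samples farther
#'   from the viewer (0 disables).
#' @param shading_enabled apply Lambertian gradient shading.
#' @param ambient ambient light level used when shading.
#' @param shadow_strength in `[0, 1]`; strength of the simplified light-ray
#'   opacity shadow term (0 disables).
#' @param visible include this channel when rendering a scene.
#' @return an object of class `fv_settings`.
#' @export
render_settings <- function(mode = c("DVR", "MIP"),
                            color = c(1, 1, 1),
                            colormap_enabled = FALSE,
                            gamma = 1,
                            low_threshold = 0,
                            high_threshold = 1,
                            alpha_scale = 1,
                            depth_attenuation = 0,
                            shading_enabled = FALSE,
                            ambient = 0.3,
                            shadow_strength = 0,
                            visible = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(color) == 3, all(color >= 0), all(color <= 1))
  if (gamma <= 0) stop("gamma must be positive")
  if (!(low_threshold >= 0 && high_threshold <= 1 && low_threshold < high_threshold)) {
    stop("thresholds must satisfy 0 <= low < high <= 1")
  }
  stopifnot(alpha_scale >= 0, alpha_scale <= 1,
            depth_attenuation >= 0, depth_attenuation <= 1,
            shadow_strength >= 0, shadow_strength <= 1,
            ambient >= 0, ambient <= 1)
  structure(list(mode = mode, color = as.numeric(color),
                 colormap_enabled = isTRUE(colormap_enabled), gamma = gamma,
                 low_threshold = low_threshold, high_threshold = high_threshold,
                 alpha_scale = alpha_scale, depth_attenuation = depth_attenuation,
                 shading_enabled = isTRUE(shading_enabled), ambient = ambient,
                 shadow_strength = shadow_strength, visible = isTRUE(visible)),
            class = "fv_settings")
}

#' Construct a channel: one grayscale volume plus its render settings
#'
#' A channel is the unit of visualization, streaming and segmentation: a
#' spectrally distinct acquisition, a co-registered scan, or a subvolume
#' extracted by segmentation.
#'
#' @param data 3D numeric array, `dim = c(nx, ny, nz)`, values in `[0, 1]`
#'   (use [normalize_intensity()] on raw integer stacks).
#' @param name channel name.
#' @param bit_depth declared source bit depth (8, 12 or 16).
#' @param spacing voxel spacing `(sx, sy, sz)` in micrometers.
#' @param settings a [render_settings()] object.
#' @return an object of class `fv_channel`.
#' @export
channel <- function(data, name = "channel", bit_depth = 8,
                    spacing = c(1, 1, 1), settings = render_settings()) {
  if (length(dim(data)) != 3) stop("channel data must be a 3D array")
  if (any(dim(data) < 1)) stop("channel dimensions must all be >= 1")
  if (any(spacing <= 0)) stop("spacing must be positive")
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 1) stop("channel data must lie in [0, 1]")
  stopifnot(inherits(settings, "fv_settings"))
  structure(list(name = as.character(name), data = data,
                 bit_depth = check_bit_depth(bit_depth),
                 spacing = as.numeric(spacing), settings = settings),
            class = "fv_channel")
}

#' @export
print.fv_channel <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fv_channel '%s'> %dx%dx%d voxels, %d-bit, spacing (%g, %g, %g) um, mode %s\n",
              x$name, d[1], d[2], d[3], x$bit_depth,
              x$spacing[1], x$spacing[2], x$spacing[3], x$settings$mode))
  invisible(x)
}

#' Axis-aligned world bounding box of a channel
#'
#' @param ch an `fv_channel`.
#' @return 2x3 matrix; row 1 the minimum corner, row 2 the maximum corner (um).
#' @export
channel_world_box <- function(ch) {
  d <- dim(ch$data)
  rbind(lo = c(0, 0, 0), hi = d * ch$spacing)
}

#' Subdivide a channel into axis-aligned bricks
#'
#' Bricks are the middle level of the streaming hierarchy
#' (channel -> brick -> slice).  Half-open index ranges tile the volume
#' exactly; each brick dimension is at most `max_brick_dim`.  Bricks are
#' ordered x-fastest, z-slowest.
#'
#' @param ch an `fv_channel`.
#' @param max_brick_dim maximum brick extent in voxels (>= 2).
#' @return list of `fv_brick` objects, each with `index_range` (2x3,
#'   zero-based half-open `[lo, hi)`) and `world_box` (2x3, micrometers).
#' @export
make_bricks <- function(ch, max_brick_dim = 128) {
  stopifnot(inherits(ch, "fv_channel"))
  if (max_brick_dim < 2) stop("max_brick_dim must be >= 2")
  d <- dim(ch$data)
  splits <- lapply(d, function(n) {
    k <- ceiling(n / max_brick_dim)
    bounds <- round(seq(0, n, length.out = k + 1))
    cbind(bounds[-length(bounds)], bounds[-1])
  })
  bricks <- list()
  for (kz in seq_len(nrow(splits[[3]]))) {
    for (ky in seq_len(nrow(splits[[2]]))) {
      for (kx in seq_len(nrow(splits[[1]]))) {
        lo <- c(splits[[1]][kx, 1], splits[[2]][ky, 1], splits[[3]][kz, 1])
        hi <- c(splits[[1]][kx, 2], splits[[2]][ky, 2], splits[[3]][kz, 2])
        bricks[[length(bricks) + 1L]] <- structure(
          list(index_range = rbind(lo = lo, hi = hi),
               world_box = rbind(lo = lo * ch$spacing, hi = hi * ch$spacing)),
          class = "fv_brick")
      }
    }
  }
  bricks
}

#' Map a voxel index to its world-space center
#'
#' @param index zero-based voxel index `(i, j, k)` (vector or n x 3 matrix).
#' @param ch an `fv_channel`.
#' @return world coordinates in micrometers (same shape as `index`).
#' @export
voxel_to_world <- function(index, ch) {
  stopifnot(inherits(ch, "fv_channel"))
  m <- if (is.matrix(index)) index else matrix(index, nrow = 1)
  d <- dim(ch$data)
  if (any(m < 0) || any(m[, 1] >= d[1]) || any(m[, 2] >= d[2]) || any(m[, 3] >= d[3])) {
    stop("voxel index out of range")
  }
  out <- sweep(m + 0.5, 2, ch$spacing, `*`)
  if (is.matrix(index)) out else drop(out)
}

#' Group channels under their own intermixing mode
#'
#' Groups render to their own buffer with the intra-group mode, then the
#' group buffer is combined with its siblings by the scene mode, which lets
#' e.g. nerves+muscles share true depth occlusion while floating in front of
#' a layered background.
#'
#' @param members list of `fv_channel` objects.
#' @param intermix_mode `"depth"`, `"composite"` or `"layered"`.
#' @param name group name.
#' @return an object of class `fv_group`.
#' @export
channel_group <- function(members, intermix_mode = c("composite", "depth", "layered"),
                          name = "group") {
  intermix_mode <- match.arg(intermix_mode)
  if (length(members) == 0) stop("a group must have at least one member")
  stopifnot(all(vapply(members, inherits, logical(1), "fv_channel")))
  structure(list(members = members, intermix_mode = intermix_mode,
                 name = as.character(name)),
            class = "fv_group")
}

#' Assemble channels and groups into a renderable scene
#'
#' @param items ordered list of `fv_channel` / `fv_group` objects.  In the
#'   layered mode earlier items sit in front of later ones.
#' @param intermix_mode how the items are combined: `"depth"` (true 3D
#'   occlusion; requires co-registered channels), `"composite"` (additive
#'   accumulation) or `"layered"` (ordered superimposition).
#' @param camera an [ortho_camera()]; `NULL` builds a default +z view framing
#'   all items.
#' @param background display background RGB (used at tone-map time).
#' @param sample_spacing slice spacing in micrometers; `NULL` uses the
#'   smallest voxel spacing among the items.
#' @param max_brick_dim brick size used when streaming.
#' @return an object of class `fv_scene`.
#' @export
scene <- function(items, intermix_mode = c("composite", "depth", "layered"),
                  camera = NULL, background = c(0, 0, 0),
                  sample_spacing = NULL, max_brick_dim = 128) {
  intermix_mode <- match.arg(intermix_mode)
  if (inherits(items, "fv_channel") || inherits(items, "fv_group")) items <- list(items)
  if (length(items) == 0) stop("a scene needs at least one channel or group")
  ok <- vapply(items, function(it) inherits(it, "fv_channel") || inherits(it, "fv_group"),
               logical(1))
  if (!all(ok)) stop("scene items must be channels or groups")
  chans <- scene_channels_internal(items)
  if (intermix_mode == "depth") {
    dims <- vapply(chans, function(ch) dim(ch$data), integer(3))
    sps <- vapply(chans, function(ch) ch$spacing, numeric(3))
    if (ncol(dims) > 1 &&
        (any(dims != dims[, 1]) || any(abs(sps - sps[, 1]) > 1e-12))) {
      stop("depth mode requires co-registered channels (equal dimensions and spacing)")
    }
  }
  if (is.null(sample_spacing)) {
    sample_spacing <- min(vapply(chans, function(ch) min(ch$spacing), numeric(1)))
  }
  if (sample_spacing <= 0) stop("sample_spacing must be positive")
  if (is.null(camera)) {
    camera <- ortho_camera(scene_box(items))
  }
  stopifnot(inherits(camera, "fv_camera"))
  structure(list(items = items, intermix_mode = intermix_mode, camera = camera,
                 background = as.numeric(background),
                 sample_spacing = sample_spacing,
                 max_brick_dim = max_brick_dim),
            class = "fv_scene")
}

scene_channels_internal <- function(items) {
  out <- list()
  for (it in items) {
    if (inherits(it, "fv_channel")) out[[length(out) + 1L]] <- it
    else out <- c(out, it$members)
  }
  out
}

scene_box <- function(items) {
  chans <- scene_channels_internal(items)
  boxes <- lapply(chans, channel_world_box)
  lo <- do.call(rbind, lapply(boxes, function(b) b[1, ]))
  hi <- do.call(rbind, lapply(boxes, function(b) b[2, ]))
  rbind(lo = apply(lo, 2, min), hi = apply(hi, 2, max))
}

#' @export
print.fv_scene <- function(x, ...) {
  n <- length(scene_channels_internal(x$items))
  cat(sprintf("<fv_scene> %d item(s), %d channel(s), intermix '%s', viewport %dx%d\n",
              length(x$items), n, x$intermix_mode,
              x$camera$viewport[1], x$camera$viewport[2]))
  invisible(x)
}
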