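# The five compositing operators, the two streaming orders, and the
# triple-buffer protocol that together produce one intermixed HDR image
# from many channels.
#
# FrameBuffers are H x W x 4 arrays of 32-bit-float (double in R)
# premultiplied RGBA.  No value is ever clamped before tone mapping: the
# composite mode deliberately accumulates above 1, and the high-dynamic-range
# result is normalized later by tone_map().

#' Create an empty RGBA frame buffer
#'
#' @param width,height pixel dimensions.
#' @param role one of `"channel"`, `"output"`, `"intermediate"` -- the three
#'   buffer roles of the streamed triple-buffer protocol.
#' @return H x W x 4 zero array with class `fv_framebuffer`.
#' @export
framebuffer <- function(width, height, role = c("output", "channel", "intermediate")) {
  role <- match.arg(role)
  structure(array(0, c(height, width, 4)), class = "fv_framebuffer", role = role)
}

as_framebuffer <- function(x, role = "output") {
  structure(x, class = "fv_framebuffer", role = role)
}

#' Compositing operators
#'
#' The five operators used throughout the pipeline, applied to premultiplied
#' RGBA values:
#' \describe{
#'   \item{front_to_back}{`C_out = (1 - a_dest) * C_source + C_dest`,
#'     `a_out = (1 - a_dest) * a_source + a_dest`.  Blends semitransparent
#'     layers front to back; DVR slice accumulation for one channel
#'     (`dest` holds the layers already in front).}
#'   \item{back_to_front}{`C_out = a_source * C_source + (1 - a_source) *
#'     C_dest`, `a_out = a_source + (1 - a_source) * a_dest`.  Places the
#'     source in front of the destination; the layered intermixing mode.}
#'   \item{addition}{componentwise sum; the composite intermixing mode and
#'     the cross-channel combination within one slice in depth mode.}
#'   \item{maximum}{componentwise max; MIP accumulation for one channel.}
#'   \item{multiplication}{componentwise product (modulation); shading and
#'     shadow effects.}
#' }
#'
#' @param op operator name (see above).
#' @param source,dest RGBA values: length-4 vectors or `... x 4` arrays of
#'   matching shape.
#' @return RGBA of the same shape as the inputs.
#' @export
composite <- function(op, source, dest) {
  ops <- c("front_to_back", "back_to_front", "addition", "maximum", "multiplication")
  if (!op %in% ops) stop(sprintf("unknown compositing operator '%s'", op))
  s <- source; d <- dest
  sv <- is.null(dim(s))
  getc <- function(x, k) if (sv) x[k] else slab_comp(x, k)
  out <- s
  if (op == "addition") {
    out <- s + d
  } else if (op == "maximum") {
    out <- pmax(s, d)
  } else if (op == "multiplication") {
    out <- s * d
  } else if (op == "front_to_back") {
    ad <- getc(d, 4)
    for (k in 1:4) out <- setc(out, k, (1 - ad) * getc(s, k) + getc(d, k), sv)
  } else { # back_to_front
    as_ <- getc(s, 4)
    for (k in 1:3) out <- setc(out, k, as_ * getc(s, k) + (1 - as_) * getc(d, k), sv)
    out <- setc(out, 4, as_ + (1 - as_) * getc(d, 4), sv)
  }
  out
}

slab_comp <- function(x, k) {
  nd <- length(dim(x))
  if (nd == 3) x[, , k] else x[, k]
}

setc <- function(x, k, value, scalar) {
  if (scalar) {
    x[k] <- value
  } else if (length(dim(x)) == 3) {
    x[, , k] <- value
  } else {
    x[, k] <- value
  }
  x
}

# ---------------------------------------------------------------------------
# Streaming

#' Plan the streamed rendering of a scene
#'
#' Orders every (channel, brick, slice) work unit of the visible channels and
#' partitions the sequence into render loops of at most `budget` units.
#' The layered and composite intermixing modes stream channel-major
#' (channel -> brick -> slice); the depth mode streams brick-major
#' (brick -> slice -> channel) with bricks sorted front to back, because all
#' channels must contribute to a slice before the next slice is composited.
#' Loop boundaries fall only at legal interruption points: anywhere between
#' units in channel-major order, and between slices in brick-major order
#' (never inside one slice).
#'
#' @param scn an [scene()].
#' @param order `"channel_major"` or `"brick_major"`; defaults to the order
#'   the scene's intermixing mode requires.
#' @param budget work units (slices sampled) per render loop; `Inf` renders
#'   in one loop.  The budget controls progressive display only -- the final
#'   image is independent of it.
#' @return an `fv_schedule`: data.frame `units` (channel, brick, slice,
#'   one-based), `loop_ends` (unit indices closing each loop), plus the
#'   geometry parameters the executor needs.
#' @export
plan_stream <- function(scn, order = NULL, budget = Inf) {
  stopifnot(inherits(scn, "fv_scene"))
  required <- if (scn$intermix_mode == "depth") "brick_major" else "channel_major"
  if (is.null(order)) order <- required
  if (order != required) {
    stop(sprintf("intermix mode '%s' requires %s streaming", scn$intermix_mode, required))
  }
  if (!(budget >= 1)) stop("budget must be >= 1")
  geom <- scene_geometry(scn)
  nch <- length(geom$channels)
  if (nch == 0) stop("no visible channels to stream")
  units <- NULL
  if (order == "channel_major") {
    rows <- list()
    for (ci in seq_len(nch)) {
      sl <- geom$slices[[ci]]
      for (bi in seq_along(sl)) {
        ns <- length(sl[[bi]])
        rows[[length(rows) + 1L]] <- data.frame(channel = ci, brick = geom$brick_order[[ci]][bi],
                                                slice = seq_len(ns))
      }
    }
    units <- do.call(rbind, rows)
    legal <- rep(TRUE, nrow(units))
  } else {
    # depth mode: co-registered channels share one brick grid and slice set
    sl <- geom$slices[[1]]
    rows <- list()
    for (bi in seq_along(sl)) {
      ns <- length(sl[[bi]])
      rows[[length(rows) + 1L]] <- data.frame(
        channel = rep(seq_len(nch), times = ns),
        brick = geom$brick_order[[1]][bi],
        slice = rep(seq_len(ns), each = nch))
    }
    units <- do.call(rbind, rows)
    # legal interruption points: after the last channel of each slice
    legal <- seq_len(nrow(units)) %% nch == 0
  }
  rownames(units) <- NULL
  n <- nrow(units)
  loop_ends <- integer(0)
  if (is.finite(budget)) {
    i <- 0
    while (i < n) {
      target <- min(i + budget, n)
      nxt <- target
      while (nxt < n && !legal[nxt]) nxt <- nxt + 1
      loop_ends <- c(loop_ends, nxt)
      i <- nxt
    }
  } else {
    loop_ends <- n
  }
  structure(list(units = units, loop_ends = loop_ends, budget = budget,
                 order = order, n_channels = nch),
            class = "fv_schedule")
}

# Shared geometry: visible channels (flattened), bricks sorted front-to-back,
# per-brick slices.
scene_geometry <- function(scn) {
  chans <- Filter(function(ch) ch$settings$visible, scene_channels_internal(scn$items))
  cam <- scn$camera
  slices <- list()
  bricks <- list()
  brick_order <- list()
  for (ci in seq_along(chans)) {
    bl <- make_bricks(chans[[ci]], scn$max_brick_dim)
    dep <- vapply(bl, function(b) min(camera_depth(
      as.matrix(expand.grid(b$world_box[, 1], b$world_box[, 2], b$world_box[, 3])), cam)),
      numeric(1))
    ord <- order(dep)
    bricks[[ci]] <- bl
    brick_order[[ci]] <- ord
    slices[[ci]] <- lapply(ord, function(bi) {
      compute_view_slices(bl[[bi]], cam, scn$sample_spacing)
    })
  }
  if (scn$intermix_mode == "depth" && length(chans) > 1) {
    nb <- vapply(bricks, length, integer(1))
    if (any(nb != nb[1])) stop("depth mode requires identical brick grids across channels")
  }
  list(channels = chans, bricks = bricks, brick_order = brick_order, slices = slices)
}

#' Execute a stream schedule with the triple-buffer protocol
#'
#' Maintains three buffers.  The \emph{channel} buffer accumulates the
#' slices of the channel currently streaming (front-to-back for DVR,
#' maximum for MIP); on channel completion it is intermixed into the
#' \emph{intermediate} buffer (addition for the composite mode; the layered
#' mode places the already-accumulated front layers over the new channel)
#' and cleared.  At each render-loop boundary the \emph{output} buffer shown
#' to the caller is the intermediate buffer composited with the in-progress
#' channel buffer, so partial results from different compositing operators
#' never interfere.  In depth mode the channels' slabs of one slice are
#' combined by addition and slices composite front to back directly into the
#' output.  The final image is independent of the loop budget.
#'
#' @param schedule an `fv_schedule` from [plan_stream()].
#' @param scn the scene the schedule was planned for.
#' @return list with `final` (HDR `fv_framebuffer`) and `snapshots` (list of
#'   per-loop output buffers).
#' @export
execute_stream <- function(schedule, scn) {
  stopifnot(inherits(schedule, "fv_schedule"), inherits(scn, "fv_scene"))
  geom <- scene_geometry(scn)
  if (length(geom$channels) != schedule$n_channels) {
    stop("schedule/scene mismatch: channel count differs")
  }
  if (schedule$order == "brick_major") {
    execute_depth(schedule, scn, geom)
  } else {
    execute_channel_major(schedule, scn, geom)
  }
}

execute_channel_major <- function(schedule, scn, scene_geom) {
  cam <- scn$camera
  W <- cam$viewport[1]; H <- cam$viewport[2]
  units <- schedule$units
  n <- nrow(units)
  depth_ranges <- lapply(scene_geom$channels, function(ch) {
    box <- channel_world_box(ch)
    range(camera_depth(as.matrix(expand.grid(box[, 1], box[, 2], box[, 3])), cam))
  })
  inter <- array(0, c(H, W, 4))
  chan_buf <- array(0, c(H, W, 4))
  mip_v <- NULL
  cur <- 0L
  last_of_channel <- c(units$channel[-1] != units$channel[-n], TRUE)
  if (n == 1) last_of_channel <- TRUE
  snapshots <- list()
  loop_idx <- 1L

  finalize_channel <- function(ch, buf, vmax) {
    if (ch$settings$mode == "MIP") mip_image(ch, vmax, H, W) else buf
  }
  intermix <- function(acc, img) {
    switch(scn$intermix_mode,
           composite = composite("addition", img, acc),
           layered = composite("back_to_front", acc, img),
           stop("unsupported intermix for channel-major execution"))
  }

  for (u in seq_len(n)) {
    ci <- units$channel[u]
    ch <- scene_geom$channels[[ci]]
    if (ci != cur) {
      cur <- ci
      chan_buf[] <- 0
      mip_v <- if (ch$settings$mode == "MIP") matrix(0, H, W) else NULL
    }
    bi <- match(units$brick[u], scene_geom$brick_order[[ci]])
    slice <- scene_geom$slices[[ci]][[bi]][[units$slice[u]]]
    if (ch$settings$mode == "MIP") {
      sv <- slice_scalar(ch, slice, cam)
      vt <- matrix(0, H, W)
      vt[sv$inside] <- transfer_v(sv$value[sv$inside], ch$settings)
      mip_v <- pmax(mip_v, vt)
    } else {
      slab <- sample_slice(ch, slice, cam, reference_spacing = min(ch$spacing),
                           depth_range = depth_ranges[[ci]])
      chan_buf <- composite("front_to_back", slab, chan_buf)
    }
    if (last_of_channel[u]) {
      img <- finalize_channel(ch, chan_buf, mip_v)
      inter <- intermix(inter, img)
      chan_buf[] <- 0
      mip_v <- NULL
      cur <- 0L
    }
    if (loop_idx <= length(schedule$loop_ends) && u == schedule$loop_ends[loop_idx]) {
      out <- inter
      if (cur != 0L) {
        out <- intermix(inter, finalize_channel(ch, chan_buf, mip_v))
      }
      snapshots[[loop_idx]] <- as_framebuffer(out, "output")
      log_msg("DEBUG", "render loop %d/%d complete (%d units)",
              loop_idx, length(schedule$loop_ends), u)
      loop_idx <- loop_idx + 1L
    }
  }
  list(final = as_framebuffer(inter, "output"), snapshots = snapshots)
}

mip_image <- function(ch, vmax, H, W) {
  st <- ch$settings
  a <- st$alpha_scale * vmax
  base <- if (st$colormap_enabled) rainbow_colormap(as.vector(vmax)) else outer(as.vector(vmax), st$color)
  img <- array(0, c(H, W, 4))
  for (k in 1:3) img[, , k] <- matrix(base[, k], H, W) * a
  img[, , 4] <- a
  img
}

execute_depth <- function(schedule, scn, scene_geom) {
  cam <- scn$camera
  W <- cam$viewport[1]; H <- cam$viewport[2]
  chans <- scene_geom$channels
  if (any(vapply(chans, function(ch) ch$settings$mode, character(1)) == "MIP")) {
    stop("depth mode interleaves channels within each slice and supports DVR channels only")
  }
  units <- schedule$units
  n <- nrow(units)
  box <- channel_world_box(chans[[1]])
  depth_range <- range(camera_depth(
    as.matrix(expand.grid(box[, 1], box[, 2], box[, 3])), cam))
  output <- array(0, c(H, W, 4))
  slice_sum <- array(0, c(H, W, 4))
  nch <- length(chans)
  snapshots <- list()
  loop_idx <- 1L
  for (u in seq_len(n)) {
    ci <- units$channel[u]
    ch <- chans[[ci]]
    bi <- match(units$brick[u], scene_geom$brick_order[[1]])
    slice <- scene_geom$slices[[1]][[bi]][[units$slice[u]]]
    slab <- sample_slice(ch, slice, cam, reference_spacing = min(ch$spacing),
                         depth_range = depth_range)
    slice_sum <- composite("addition", slab, slice_sum)
    if (ci == nch) { # last channel of this slice
      output <- composite("front_to_back", slice_sum, output)
      slice_sum[] <- 0
    }
    if (loop_idx <= length(schedule$loop_ends) && u == schedule$loop_ends[loop_idx]) {
      snapshots[[loop_idx]] <- as_framebuffer(output, "output")
      log_msg("DEBUG", "render loop %d/%d complete (%d units)",
              loop_idx, length(schedule$loop_ends), u)
      loop_idx <- loop_idx + 1L
    }
  }
  list(final = as_framebuffer(output, "output"), snapshots = snapshots)
}

#' Render a scene to an HDR frame buffer
#'
#' Groups are rendered recursively: each group streams to its own HDR buffer
#' under its intra-group intermixing mode, then the item buffers are combined
#' with the scene mode in list order.  Scene-level depth intermixing operates
#' on channels directly (a group has no single depth per pixel), so depth
#' scenes must contain channels only.
#'
#' @param scn an [scene()].
#' @param budget render-loop budget in work units (affects progressive
#'   snapshots only, never the final image).
#' @return HDR `fv_framebuffer` (premultiplied RGBA, unclamped).
#' @export
render_scene <- function(scn, budget = Inf) {
  stopifnot(inherits(scn, "fv_scene"))
  has_groups <- any(vapply(scn$items, inherits, logical(1), "fv_group"))
  if (!has_groups) {
    sched <- plan_stream(scn, budget = budget)
    return(execute_stream(sched, scn)$final)
  }
  if (scn$intermix_mode == "depth") {
    stop("depth mode at the scene level requires channels, not groups")
  }
  bufs <- lapply(scn$items, function(it) {
    if (inherits(it, "fv_channel")) {
      sub <- scene(list(it), intermix_mode = "composite", camera = scn$camera,
                   sample_spacing = scn$sample_spacing,
                   max_brick_dim = scn$max_brick_dim)
    } else {
      sub <- scene(it$members, intermix_mode = it$intermix_mode, camera = scn$camera,
                   sample_spacing = scn$sample_spacing,
                   max_brick_dim = scn$max_brick_dim)
    }
    render_scene(sub, budget = budget)
  })
  acc <- bufs[[1]]
  for (i in seq_along(bufs)[-1]) {
    acc <- switch(scn$intermix_mode,
                  composite = composite("addition", bufs[[i]], acc),
                  layered = composite("back_to_front", acc, bufs[[i]]))
  }
  as_framebuffer(acc, "output")
}

#' Render a single channel (convenience wrapper)
#'
#' @param ch an `fv_channel`.
#' @param camera optional `fv_camera`; default frames the channel along +z.
#' @param ... passed to [scene()].
#' @return HDR `fv_framebuffer`.
#' @export
render_channel <- function(ch, camera = NULL, ...) {
  render_scene(scene(list(ch), intermix_mode = "composite", camera = camera, ...))
}
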