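# SOI extraction and quantitative analysis: masked-channel extraction,
# connected components, volumetric size, intensity statistics and ruler
# lengths.  Intensity statistics are reported on the channel's declared raw
# bit-depth scale (a 12-bit scan reads 0-4095), because that is the scale
# biologists compare against acquisition settings.

#' Extract the masked structure into a new channel
#'
#' The new channel keeps the original intensity where the binary mask is
#' true and is zero elsewhere; render settings are copied.  Extraction is
#' conservative: extracted + complement-extracted reconstructs the original
#' voxelwise.
#'
#' @param ch an `fv_channel`.
#' @param mask an `fv_mask` of the same shape.
#' @param name name for the new channel.
#' @return a new `fv_channel`.
#' @export
extract_masked_channel <- function(ch, mask, name = paste0(ch$name, "_soi")) {
  stopifnot(inherits(ch, "fv_channel"), inherits(mask, "fv_mask"))
  if (!identical(dim(mask$u), dim(ch$data))) stop("mask and channel shapes differ")
  b <- binary_mask(mask)
  if (!any(b)) warning("empty mask: extracted channel is all zero")
  channel(ch$data * b, name = name, bit_depth = ch$bit_depth,
          spacing = ch$spacing, settings = ch$settings)
}

#' Label connected components of a binary mask
#'
#' Components are found under 6- or 26-connectivity and labeled 1..K in
#' decreasing voxel-count order (ties broken by the first voxel in scan
#' order, x fastest).  Per-component statistics are computed against the
#' source channel.
#'
#' @param mask an `fv_mask` (or logical 3D array).
#' @param ch the source `fv_channel` (for intensity statistics and spacing).
#' @param connectivity 6 or 26.
#' @return list with `labels` (integer 3D array, 0 = background) and `stats`
#'   (data.frame: id, voxel_count, volume_um3, mean_intensity,
#'   mean_intensity_raw, sum_intensity_raw, and the zero-based bounding-box
#'   columns x0, x1, y0, y1, z0, z1 -- half-open like brick ranges).
#' @export
connected_components <- function(mask, ch = NULL, connectivity = 26) {
  b <- if (inherits(mask, "fv_mask")) binary_mask(mask) else mask
  stopifnot(is.logical(b), length(dim(b)) == 3, connectivity %in% c(6, 26))
  d <- dim(b)
  fg <- which(b)
  labels <- array(0L, d)
  if (length(fg) == 0) {
    return(list(labels = labels, stats = component_stats(integer(0), labels, ch, d)))
  }
  comp_of <- rep(0L, length(fg))
  pos <- arrayInd(fg, d)
  # map linear index -> position in fg
  lookup <- integer(prod(d))
  lookup[fg] <- seq_along(fg)
  offsets <- connectivity_offsets(connectivity)
  edges <- list()
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    q <- sweep(pos, 2, o, `+`)
    ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
      q[, 3] >= 1 & q[, 3] <= d[3]
    if (!any(ok)) next
    qlin <- q[ok, 1] + d[1] * (q[ok, 2] - 1L + d[2] * (q[ok, 3] - 1L))
    nb <- lookup[qlin]
    src <- which(ok)[nb > 0]
    if (length(src)) edges[[length(edges) + 1L]] <- cbind(src, nb[nb > 0])
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  memb <- igraph::components(g)$membership
  # relabel: by voxel count desc, ties by first (scan-order) voxel
  cnt <- tabulate(memb)
  first <- rep(NA_integer_, length(cnt))
  firsts <- tapply(fg, memb, min)
  first[as.integer(names(firsts))] <- as.integer(firsts)
  ord <- order(-cnt, first)
  newlab <- integer(length(cnt))
  newlab[ord] <- seq_along(ord)
  labels[fg] <- newlab[memb]
  list(labels = labels, stats = component_stats(seq_along(ord), labels, ch, d))
}

connectivity_offsets <- function(connectivity) {
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
}

component_stats <- function(ids, labels, ch, d) {
  spacing <- if (is.null(ch)) c(1, 1, 1) else ch$spacing
  vx <- prod(spacing)
  rows <- lapply(ids, function(id) {
    lin <- which(labels == id)
    p <- arrayInd(lin, d)
    mean_n <- if (is.null(ch)) NA_real_ else mean(ch$data[lin])
    full <- if (is.null(ch)) NA_real_ else 2^ch$bit_depth - 1
    data.frame(id = id, voxel_count = length(lin),
               volume_um3 = length(lin) * vx,
               mean_intensity = mean_n,
               mean_intensity_raw = mean_n * full,
               sum_intensity_raw = if (is.null(ch)) NA_real_ else sum(round(ch$data[lin] * full)),
               x0 = min(p[, 1]) - 1L, x1 = max(p[, 1]),
               y0 = min(p[, 2]) - 1L, y1 = max(p[, 2]),
               z0 = min(p[, 3]) - 1L, z1 = max(p[, 3]))
  })
  if (length(rows) == 0) {
    return(data.frame(id = integer(0), voxel_count = integer(0),
                      volume_um3 = numeric(0), mean_intensity = numeric(0),
                      mean_intensity_raw = numeric(0), sum_intensity_raw = numeric(0),
                      x0 = integer(0), x1 = integer(0), y0 = integer(0),
                      y1 = integer(0), z0 = integer(0), z1 = integer(0)))
  }
  do.call(rbind, rows)
}

#' Place a 3D ruler anchor from a 2D click
#'
#' The pixel's view ray is marched through the volume and the anchor is
#' placed at the world position of the maximum transferred intensity along
#' the ray (ties resolved to the sample nearest the viewer), so anchors snap
#' to the visible signal rather than to an arbitrary depth.
#'
#' @param pixel `(px, py)` pixel coordinates within the viewport.
#' @param ch an `fv_channel`.
#' @param camera an `fv_camera`.
#' @param step march step in micrometers; default half the smallest voxel
#'   spacing.
#' @return list with `point` (world coordinates, micrometers) and `placed`
#'   (FALSE when the ray meets no nonzero transferred intensity).
#' @export
place_anchor <- function(pixel, ch, camera, step = min(ch$spacing) / 2) {
  W <- camera$viewport[1]; H <- camera$viewport[2]
  if (pixel[1] < 0 || pixel[1] > W || pixel[2] < 0 || pixel[2] > H) {
    stop("pixel outside the viewport")
  }
  ex <- camera$half_extents
  ndc_x <- pixel[1] / W * 2 - 1
  ndc_y <- pixel[2] / H * 2 - 1
  origin <- camera$center + ndc_x * ex[1] * camera$right +
    ndc_y * ex[2] * camera$down - ex[3] * camera$view_direction
  depths <- seq(0, 2 * ex[3], by = step)
  pts <- matrix(origin, length(depths), 3, byrow = TRUE) +
    outer(depths, camera$view_direction)
  box <- channel_world_box(ch)
  inside <- pts[, 1] >= box[1, 1] & pts[, 1] <= box[2, 1] &
    pts[, 2] >= box[1, 2] & pts[, 2] <= box[2, 2] &
    pts[, 3] >= box[1, 3] & pts[, 3] <= box[2, 3]
  if (!any(inside)) return(list(point = NULL, placed = FALSE))
  vi <- sweep(pts[inside, , drop = FALSE], 2, ch$spacing, `/`) - 0.5
  v <- transfer_v(trilinear(ch$data, vi[, 1], vi[, 2], vi[, 3]), ch$settings)
  if (max(v) <= 0) return(list(point = NULL, placed = FALSE))
  best <- which(v == max(v))[1]  # nearest to the viewer on ties
  list(point = pts[inside, , drop = FALSE][best, ], placed = TRUE)
}

#' Construct a ruler from ordered 3D anchors
#'
#' @param anchors n x 3 matrix of world points (micrometers), n >= 2.
#' @param name ruler name.
#' @return an object of class `fv_ruler`.
#' @export
ruler <- function(anchors, name = "ruler") {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) < 2 || ncol(anchors) != 3) stop("a ruler needs >= 2 anchors (n x 3)")
  structure(list(anchors = anchors, name = name), class = "fv_ruler")
}

#' Polyline length of a ruler in micrometers
#'
#' Sum of Euclidean segment lengths in world space (so anisotropic voxel
#' spacing is already accounted for).  Invariant to reversing the anchors.
#'
#' @param r an [ruler()].
#' @return length in micrometers.
#' @export
ruler_length <- function(r) {
  stopifnot(inherits(r, "fv_ruler"))
  seg <- diff(r$anchors)
  sum(sqrt(rowSums(seg^2)))
}

#' Quantitative report over named structures of interest
#'
#' One row per SOI mask: volume, voxel count, mean intensity on the raw
#' bit-depth scale, and the attached ruler's polyline length where present.
#'
#' @param ch the source `fv_channel`.
#' @param masks named list of `fv_mask` objects sharing the channel shape.
#' @param rulers optional named list of [ruler()]s; matched to masks by name.
#' @return data.frame with columns `id`, `name`, `voxel_count`,
#'   `volume_um3`, `mean_intensity_raw`, `length_um`.
#' @export
soi_report <- function(ch, masks, rulers = list()) {
  stopifnot(inherits(ch, "fv_channel"), length(masks) > 0)
  if (is.null(names(masks))) names(masks) <- paste0("soi", seq_along(masks))
  full <- 2^ch$bit_depth - 1
  vx <- prod(ch$spacing)
  rows <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    stopifnot(inherits(m, "fv_mask"))
    if (!identical(dim(m$u), dim(ch$data))) stop("mask shape differs from channel")
    b <- binary_mask(m)
    n <- sum(b)
    mean_raw <- if (n == 0) NA_real_ else mean(round(ch$data[b] * full))
    len <- if (names(masks)[i] %in% names(rulers)) {
      ruler_length(rulers[[names(masks)[i]]])
    } else {
      NA_real_
    }
    data.frame(id = i, name = names(masks)[i], voxel_count = n,
               volume_um3 = n * vx, mean_intensity_raw = mean_raw,
               length_um = len)
  })
  do.call(rbind, rows)
}
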