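# Freehand 3D segmentation: paint-projection candidate selection,
# histogram-based automatic thresholding, occlusion-aware seed validation by
# backward ray casting, and region growth by morphological diffusion.
#
# The diffusion iterates u' = g * dilate(u) + (1 - g) * u, a monotone
# substitute for anisotropic heat diffusion: because dilate(u) >= u the
# field's energy increases monotonically, so it converges in few iterations
# and never oscillates.

#' A 2D brush stroke: seed and diffusion regions in image space
#'
#' A stroke defines two binary regions on the viewport: the (smaller) seed
#' region where selection seeds originate, and the diffusion region to which
#' the subsequent growth is confined.
#'
#' @param seed_region logical/0-1 matrix (viewport height x width).
#' @param diffusion_region logical/0-1 matrix of the same shape; must
#'   contain the seed region.
#' @param brush_type `"select"`, `"erase"` or `"diffuse"`.
#' @return an object of class `fv_stroke`.
#' @export
brush_stroke <- function(seed_region, diffusion_region = seed_region,
                         brush_type = c("select", "erase", "diffuse")) {
  brush_type <- match.arg(brush_type)
  seed_region <- seed_region > 0
  diffusion_region <- diffusion_region > 0
  if (!identical(dim(seed_region), dim(diffusion_region))) {
    stop("seed and diffusion rasters must have identical dimensions")
  }
  if (any(seed_region & !diffusion_region)) {
    stop("the seed region must be contained in the diffusion region")
  }
  structure(list(seed_region = seed_region, diffusion_region = diffusion_region,
                 brush_type = brush_type),
            class = "fv_stroke")
}

#' A per-channel selection mask
#'
#' Holds the continuous field `u` in `[0, 1]` grown by morphological
#' diffusion; the binary structure-of-interest mask is `u >= 0.5`
#' ([binary_mask()]).  The continuous field is retained so the `diffuse`
#' brush can refine an existing selection.
#'
#' @param u 3D numeric array in `[0, 1]` (or integer dims to create zeros).
#' @return an object of class `fv_mask`.
#' @export
selection_mask <- function(u) {
  if (!is.array(u)) u <- array(0, u)
  if (min(u) < 0 || max(u) > 1) stop("selection field u must lie in [0, 1]")
  structure(list(u = u), class = "fv_mask")
}

#' @rdname selection_mask
#' @param mask an `fv_mask`.
#' @export
binary_mask <- function(mask) {
  stopifnot(inherits(mask, "fv_mask"))
  mask$u >= 0.5
}

#' Morphological-diffusion parameters
#'
#' @param threshold intensity threshold `t` in `[0, 1]`, or `NA` when the
#'   automatic estimate is to be used by [apply_brush()].
#' @param threshold_width width `w` of the smooth threshold ramp: the stop
#'   function's intensity term rises linearly from 0 at `t - w` to 1 at `t`.
#' @param kappa edge-stopping scale: boundaries with gradient magnitude
#'   around `kappa` (intensity units per voxel) halt diffusion.
#' @param neighborhood 26 (3x3x3 box) or 6 (face neighbors) dilation
#'   neighborhood, both including the voxel itself.
#' @param max_iterations iteration cap for [grow_selection()].
#' @param convergence_tol stop when `max |u' - u|` falls below this.
#' @return an object of class `fv_diffusion_params`.
#' @export
diffusion_params <- function(threshold = NA_real_, threshold_width = 0.1,
                             kappa = 0.5, neighborhood = 26,
                             max_iterations = 128, convergence_tol = 1e-4) {
  stopifnot(is.na(threshold) || (threshold >= 0 && threshold <= 1),
            threshold_width > 0, threshold_width <= 1, kappa > 0,
            neighborhood %in% c(6, 26), max_iterations >= 1,
            convergence_tol > 0)
  structure(list(threshold = threshold, threshold_width = threshold_width,
                 kappa = kappa, neighborhood = neighborhood,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol),
            class = "fv_diffusion_params")
}

#' Backward-ray occlusion parameters
#'
#' @param opacity_cutoff in `(0, 1]`: a seed is rejected once the opacity
#'   accumulated between it and the viewer reaches this value.
#' @param step sample spacing along the backward ray (micrometers); `NULL`
#'   uses the channel's smallest voxel spacing.
#' @return an object of class `fv_occlusion_params`.
#' @export
occlusion_params <- function(opacity_cutoff = 0.7, step = NULL) {
  stopifnot(opacity_cutoff > 0, opacity_cutoff <= 1, is.null(step) || step > 0)
  structure(list(opacity_cutoff = opacity_cutoff, step = step),
            class = "fv_occlusion_params")
}

#' Project every voxel and intersect with a painted stroke
#'
#' Each voxel center is forward-projected through the camera ([project_voxel()]);
#' a voxel becomes a seed candidate iff its projection lands on a marked
#' pixel of the stroke's seed region, and enters the diffusion domain
#' likewise.  Every voxel is tested independently.
#'
#' @param ch an `fv_channel`.
#' @param stroke an [brush_stroke()] whose rasters match the camera viewport.
#' @param camera an `fv_camera`.
#' @return list with `seed_candidates` and `diffusion_domain` (n x 3
#'   zero-based voxel index matrices) and `seed_lin` / `domain_lin`
#'   (1-based linear indices into the channel array).
#' @export
select_candidates <- function(ch, stroke, camera) {
  stopifnot(inherits(ch, "fv_channel"), inherits(stroke, "fv_stroke"),
            inherits(camera, "fv_camera"))
  W <- camera$viewport[1]; H <- camera$viewport[2]
  if (!identical(dim(stroke$seed_region), c(H, W))) {
    stop("stroke rasters must match the camera viewport")
  }
  if (!any(stroke$diffusion_region)) {
    warning("empty stroke: no candidates selected")
    empty <- matrix(integer(0), 0, 3)
    return(list(seed_candidates = empty, diffusion_domain = empty,
                seed_lin = integer(0), domain_lin = integer(0)))
  }
  d <- dim(ch$data)
  idx <- arrayInd(seq_len(prod(d)), d) - 1L
  world <- sweep(idx + 0.5, 2, ch$spacing, `*`)
  pr <- project_voxel(world, camera)
  col <- floor(pr[, 1]) + 1L
  row <- floor(pr[, 2]) + 1L
  onscreen <- pr[, 3] > 0 & col >= 1L & col <= W & row >= 1L & row <= H
  hit <- function(raster) {
    sel <- logical(nrow(idx))
    sel[onscreen] <- raster[cbind(row[onscreen], col[onscreen])]
    sel
  }
  seed_sel <- hit(stroke$seed_region)
  dom_sel <- hit(stroke$diffusion_region)
  list(seed_candidates = idx[seed_sel, , drop = FALSE],
       diffusion_domain = idx[dom_sel, , drop = FALSE],
       seed_lin = which(seed_sel), domain_lin = which(dom_sel))
}

#' Automatic threshold from the in-stroke intensity histogram
#'
#' Builds a 256-bin histogram of the candidate intensities, fits a single
#' Gaussian to it via the sample mean and standard deviation, and places the
#' threshold two standard deviations below the mean:
#' `t = max(mean - 2 sd, 0.01)`.  The floor excludes low-intensity noise.
#' With fewer than 16 candidates the supplied fallback threshold is used;
#' with zero spread the degenerate value `mean - 0.01` is returned with a
#' warning.
#'
#' @param ch an `fv_channel`.
#' @param seed_candidates n x 3 zero-based voxel index matrix (or a vector of
#'   intensities).
#' @param fallback manual threshold used when there are fewer than 16
#'   candidates.
#' @return threshold in `[0, 1]`, with attributes `mean`, `sd` (the fitted
#'   Gaussian) and `histogram` (256-bin counts).
#' @export
auto_threshold <- function(ch, seed_candidates, fallback = NA_real_) {
  vals <- if (is.matrix(seed_candidates) && ncol(seed_candidates) == 3) {
    ch$data[seed_candidates + 1L]
  } else {
    as.numeric(seed_candidates)
  }
  if (length(vals) < 16) {
    if (is.na(fallback)) stop("fewer than 16 seed candidates and no manual threshold")
    return(fallback)
  }
  h <- tabulate(pmin(floor(vals * 256) + 1L, 256L), nbins = 256L)
  mu <- mean(vals)
  sg <- stats::sd(vals)
  floor_t <- 0.01
  if (sg == 0) {
    warning("degenerate histogram (zero spread); threshold set just below the peak")
    t <- mu - floor_t
  } else {
    t <- max(mu - 2 * sg, floor_t)
  }
  structure(clamp01(t), mean = mu, sd = sg, histogram = h)
}

#' Validate seeds by backward ray casting
#'
#' From each seed, a ray is cast back toward the viewer, accumulating
#' opacity under the channel's own transfer function ("what you see is what
#' you can pick").  A seed is valid iff the accumulated opacity upon leaving
#' the volume stays below `opacity_cutoff`; occluded structures are thereby
#' protected from accidental selection.
#'
#' @param seeds n x 3 zero-based voxel index matrix.
#' @param ch an `fv_channel`.
#' @param camera an `fv_camera`.
#' @param params an [occlusion_params()] object.
#' @return logical vector: `TRUE` where the seed is visible.
#' @export
occlusion_test <- function(seeds, ch, camera, params = occlusion_params()) {
  if (nrow(seeds) == 0) return(logical(0))
  step <- if (is.null(params$step)) min(ch$spacing) else params$step
  world <- sweep(seeds + 0.5, 2, ch$spacing, `*`)
  back <- -camera$view_direction
  box <- channel_world_box(ch)
  depth <- camera_depth(world, camera)
  kmax <- ceiling((max(depth) - min(camera_depth(
    as.matrix(expand.grid(box[, 1], box[, 2], box[, 3])), camera))) / step) + 1L
  trans <- rep(1, nrow(seeds))
  ref <- min(ch$spacing)
  st <- ch$settings
  for (k in seq_len(kmax)) {
    q <- world + k * step * matrix(back, nrow(seeds), 3, byrow = TRUE)
    inside <- q[, 1] >= box[1, 1] & q[, 1] <= box[2, 1] &
      q[, 2] >= box[1, 2] & q[, 2] <= box[2, 2] &
      q[, 3] >= box[1, 3] & q[, 3] <= box[2, 3]
    if (!any(inside)) break
    vi <- sweep(q[inside, , drop = FALSE], 2, ch$spacing, `/`) - 0.5
    val <- trilinear(ch$data, vi[, 1], vi[, 2], vi[, 3])
    a <- st$alpha_scale * transfer_v(val, st)
    a <- 1 - (1 - pmin(a, 1 - 1e-12))^(step / ref)
    trans[inside] <- trans[inside] * (1 - a)
  }
  (1 - trans) < params$opacity_cutoff
}

#' Diffusion stop function
#'
#' `g(x) = s(I(x)) * e(x)` with the smooth threshold term
#' `s = clamp((I - (t - w)) / w, 0, 1)` and the edge-stopping term
#' `e = exp(-(|grad I| / kappa)^2)` (central-difference gradient in
#' intensity units per voxel).  Diffusion proceeds freely (`g = 1`) inside
#' uniform bright structures and is forbidden (`g = 0`) in background and
#' across sharp boundaries.
#'
#' @param ch an `fv_channel`.
#' @param t intensity threshold in `[0, 1]`.
#' @param params a [diffusion_params()] object (supplies `w` and `kappa`).
#' @return 3D array `g` in `[0, 1]`, same shape as the channel.
#' @export
stop_function <- function(ch, t, params = diffusion_params()) {
  stopifnot(t >= 0, t <= 1)
  I <- ch$data
  w <- params$threshold_width
  s <- clamp01((I - (t - w)) / w)
  gm <- gradient_magnitude(I)
  e <- exp(-(gm / params$kappa)^2)
  s * e
}

# Central-difference gradient magnitude, per voxel step, one-sided at faces.
gradient_magnitude <- function(I) {
  d <- dim(I)
  gsq <- array(0, d)
  for (ax in 1:3) {
    if (d[ax] == 1) next
    up <- shift_array(I, ax, -1L)
    dn <- shift_array(I, ax, 1L)
    # at the faces the shifted copies replicate the edge -> one-sided diff
    g <- (up - dn) / 2
    idx_first <- slice_index(d, ax, 1L)
    idx_last <- slice_index(d, ax, d[ax])
    g[idx_first] <- g[idx_first] * 2
    g[idx_last] <- g[idx_last] * 2
    gsq <- gsq + g^2
  }
  sqrt(gsq)
}

# Shift along axis: by = +1 moves content toward higher indices
# (i.e. result[i] = a[i - 1]); the exposed edge replicates the boundary.
shift_array <- function(a, axis, by) {
  d <- dim(a)
  src <- clamp(seq_len(d[axis]) - by, 1L, d[axis])
  if (axis == 1) a[src, , , drop = FALSE]
  else if (axis == 2) a[, src, , drop = FALSE]
  else a[, , src, drop = FALSE]
}

slice_index <- function(d, axis, at) {
  m <- array(FALSE, d)
  if (axis == 1) m[at, , ] <- TRUE
  else if (axis == 2) m[, at, ] <- TRUE
  else m[, , at] <- TRUE
  m
}

# Grey-level dilation by the chosen neighborhood (both include the center).
dilate_u <- function(u, neighborhood) {
  if (neighborhood == 26) {
    out <- u
    for (ax in 1:3) {
      out <- pmax(out, shift_array(out, ax, 1L), shift_array(out, ax, -1L))
    }
    out
  } else {
    out <- u
    for (ax in 1:3) {
      out <- pmax(out, shift_array(u, ax, 1L), shift_array(u, ax, -1L))
    }
    out
  }
}

#' One morphological-diffusion step
#'
#' `delta(x) = max(u(x + b), b in B)` (grey-level dilation) and
#' `u'(x) = g(x) delta(x) + (1 - g(x)) u(x)`.  Since `delta >= u` and
#' `g` lies in `[0, 1]`, `u' >= u` pointwise: the field's energy can only
#' grow, which is what makes the scheme converge quickly.
#'
#' @param u 3D field in `[0, 1]`.
#' @param g stop-function field, same shape.
#' @param neighborhood 26 or 6.
#' @return updated field `u'`.
#' @export
diffusion_step <- function(u, g, neighborhood = 26) {
  stopifnot(identical(dim(u), dim(g)), neighborhood %in% c(6, 26))
  delta <- dilate_u(u, neighborhood)
  g * delta + (1 - g) * u
}

#' Grow validated seeds into a selection mask
#'
#' Starts from `u = 1` on the seeds and iterates [diffusion_step()] with the
#' stop function forced to zero outside the diffusion domain, until the
#' maximum pointwise change drops below `convergence_tol` or
#' `max_iterations` is reached.  The selection therefore spreads only
#' through connected, above-threshold, low-gradient voxels painted by the
#' stroke.
#'
#' @param seeds n x 3 zero-based voxel index matrix (non-empty).
#' @param ch an `fv_channel`.
#' @param diffusion_domain n x 3 index matrix, or 1-based linear indices, or
#'   a logical array; growth is confined to it.
#' @param params a [diffusion_params()] with a numeric `threshold`.
#' @param g optional precomputed stop function (3D array); overrides the
#'   threshold-based computation.
#' @return an `fv_mask`; its `u` field records the continuous selection.
#' @export
grow_selection <- function(seeds, ch, diffusion_domain, params = diffusion_params(),
                           g = NULL) {
  if (is.matrix(seeds)) {
    if (nrow(seeds) == 0) stop("grow_selection requires at least one seed")
    seed_lin <- as.integer(seeds[, 1] + 1L +
                             dim(ch$data)[1] * (seeds[, 2] + dim(ch$data)[2] * seeds[, 3]))
  } else {
    seed_lin <- as.integer(seeds)
    if (length(seed_lin) == 0) stop("grow_selection requires at least one seed")
  }
  d <- dim(ch$data)
  dom <- domain_logical(diffusion_domain, d)
  if (is.null(g)) {
    if (is.na(params$threshold)) stop("diffusion_params$threshold must be set (or pass g)")
    g <- stop_function(ch, params$threshold, params)
  }
  g[!dom] <- 0
  u <- array(0, d)
  u[seed_lin] <- 1
  for (it in seq_len(params$max_iterations)) {
    un <- diffusion_step(u, g, params$neighborhood)
    if (max(un - u) < params$convergence_tol) {
      u <- un
      break
    }
    u <- un
  }
  selection_mask(u)
}

domain_logical <- function(diffusion_domain, d) {
  if (is.logical(diffusion_domain) && is.array(diffusion_domain)) {
    stopifnot(identical(dim(diffusion_domain), d))
    return(diffusion_domain)
  }
  dom <- array(FALSE, d)
  if (is.matrix(diffusion_domain)) {
    if (nrow(diffusion_domain) > 0) dom[diffusion_domain + 1L] <- TRUE
  } else {
    dom[as.integer(diffusion_domain)] <- TRUE
  }
  dom
}

#' Apply a brush stroke to a selection mask
#'
#' The three brush types:
#' \describe{
#'   \item{select}{the full pipeline -- candidates by projection, automatic
#'     (or manual) threshold, occlusion validation of seeds, morphological
#'     diffusion -- and union with the existing mask.}
#'   \item{erase}{clears the field at every voxel projecting into the
#'     stroke's diffusion region (occlusion-blind).}
#'   \item{diffuse}{re-grows from the existing mask restricted to the
#'     diffusion domain: refinement without new seeds.}
#' }
#'
#' @param mask an `fv_mask` (the channel's current selection).
#' @param stroke an [brush_stroke()].
#' @param ch the `fv_channel` being segmented.
#' @param camera an `fv_camera`.
#' @param params a [diffusion_params()]; its `threshold` field is the manual
#'   threshold, used when `threshold = "manual"`.
#' @param occlusion an [occlusion_params()].
#' @param threshold `"auto"` (histogram-based) or `"manual"` (use
#'   `params$threshold`).
#' @return the updated `fv_mask`.
#' @export
apply_brush <- function(mask, stroke, ch, camera, params = diffusion_params(),
                        occlusion = occlusion_params(),
                        threshold = c("auto", "manual")) {
  stopifnot(inherits(mask, "fv_mask"), inherits(stroke, "fv_stroke"))
  threshold <- match.arg(threshold)
  if (!identical(dim(mask$u), dim(ch$data))) stop("mask and channel shapes differ")
  cand <- select_candidates(ch, stroke, camera)
  if (length(cand$domain_lin) == 0) return(mask)

  if (stroke$brush_type == "erase") {
    u <- mask$u
    u[cand$domain_lin] <- 0
    return(selection_mask(u))
  }

  if (stroke$brush_type == "select") {
    if (length(cand$seed_lin) == 0) {
      warning("stroke seed region selects no voxels; mask unchanged")
      return(mask)
    }
    t <- if (threshold == "auto") {
      as.numeric(auto_threshold(ch, cand$seed_candidates, fallback = params$threshold))
    } else {
      if (is.na(params$threshold)) stop("manual threshold requested but params$threshold is NA")
      params$threshold
    }
    keep <- ch$data[cand$seed_lin] >= t
    seeds <- cand$seed_candidates[keep, , drop = FALSE]
    if (nrow(seeds) > 0) {
      valid <- occlusion_test(seeds, ch, camera, occlusion)
      seeds <- seeds[valid, , drop = FALSE]
    }
    if (nrow(seeds) == 0) {
      warning("no valid seeds after thresholding/occlusion; mask unchanged")
      return(mask)
    }
    p2 <- params
    p2$threshold <- t
    grown <- grow_selection(seeds, ch, cand$domain_lin, p2)
    return(selection_mask(pmax(mask$u, grown$u)))
  }

  # diffuse: refine from existing mask within the stroke
  dom <- domain_logical(cand$domain_lin, dim(ch$data))
  seed_log <- binary_mask(mask) & dom
  if (!any(seed_log)) return(mask)
  seed_lin <- which(seed_log)
  t <- if (threshold == "auto") {
    as.numeric(auto_threshold(ch, ch$data[seed_lin], fallback = params$threshold))
  } else {
    if (is.na(params$threshold)) stop("manual threshold requested but params$threshold is NA")
    params$threshold
  }
  p2 <- params
  p2$threshold <- t
  grown <- grow_selection(seed_lin, ch, cand$domain_lin, p2)
  selection_mask(pmax(mask$u, grown$u))
}
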