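# Independent brute-force oracles the pipeline is checked against.  These
# deliberately share no code with the slice-based renderer or the diffusion
# solver: rays are marched point by point, flood fill runs a queue-based BFS.

# Multichannel front-to-back ray marcher: at every step along each pixel's
# ray, all channels are sampled, transferred and summed, then composited
# front to back.  With a single channel this is the classic DVR ray caster.
oracle_ray_march <- function(channels, cam, spacing = 1) {
  W <- cam$viewport[1]; H <- cam$viewport[2]
  ex <- cam$half_extents
  out <- array(0, c(H, W, 4))
  depths <- seq(0, 2 * ex[3], by = spacing)
  for (py in seq_len(H)) {
    for (px in seq_len(W)) {
      ndx <- ((px - 0.5) / W) * 2 - 1
      ndy <- ((py - 0.5) / H) * 2 - 1
      o <- cam$center + ndx * ex[1] * cam$right + ndy * ex[2] * cam$down -
        ex[3] * cam$view_direction
      acc <- c(0, 0, 0, 0)
      for (d in depths) {
        p <- o + d * cam$view_direction
        s <- c(0, 0, 0, 0)
        any_in <- FALSE
        for (ch in channels) {
          dd <- dim(ch$data)
          vi <- p / ch$spacing - 0.5
          if (any(vi < -0.5 - 1e-5) || any(vi > dd - 0.5 + 1e-5)) next
          any_in <- TRUE
          st <- ch$settings
          val <- fluovol:::trilinear(ch$data, vi[1], vi[2], vi[3])
          t <- min(max((val - st$low_threshold) /
                         (st$high_threshold - st$low_threshold), 0), 1)
          v <- t^(1 / st$gamma)
          a <- st$alpha_scale * v
          # opacity corrected for the marching step, color premultiplied by it
          a <- 1 - (1 - min(a, 1 - 1e-12))^(spacing / min(ch$spacing))
          s <- s + c(a * v * st$color, a)
        }
        if (!any_in) next
        acc[1:3] <- acc[1:3] + (1 - acc[4]) * s[1:3]
        acc[4] <- acc[4] + (1 - acc[4]) * s[4]
      }
      out[py, px, ] <- acc
    }
  }
  out
}

# Per-pixel maximum of transferred intensity along each ray.
oracle_mip_v <- function(ch, cam, spacing = 1) {
  W <- cam$viewport[1]; H <- cam$viewport[2]
  ex <- cam$half_extents
  out <- matrix(0, H, W)
  depths <- seq(0, 2 * ex[3], by = spacing)
  dd <- dim(ch$data)
  st <- ch$settings
  for (py in seq_len(H)) {
    for (px in seq_len(W)) {
      ndx <- ((px - 0.5) / W) * 2 - 1
      ndy <- ((py - 0.5) / H) * 2 - 1
      o <- cam$center + ndx * ex[1] * cam$right + ndy * ex[2] * cam$down -
        ex[3] * cam$view_direction
      best <- 0
      for (d in depths) {
        p <- o + d * cam$view_direction
        vi <- p / ch$spacing - 0.5
        if (any(vi < -0.5 - 1e-5) || any(vi > dd - 0.5 + 1e-5)) next
        val <- fluovol:::trilinear(ch$data, vi[1], vi[2], vi[3])
        t <- min(max((val - st$low_threshold) /
                       (st$high_threshold - st$low_threshold), 0), 1)
        best <- max(best, t^(1 / st$gamma))
      }
      out[py, px] <- best
    }
  }
  out
}

# Queue-based flood fill from seeds over the TRUE voxels of `open`.
oracle_flood_fill <- function(open, seeds_lin, neighborhood = 26) {
  d <- dim(open)
  offs <- if (neighborhood == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
  visited <- array(FALSE, d)
  queue <- seeds_lin[open[seeds_lin]]
  visited[queue] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[1]
    queue <- queue[-1]
    pos <- arrayInd(cur, d)
    for (r in seq_len(nrow(offs))) {
      q <- pos + offs[r, ]
      if (any(q < 1) || any(q > d)) next
      lin <- q[1] + d[1] * (q[2] - 1 + d[2] * (q[3] - 1))
      if (open[lin] && !visited[lin]) {
        visited[lin] <- TRUE
        queue <- c(queue, lin)
      }
    }
  }
  visited
}

# Small random sparse test channel.
sparse_channel <- function(dims = c(16, 16, 16), n = 300, seed = 1,
                           settings = render_settings(alpha_scale = 0.7)) {
  set.seed(seed)
  v <- array(0, dims)
  v[sample(prod(dims), n)] <- runif(n, 0.3, 1)
  channel(v, settings = settings)
}

# Standard small camera framing a box of the given dims (unit spacing).
box_camera <- function(dims, viewport = dims[1:2], view = c(0, 0, 1)) {
  ortho_camera(rbind(c(0, 0, 0), dims), view_direction = view,
               viewport = viewport)
}

# The single-stroke tube selection scenario shared by the segmentation tests
# and the acceptance suite: paint a sweep covering the tube footprint with a
# small central seed patch, grow with a manual threshold.
tube_selection_scenario <- function(seed = 7) {
  g <- gen_tube(seed = seed)
  ch <- g$channel
  cam <- ortho_camera(channel_world_box(ch), viewport = c(64, 64))
  pr <- project_voxel(sweep(which(g$truth, arr.ind = TRUE) - 1 + 0.5, 2,
                            ch$spacing, `*`), cam)
  diffusion <- matrix(FALSE, 64, 64)
  diffusion[cbind(floor(pr[, 2]) + 1, floor(pr[, 1]) + 1)] <- TRUE
  for (i in 1:2) { # dilate the footprint like a generous brush sweep
    d2 <- diffusion
    d2[-1, ] <- d2[-1, ] | diffusion[-64, ]
    d2[-64, ] <- d2[-64, ] | diffusion[-1, ]
    d2[, -1] <- d2[, -1] | diffusion[, -64]
    d2[, -64] <- d2[, -64] | diffusion[, -1]
    diffusion <- d2
  }
  seed_r <- matrix(FALSE, 64, 64)
  seed_r[28:36, 28:36] <- diffusion[28:36, 28:36]
  list(gen = g, channel = ch, camera = cam,
       stroke = brush_stroke(seed_r, diffusion, "select"),
       erase_stroke = brush_stroke(seed_r, diffusion, "erase"),
       params = diffusion_params(threshold = 0.3, kappa = 1.0))
}

# BFS eccentricity of the seeds in the open-voxel graph: the number of
# dilation fronts needed to cover the reachable set.
graph_diameter_bound <- function(open, seeds) {
  d <- dim(open)
  dist <- array(Inf, d)
  frontier <- seeds[open[seeds]]
  dist[frontier] <- 0
  lvl <- 0
  g26 <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g26 <- g26[rowSums(abs(g26)) > 0, ]
  while (length(frontier) > 0) {
    nxt <- integer(0)
    pos <- arrayInd(frontier, d)
    for (r in seq_len(nrow(g26))) {
      q <- sweep(pos, 2, g26[r, ], `+`)
      ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
        q[, 3] >= 1 & q[, 3] <= d[3]
      lin <- q[ok, 1] + d[1] * (q[ok, 2] - 1 + d[2] * (q[ok, 3] - 1))
      lin <- lin[open[lin] & !is.finite(dist[lin])]
      dist[lin] <- lvl + 1
      nxt <- c(nxt, lin)
    }
    frontier <- unique(nxt)
    lvl <- lvl + 1
  }
  max(dist[is.finite(dist)])
}
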