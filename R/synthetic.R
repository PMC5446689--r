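# Deterministic synthetic fixtures emulating common fluorescence regimes:
# a curved tube whose wall outshines its core (the structure isosurfacing
# obscures), fields of nuclear blobs, a many-channel filament atlas, and a
# three-channel limb-like occlusion layout.  Every generator is a pure
# function of its arguments (one private seeded RNG stream; global random
# state is never consulted) and returns ground truth sufficient to score
# segmentation and analysis without any reference data.

#' Generate a curved dim-core tube channel with ground truth
#'
#' The tube runs along x with a sinusoidal bend in y; its wall is bright and
#' its core dim, the intensity profile that makes threshold isosurfaces
#' misleading and motivates grayscale selection.  Additive Gaussian noise is
#' clipped to `[0, 1]`.
#'
#' @param dims volume dimensions `(nx, ny, nz)`.
#' @param radius tube radius in voxels; the dim core fills half the radius.
#' @param wall_intensity,core_intensity intensities with
#'   `core_intensity < wall_intensity`.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed integer seed; identical seeds give identical volumes.
#' @param bend amplitude (voxels) of the sinusoidal centerline bend.
#' @return list with `channel` (an `fv_channel`) and `truth` (logical array,
#'   the tube's voxels).
#' @export
gen_tube <- function(dims = c(64, 64, 64), radius = 6, wall_intensity = 0.85,
                     core_intensity = 0.4, noise_sd = 0.05, seed = 1, bend = 3) {
  stopifnot(core_intensity < wall_intensity)
  if (2 * radius >= min(dims[2], dims[3])) stop("radius too large for the volume")
  cy <- dims[2] / 2 - 0.5
  cz <- dims[3] / 2 - 0.5
  x <- seq_len(dims[1]) - 1
  ycen <- cy + bend * sin(2 * pi * x / dims[1])
  vol <- array(0, dims)
  truth <- array(FALSE, dims)
  yy <- matrix(seq_len(dims[2]) - 1, dims[2], dims[3])
  zz <- matrix(seq_len(dims[3]) - 1, dims[2], dims[3], byrow = TRUE)
  for (i in seq_len(dims[1])) {
    r2 <- (yy - ycen[i])^2 + (zz - cz)^2
    core <- r2 <= (radius / 2)^2
    wall <- r2 <= radius^2 & !core
    plane <- matrix(0, dims[2], dims[3])
    plane[wall] <- wall_intensity
    plane[core] <- core_intensity
    vol[i, , ] <- plane
    truth[i, , ] <- core | wall
  }
  vol <- with_seed(seed, clamp01(vol + stats::rnorm(length(vol), 0, noise_sd)))
  list(channel = channel(array(vol, dims), name = "tube", bit_depth = 12),
       truth = truth)
}

#' Generate non-overlapping Gaussian blobs with per-blob labels
#'
#' Emulates nuclear labels: isotropic Gaussian-profile blobs (peak at the
#' center voxel) placed by rejection sampling so that no two blobs overlap.
#'
#' @param dims volume dimensions.
#' @param n_blobs number of blobs (>= 1).
#' @param radius_range blob radius range in voxels.
#' @param seed integer seed.
#' @param peak peak intensity of each blob.
#' @param max_tries placement attempts before giving up.
#' @return list with `channel`, `labels` (integer array, 0 background) and
#'   `centers` (n x 3 zero-based voxel coordinates).
#' @export
gen_blobs <- function(dims = c(64, 64, 64), n_blobs = 5, radius_range = c(4, 7),
                      seed = 1, peak = 0.9, max_tries = 2000) {
  stopifnot(n_blobs >= 1)
  with_seed(seed, {
    centers <- matrix(numeric(0), 0, 3)
    radii <- numeric(0)
    tries <- 0
    while (nrow(centers) < n_blobs && tries < max_tries) {
      tries <- tries + 1
      r <- stats::runif(1, radius_range[1], radius_range[2])
      c0 <- floor(stats::runif(3, r + 1, dims - r - 1))
      if (nrow(centers) > 0) {
        dist <- sqrt(rowSums(sweep(centers, 2, c0)^2))
        if (any(dist < radii + r + 2)) next
      }
      centers <- rbind(centers, c0)
      radii <- c(radii, r)
    }
    if (nrow(centers) < n_blobs) {
      stop(sprintf("could not place %d non-overlapping blobs (achieved %d)",
                   n_blobs, nrow(centers)))
    }
    vol <- array(0, dims)
    labels <- array(0L, dims)
    xx <- seq_len(dims[1]) - 1
    yy <- seq_len(dims[2]) - 1
    zz <- seq_len(dims[3]) - 1
    for (b in seq_len(n_blobs)) {
      c0 <- centers[b, ]
      r <- radii[b]
      ix <- which(abs(xx - c0[1]) <= r)
      iy <- which(abs(yy - c0[2]) <= r)
      iz <- which(abs(zz - c0[3]) <= r)
      sub <- expand.grid(ix, iy, iz)
      d2 <- (xx[sub[, 1]] - c0[1])^2 + (yy[sub[, 2]] - c0[2])^2 + (zz[sub[, 3]] - c0[3])^2
      keep <- d2 <= r^2
      lin <- as.matrix(sub[keep, ])
      vol[lin] <- pmax(vol[lin], peak * exp(-d2[keep] / (2 * (r / 2)^2)))
      labels[lin] <- b
    }
    list(channel = channel(vol, name = "blobs", bit_depth = 8),
         labels = labels, centers = centers)
  })
}

#' Generate a many-channel filament atlas
#'
#' Co-registered channels, each containing one smooth curved filament bundle
#' with a distinct hue -- a desk-scale emulation of clonal-unit brain
#' atlases in which on the order of a hundred channels are rendered at once.
#'
#' @param n_channels number of channels (default 96).
#' @param dims per-channel dimensions.
#' @param seed integer seed.
#' @param filament_radius tube radius of each filament (voxels).
#' @return list of `fv_channel` objects.
#' @export
gen_atlas <- function(n_channels = 96, dims = c(64, 64, 64), seed = 1,
                      filament_radius = 1.5) {
  stopifnot(n_channels >= 1)
  ball <- ball_offsets(filament_radius)
  with_seed(seed, {
    lapply(seq_len(n_channels), function(ci) {
      vol <- array(0, dims)
      # smooth random walk with momentum, stamped as a thin tube
      p <- stats::runif(3, dims * 0.2, dims * 0.8)
      v <- vnorm(stats::rnorm(3))
      nsteps <- 3 * max(dims)
      for (s in seq_len(nsteps)) {
        v <- vnorm(v + 0.25 * stats::rnorm(3))
        p <- p + v
        p <- clamp(p, 2, dims - 3)
        at <- sweep(ball, 2, round(p), `+`) + 1L
        ok <- at[, 1] >= 1 & at[, 1] <= dims[1] & at[, 2] >= 1 & at[, 2] <= dims[2] &
          at[, 3] >= 1 & at[, 3] <= dims[3]
        vol[at[ok, , drop = FALSE]] <- 1
      }
      vol <- vol * 0.8
      hue <- (ci - 1) / n_channels
      col <- as.vector(grDevices::col2rgb(grDevices::hsv(hue, 1, 1)) / 255)
      channel(vol, name = sprintf("clone%02d", ci), bit_depth = 8,
              settings = render_settings(color = col, alpha_scale = 0.9))
    })
  })
}

ball_offsets <- function(r) {
  k <- ceiling(r)
  g <- as.matrix(expand.grid(-k:k, -k:k, -k:k))
  g[rowSums(g^2) <= r^2, , drop = FALSE]
}

#' Generate a three-channel limb-like occlusion fixture
#'
#' Three co-registered channels laid out so the intermixing modes are
#' distinguishable: a dense muscle-like sheet in front (along +z), cord-like
#' tendons to the side, and thin nerve-like branches running behind the
#' sheet.  Viewed along +z in depth mode the nerves are occluded where the
#' sheet saturates; the layered mode with nerves first shows them in front.
#'
#' @param dims volume dimensions shared by the channels.
#' @param seed integer seed (noise only).
#' @param noise_sd additive Gaussian noise standard deviation.
#' @return named list of three `fv_channel`s: `muscle`, `tendon`, `nerve`.
#' @export
gen_limb <- function(dims = c(48, 48, 48), seed = 1, noise_sd = 0.02) {
  mk <- function(fill, name, col, alpha) {
    vol <- with_seed(seed + match(name, c("muscle", "tendon", "nerve")),
                     clamp01(fill + stats::rnorm(length(fill), 0, noise_sd)))
    channel(array(vol, dims), name = name, bit_depth = 8,
            settings = render_settings(color = col, alpha_scale = alpha))
  }
  rg <- function(a, b, n) seq(clamp(round(a), 1, n), clamp(round(b), 1, n))
  muscle <- array(0, dims)
  # dense sheet near the viewer (+z view): occupies the central x-y block
  muscle[rg(dims[1] * 0.2, dims[1] * 0.8, dims[1]),
         rg(dims[2] * 0.25, dims[2] * 0.75, dims[2]),
         rg(dims[3] * 0.15, dims[3] * 0.3, dims[3])] <- 0.95
  tendon <- array(0, dims)
  for (off in c(0.12, 0.88)) {
    tendon[rg(dims[1] * 0.1, dims[1] * 0.9, dims[1]),
           rg(dims[2] * off - 2, dims[2] * off + 2, dims[2]),
           rg(dims[3] * 0.4, dims[3] * 0.5, dims[3])] <- 0.8
  }
  nerve <- array(0, dims)
  for (off in c(0.35, 0.5, 0.65)) {
    nerve[rg(dims[1] * 0.05, dims[1] * 0.95, dims[1]),
          rg(dims[2] * off - 1, dims[2] * off + 1, dims[2]),
          rg(dims[3] * 0.6, dims[3] * 0.66, dims[3])] <- 0.85
  }
  list(muscle = mk(muscle, "muscle", c(1, 0.2, 0.2), 1),
       tendon = mk(tendon, "tendon", c(0.2, 1, 0.2), 0.9),
       nerve = mk(nerve, "nerve", c(0.3, 0.3, 1), 0.9))
}
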