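test_that("the five compositing operators match their defining equations", {
  set.seed(11)
  n <- 1000
  S <- cbind(matrix(runif(3 * n, 0, 2), n, 3), runif(n))
  D <- cbind(matrix(runif(3 * n, 0, 2), n, 3), runif(n))
  # direct evaluation of the equations, written out independently
  ftb <- cbind((1 - D[, 4]) * S[, 1:3] + D[, 1:3], (1 - D[, 4]) * S[, 4] + D[, 4])
  btf <- cbind(S[, 4] * S[, 1:3] + (1 - S[, 4]) * D[, 1:3],
               S[, 4] + (1 - S[, 4]) * D[, 4])
  expect_equal(composite("front_to_back", S, D), ftb, ignore_attr = TRUE)
  expect_equal(composite("back_to_front", S, D), btf, ignore_attr = TRUE)
  expect_equal(composite("addition", S, D), S + D)
  expect_equal(composite("maximum", S, D), pmax(S, D))
  expect_equal(composite("multiplication", S, D), S * D)
  # scalar cases from the defining table
  expect_equal(composite("addition", c(0.4, 0.4, 0.4, 0.4), c(0.2, 0.2, 0.2, 0.2)),
               rep(0.6, 4))
  expect_equal(composite("maximum", c(0.3, 0.3, 0.3, 0.3), c(0.7, 0.7, 0.7, 0.7)),
               rep(0.7, 4))
  # fully occluded source contributes nothing front-to-back
  out <- composite("front_to_back", c(0.5, 0.5, 0.5, 0.5), c(0.1, 0.2, 0.3, 1))
  expect_equal(out, c(0.1, 0.2, 0.3, 1))
  expect_error(composite("overlay", 1:4, 1:4), "unknown compositing operator")
})

test_that("stream plans enumerate the two streaming orders", {
  c1 <- sparse_channel(c(6, 6, 3), n = 20, seed = 1)
  c2 <- sparse_channel(c(6, 6, 3), n = 20, seed = 2)
  scn <- scene(list(c1, c2), "composite", camera = box_camera(c(6, 6, 3)),
               sample_spacing = 1)
  pl <- plan_stream(scn)
  ns <- sum(pl$units$channel == 1)
  # channel-major: all of channel 1's slices, then all of channel 2's
  expect_equal(pl$units$channel, rep(1:2, each = ns))
  expect_equal(pl$units$slice[1:ns], 1:ns)

  scn_d <- scene(list(c1, c2), "depth", camera = box_camera(c(6, 6, 3)),
                 sample_spacing = 1)
  pd <- plan_stream(scn_d)
  # brick-major: channels interleave within each slice
  expect_equal(pd$units$channel, rep(1:2, times = ns))
  expect_equal(pd$units$slice, rep(1:ns, each = 2))
  # depth-mode loop boundaries never split a slice
  pdb <- plan_stream(scn_d, budget = 3)
  expect_true(all(pdb$loop_ends %% 2 == 0))
  # budget >= total -> one loop
  expect_length(plan_stream(scn, budget = 10000)$loop_ends, 1)
  expect_error(plan_stream(scn, order = "brick_major"), "requires")
  expect_error(plan_stream(scn_d, order = "channel_major"), "requires")
})

test_that("final images are invariant to the render-loop budget in every mode", {
  c1 <- sparse_channel(c(10, 10, 10), n = 120, seed = 4)
  c2 <- sparse_channel(c(10, 10, 10), n = 120, seed = 5,
                       settings = render_settings(color = c(1, 0, 0), alpha_scale = 0.5))
  cam <- box_camera(c(10, 10, 10))
  for (mode in c("composite", "layered", "depth")) {
    scn <- scene(list(c1, c2), mode, camera = cam, sample_spacing = 1)
    ref <- execute_stream(plan_stream(scn), scn)$final
    for (budget in c(1, 7)) {
      got <- execute_stream(plan_stream(scn, budget = budget), scn)
      expect_lt(max(abs(got$final - ref)), 1e-4)
      expect_gt(length(got$snapshots), 1)
    }
  }
})

test_that("degenerate and disjoint scenes reduce to single-channel renders", {
  ch <- sparse_channel(c(10, 10, 10), n = 100, seed = 6)
  cam <- box_camera(c(10, 10, 10))
  single <- render_channel(ch, cam, sample_spacing = 1)
  for (mode in c("composite", "layered", "depth")) {
    scn <- scene(list(ch), mode, camera = cam, sample_spacing = 1)
    expect_lt(max(abs(render_scene(scn) - single)), 1e-10)
  }
  # two channels disjoint in image space: composite = union of singles
  v1 <- array(0, c(16, 16, 8)); v1[2:5, 2:5, 3:6] <- 0.8
  v2 <- array(0, c(16, 16, 8)); v2[10:14, 10:14, 3:6] <- 0.6
  a <- channel(v1); b <- channel(v2, settings = render_settings(color = c(0, 1, 0)))
  cam2 <- box_camera(c(16, 16, 8))
  scn <- scene(list(a, b), "composite", camera = cam2, sample_spacing = 1)
  fb <- render_scene(scn)
  fa <- render_channel(a, cam2, sample_spacing = 1)
  fbb <- render_channel(b, cam2, sample_spacing = 1)
  expect_lt(max(abs(fb - (fa + fbb))), 1e-10)
})

test_that("composite mode accumulates linearly without clipping", {
  v <- array(0, c(8, 8, 4)); v[3:6, 3:6, 2] <- 1
  chans <- lapply(1:3, function(i) channel(v))
  cam <- box_camera(c(8, 8, 4))
  fb1 <- render_channel(chans[[1]], cam, sample_spacing = 1)
  fb3 <- render_scene(scene(chans, "composite", camera = cam, sample_spacing = 1))
  expect_equal(fb3, 3 * fb1, tolerance = 1e-12, ignore_attr = TRUE)
  expect_gt(max(fb3), 1)  # HDR values preserved, never clamped
  # and addition commutes: channel order does not matter
  fb3r <- render_scene(scene(rev(chans), "composite", camera = cam, sample_spacing = 1))
  expect_equal(fb3, fb3r, ignore_attr = TRUE)
})

test_that("layered mode keeps the first-listed channel in front", {
  v1 <- array(0, c(8, 8, 8)); v1[3:6, 3:6, 5:7] <- 1   # back object, but listed first
  v2 <- array(0, c(8, 8, 8)); v2[3:6, 3:6, 1:3] <- 1   # front object in depth
  front <- channel(v1, settings = render_settings(color = c(1, 0, 0)))
  back <- channel(v2, settings = render_settings(color = c(0, 0, 1)))
  cam <- box_camera(c(8, 8, 8))
  fb <- render_scene(scene(list(front, back), "layered", camera = cam, sample_spacing = 1))
  # where the first channel is opaque, the second is invisible regardless of depth
  expect_gt(fb[4, 4, 1], 0.7)  # red (alpha saturates across the object's slices)
  expect_equal(fb[4, 4, 4], 1)
  expect_lt(fb[4, 4, 3], 1e-6) # no blue
})

test_that("depth mode matches the multichannel ray-marching oracle", {
  # two interleaved rods along x at different depths
  v1 <- array(0, c(12, 12, 12)); v1[, 5:7, 3:5] <- 0.9
  v2 <- array(0, c(12, 12, 12)); v2[, 5:7, 7:9] <- 0.9
  c1 <- channel(v1, settings = render_settings(color = c(1, 0, 0), alpha_scale = 0.8))
  c2 <- channel(v2, settings = render_settings(color = c(0, 0, 1), alpha_scale = 0.8))
  cam <- box_camera(c(12, 12, 12))
  scn <- scene(list(c1, c2), "depth", camera = cam, sample_spacing = 1)
  fb <- render_scene(scn)
  oracle <- oracle_ray_march(list(c1, c2), cam, spacing = 1)
  expect_lt(max(abs(fb - oracle)), 1e-3)
  # the front rod occludes the back one where it saturates; swap -> symmetric
  expect_gt(max(fb[, , 1]), max(fb[, , 3]))
})

test_that("groups render recursively and combine with the scene mode", {
  l <- gen_limb(dims = c(24, 24, 24), seed = 2)
  grp <- channel_group(list(l$muscle, l$nerve), "depth")
  cam <- box_camera(c(24, 24, 24))
  scn <- scene(list(grp, l$tendon), "layered", camera = cam, sample_spacing = 1)
  fb <- render_scene(scn)
  expect_true(all(is.finite(fb)) && min(fb) >= 0)
  # group buffer equals its own depth render placed in front of the tendon
  gfb <- render_scene(scene(list(l$muscle, l$nerve), "depth", camera = cam,
                            sample_spacing = 1))
  tfb <- render_channel(l$tendon, cam, sample_spacing = 1)
  expect_lt(max(abs(fb - composite("back_to_front", gfb, tfb))), 1e-10)
  expect_error(render_scene(scene(list(grp, l$tendon), "depth", camera = cam,
                                  sample_spacing = 1)),
               "channels, not groups")
})

test_that("toggling a channel's visibility changes only its own contribution", {
  chans <- gen_atlas(6, dims = c(32, 32, 32), seed = 5)
  cam <- box_camera(c(32, 32, 32))
  scn <- scene(chans, "composite", camera = cam, sample_spacing = 1)
  full <- render_scene(scn)
  chans2 <- chans
  chans2[[3]]$settings$visible <- FALSE
  without <- render_scene(scene(chans2, "composite", camera = cam, sample_spacing = 1))
  alone <- render_channel(chans[[3]], cam, sample_spacing = 1)
  expect_lt(max(abs(full - (without + alone))), 1e-10)
})
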