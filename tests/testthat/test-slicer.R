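test_that("a unit cube viewed along +z slices into uniformly spaced quads", {
  ch <- channel(array(0.5, c(1, 1, 1)))
  brick <- make_bricks(ch, 8)[[1]]
  cam <- box_camera(c(1, 1, 1), viewport = c(4, 4))
  sl <- compute_view_slices(brick, cam, 0.25)
  expect_length(sl, 5)
  expect_equal(vapply(sl, `[[`, numeric(1), "depth"),
               c(0, 0.25, 0.5, 0.75, 1), tolerance = 1e-4)
  expect_true(all(vapply(sl, function(s) nrow(s$polygon), integer(1)) == 4))
  expect_error(ortho_camera(channel_world_box(ch), view_direction = c(0, 0, 0)),
               "degenerate")
})

test_that("oblique slice polygons stay convex with 3-6 vertices", {
  ch <- channel(array(0, c(5, 7, 3)))
  brick <- make_bricks(ch, 8)[[1]]
  for (v in list(c(1, 1, 1), c(2, -1, 0.5), c(-1, 2, 3), c(0, 1, 1))) {
    cam <- ortho_camera(channel_world_box(ch), view_direction = v, viewport = c(8, 8))
    sl <- compute_view_slices(brick, cam, 0.5)
    nv <- vapply(sl, function(s) nrow(s$polygon), integer(1))
    expect_true(all(nv <= 6))
    # planes strictly between the extreme depths cut proper 3-6-gons;
    # the first/last slice may degenerate to the tangent corner or edge
    interior <- nv[-c(1, length(nv))]
    expect_true(all(interior >= 3 & interior <= 6))
  }
})

test_that("slicing is content-independent and scales with view extent", {
  a <- channel(array(0, c(8, 8, 8)))
  b <- channel(array(runif(512), c(8, 8, 8)))
  cam <- box_camera(c(8, 8, 8))
  sa <- compute_view_slices(make_bricks(a, 16)[[1]], cam, 1)
  sb <- compute_view_slices(make_bricks(b, 16)[[1]], cam, 1)
  expect_equal(vapply(sa, `[[`, numeric(1), "depth"),
               vapply(sb, `[[`, numeric(1), "depth"))
  # halving the spacing doubles (minus shared endpoint) the slice count
  s2 <- compute_view_slices(make_bricks(a, 16)[[1]], cam, 0.5)
  expect_equal(length(s2), 2 * length(sa) - 1)
})

test_that("the transfer function follows window, gamma and premultiplication", {
  st <- render_settings()
  tr <- apply_transfer(0.5, st)
  expect_equal(tr$alpha, 0.5)
  expect_equal(drop(tr$C), c(0.25, 0.25, 0.25))
  st2 <- render_settings(low_threshold = 0.3, high_threshold = 0.8)
  expect_equal(apply_transfer(0.25, st2)$alpha, 0)   # below the window floor
  expect_equal(apply_transfer(0.9, st2)$v, 1)        # clamped above
  expect_equal(apply_transfer(0.55, st2)$v, 0.5)     # window midpoint
  st3 <- render_settings(gamma = 2)
  expect_equal(apply_transfer(0.25, st3)$v, 0.25^(1 / 2))
  # identity settings leave v = intensity
  expect_equal(apply_transfer(c(0, 0.3, 1), st)$v, c(0, 0.3, 1))
})

test_that("depth attenuation is linear in depth and off at coefficient 0", {
  expect_equal(depth_attenuation_factor(0, 0.8), 1)
  expect_equal(depth_attenuation_factor(0.7, 0), 1)
  expect_equal(depth_attenuation_factor(1, 1), 0)
  f <- depth_attenuation_factor(seq(0, 1, 0.1), 0.5)
  expect_true(all(diff(f) <= 0))
})

test_that("shading combines ambient and Lambertian terms from the gradient", {
  # planar boundary: intensity steps up along +z, so the gradient points +z
  vol <- array(0, c(5, 5, 5))
  vol[, , 4:5] <- 1
  ch <- channel(vol, settings = render_settings(shading_enabled = TRUE, ambient = 0.3))
  # light along -z (anti-parallel to the gradient): full Lambertian
  expect_equal(shading_factor(ch, c(2, 2, 2), c(0, 0, -1)), 1.0)
  # flat interior: ambient only
  expect_equal(shading_factor(ch, c(2, 2, 0), c(0, 0, -1)), 0.3)
  # shadow disabled leaves the factor unchanged
  st <- ch$settings; st$shadow_strength <- 0
  expect_equal(shading_factor(ch, c(2, 2, 2), c(0, 0, -1), st), 1.0)
  st$shadow_strength <- 1
  expect_lte(shading_factor(ch, c(2, 2, 3), c(0, 0, -1), st), 1.0)
  expect_error(shading_factor(channel(vol), c(2, 2, 2), c(0, 0, -1)), "shading_enabled")
})

test_that("a single bright voxel lights only its projected footprint", {
  vol <- array(0, c(16, 16, 16))
  vol[5, 9, 8] <- 1
  ch <- channel(vol)
  cam <- box_camera(c(16, 16, 16))
  fb <- render_channel(ch, cam, sample_spacing = 1)
  lit <- which(fb[, , 4] > 1e-6, arr.ind = TRUE)
  expect_gt(nrow(lit), 0)
  # footprint: voxel center x=4.5, y=8.5 -> pixel col 5, row 9 (+- 1 for support)
  expect_true(all(abs(lit[, 1] - 9) <= 1 & abs(lit[, 2] - 5) <= 1))
})

test_that("slice-composited DVR and MIP match brute-force ray marching", {
  ch <- sparse_channel(c(12, 12, 12), n = 200, seed = 3)
  cam <- box_camera(c(12, 12, 12))
  fb <- render_channel(ch, cam, sample_spacing = 1)
  oracle <- oracle_ray_march(list(ch), cam, spacing = 1)
  expect_lt(max(abs(fb - oracle)), 1e-3)

  chm <- ch
  chm$settings$mode <- "MIP"
  fbm <- render_channel(chm, cam, sample_spacing = 1)
  vmax <- oracle_mip_v(chm, cam, spacing = 1)
  a <- chm$settings$alpha_scale * vmax
  expect_equal(fbm[, , 4], a, tolerance = 1e-5)
  expect_equal(fbm[, , 1], a * vmax, tolerance = 1e-5)

  # constant-zero volume renders fully transparent
  z <- channel(array(0, c(8, 8, 8)))
  expect_equal(max(abs(render_channel(z, box_camera(c(8, 8, 8))))), 0)
})

test_that("opacity correction keeps streamed renders equal to the oracle at any spacing", {
  ch <- sparse_channel(c(12, 12, 12), n = 250, seed = 9,
                       settings = render_settings(alpha_scale = 0.5))
  cam <- box_camera(c(12, 12, 12))
  for (sp in c(1, 0.5)) {
    fb <- render_scene(scene(list(ch), camera = cam, sample_spacing = sp))
    oracle <- oracle_ray_march(list(ch), cam, spacing = sp)
    expect_lt(max(abs(fb - oracle)), 1e-3)
  }
})
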