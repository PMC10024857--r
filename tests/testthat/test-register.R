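# round-to-round registration and warping

test_that("warp is exact for the identity and moves impulses correctly", {
  set.seed(1)
  m <- matrix(runif(40 * 50), 40, 50)
  w <- warp(m, identity_transform())
  expect_equal(unclass(w)[seq_along(m)], as.vector(m))
  # a 10-px shift moves a delta impulse by exactly 10 px
  g <- matrix(0, 32, 32); g[21, 25] <- 1   # impulse at x = 24, y = 20
  w2 <- warp(g, rigid_transform(0, 10, 0))
  expect_equal(which(w2 == 1, arr.ind = TRUE)[1, ], c(row = 21, col = 15))
})

test_that("warp round-trips through the inverse transform on the interior", {
  set.seed(2)
  cx <- runif(20, 20, 100); cy <- runif(20, 20, 100)
  m <- render_blob_image(cx, cy, n = 128)
  t <- rigid_transform(2, 3.5, -2.25, center = c(63.5, 63.5))
  back <- warp(warp(m, t), invert_transform(t))
  interior <- 20:109
  # double bilinear resampling of unit-amplitude sigma = 3 blobs carries
  # curvature error up to ~ 2 * max|f''| * h^2 / 8 ~ 0.07
  expect_lt(max(abs(back[interior, interior] - m[interior, interior])), 0.1)
})

test_that("out-of-field pixels are zeroed and flagged in the validity mask", {
  m <- matrix(1, 20, 20)
  w <- warp(m, rigid_transform(0, 5, 0))
  v <- attr(w, "valid")
  expect_true(all(w[, 16:20] == 0))
  expect_true(all(!v[, 16:20]))
  expect_true(all(v[, 1:15]))
})

test_that("registration recovers identity, sub-pixel shifts and rotations", {
  set.seed(3)
  cx <- runif(25, 15, 110); cy <- runif(25, 15, 110)
  fixed <- render_blob_image(cx, cy)
  # identity
  t0 <- estimate_transform(fixed, fixed, max_rotation = 2)
  p0 <- chromoplex:::decompose_transform(t0)
  expect_lt(abs(p0[["tx"]]), 0.1)
  expect_lt(abs(p0[["ty"]]), 0.1)
  expect_lt(abs(p0[["angle_deg"]]), 0.01)
  # sub-pixel shift (12.5, -7.25), synthesized analytically (no resampling)
  moving <- render_blob_image(cx + 12.5, cy - 7.25)
  t1 <- estimate_transform(fixed, moving, max_rotation = 0)
  p1 <- chromoplex:::decompose_transform(t1)
  expect_lt(abs(p1[["tx"]] - 12.5), 0.5)
  expect_lt(abs(p1[["ty"]] + 7.25), 0.5)
  # 3-degree rotation about the image centre
  th <- 3 * pi / 180; c0 <- 63.5
  rx <- cos(th) * (cx - c0) - sin(th) * (cy - c0) + c0
  ry <- sin(th) * (cx - c0) + cos(th) * (cy - c0) + c0
  t2 <- estimate_transform(fixed, render_blob_image(rx, ry))
  expect_lt(abs(chromoplex:::decompose_transform(t2)[["angle_deg"]] - 3), 0.2)
  expect_gt(t2$similarity, 0.98)
})

test_that("registration failure below the similarity floor raises a typed error", {
  set.seed(4)
  a <- render_blob_image(runif(15, 15, 110), runif(15, 15, 110))
  noise <- matrix(runif(128 * 128), 128, 128)
  expect_error(estimate_transform(a, noise, min_similarity = 0.9),
               class = "registration_failure")
})

test_that("transforms compose, invert and serialize", {
  t1 <- rigid_transform(2, 3, -1, center = c(10, 10))
  t2 <- rigid_transform(-1, 0.5, 2, center = c(10, 10))
  pts <- matrix(runif(10, 0, 20), 5, 2)
  expect_equal(apply_transform(compose_transform(t1, t2), pts),
               apply_transform(t1, apply_transform(t2, pts)), tolerance = 1e-12)
  rt <- apply_transform(invert_transform(t1), apply_transform(t1, pts))
  expect_equal(rt, pts, tolerance = 1e-12)
  f <- tempfile(fileext = ".json")
  write_transform_json(t1, f)
  t1b <- read_transform_json(f)
  expect_equal(t1b$A, t1$A, tolerance = 1e-12)
})

test_that("registration on synthetic scenes keeps centroid error under 1 px", {
  sc <- generate_scene(small_scene_config(seed = 21, max_shift_px = 8,
                                          max_rotation_deg = 2))
  sm <- default_stain_matrix()
  hema <- lapply(sc$images, function(im)
    deconvolve(rgb_to_od(im), sm)$hematoxylin)
  pts <- cbind(sc$truth$cells$x_um, sc$truth$cells$y_um)
  for (r in c(3, 7)) {
    est <- estimate_transform(hema[[1]], hema[[r]])
    tru <- sc$truth$transforms[[r]]
    err <- sqrt(rowSums((apply_transform(est, pts) -
                           apply_transform(tru, pts))^2))
    expect_lt(mean(err), 1)
  }
})

test_that("deformable mode refines at least as well as rigid", {
  set.seed(6)
  cx <- runif(25, 15, 110); cy <- runif(25, 15, 110)
  fixed <- render_blob_image(cx, cy)
  moving <- render_blob_image(cx + 4.3, cy - 2.6)
  tr <- estimate_transform(fixed, moving, mode = "rigid", max_rotation = 1)
  td <- estimate_transform(fixed, moving, mode = "deformable",
                           max_rotation = 1, block_size = 64)
  expect_gte(td$similarity, tr$similarity - 1e-6)
})
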