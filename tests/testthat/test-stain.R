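# Beer-Lambert transform and colour deconvolution

test_that("rgb_to_od matches the Beer-Lambert examples exactly", {
  img <- function(rgb) calibrated_image(array(rgb, c(1, 1, 3)), 1)
  expect_equal(as.vector(rgb_to_od(img(c(255, 255, 255)))$pixels), c(0, 0, 0))
  expect_equal(as.vector(rgb_to_od(img(c(25.5, 25.5, 25.5)))$pixels),
               c(1, 1, 1))
  # -log10(26/255) = 0.991567..., frozen from an independent evaluation
  expect_equal(as.vector(rgb_to_od(img(c(26, 255, 255)))$pixels),
               c(0.9915668, 0, 0), tolerance = 1e-6)
  # saturated-dark pixels stay finite via the one-level clamp
  expect_true(all(is.finite(rgb_to_od(img(c(0, 0, 0)))$pixels)))
})

test_that("rgb_to_od validates modality and white point", {
  od <- calibrated_image(array(0.5, c(2, 2, 3)), 1, modality = "od")
  expect_error(rgb_to_od(od), "brightfield_rgb")
  img <- calibrated_image(array(100, c(2, 2, 3)), 1)
  expect_error(rgb_to_od(img, white_point = -1), "white_point")
})

test_that("OD round-trips to RGB within one intensity level", {
  set.seed(42)
  px <- array(runif(4 * 5 * 3, 0, 255), c(4, 5, 3))
  img <- calibrated_image(px, 0.5)
  back <- od_to_rgb(rgb_to_od(img))
  expect_lt(max(abs(back$pixels - px)), 1)
})

test_that("OD is monotone decreasing in intensity", {
  I <- seq(1, 255, length.out = 50)
  img <- calibrated_image(array(rep(I, 3), c(1, 50, 3)), 1)
  od <- rgb_to_od(img)$pixels[1, , 1]
  expect_true(all(diff(od) < 0))
})

test_that("deconvolution inverts independent forward mixing to 1e-6 OD", {
  sm <- default_stain_matrix()
  set.seed(7)
  for (rep in 1:5) {
    dc <- matrix(runif(30 * 40, 0, 1.5), 30, 40)
    dh <- matrix(runif(30 * 40, 0, 1.0), 30, 40)
    od <- forward_mix_od(list(dc, dh), sm$basis)
    out <- deconvolve(calibrated_image(od, 1, modality = "od"), sm)
    expect_lt(max(abs(out[[1]]$pixels - dc)), 1e-6)
    expect_lt(max(abs(out[[2]]$pixels - dh)), 1e-6)
  }
})

test_that("deconvolution basis alignment and zero field behave exactly", {
  sm <- default_stain_matrix()
  od <- calibrated_image(array(0.8 * sm$basis[, 2], c(1, 1, 3)), 1,
                         modality = "od")
  d <- deconvolve(od, sm)
  expect_equal(d$hematoxylin$pixels[1, 1], 0.8, tolerance = 1e-9)
  expect_equal(d$amec_red$pixels[1, 1], 0, tolerance = 1e-9)
  z <- deconvolve(calibrated_image(array(0, c(3, 3, 3)), 1, modality = "od"), sm)
  expect_true(all(z$amec_red$pixels == 0) && all(z$hematoxylin$pixels == 0))
})

test_that("negative densities are clipped and reported", {
  sm <- default_stain_matrix()
  # an OD vector outside the positive cone of the two stains
  v <- c(0, 0, 0.5)
  od <- calibrated_image(array(v, c(1, 1, 3)), 1, modality = "od")
  d <- deconvolve(od, sm)
  expect_true(all(d$amec_red$pixels >= 0) && all(d$hematoxylin$pixels >= 0))
  expect_true(any(attr(d, "clip_fraction") > 0))
})

test_that("deconvolution is invariant to consistent white-point rescaling", {
  sm <- default_stain_matrix()
  set.seed(3)
  px8 <- array(runif(10 * 10 * 3, 1, 255), c(10, 10, 3))
  img8 <- calibrated_image(px8, 1, white_point = 255)
  img16 <- calibrated_image(px8 * 257, 1, white_point = 255 * 257)
  d8 <- deconvolve(rgb_to_od(img8), sm)
  d16 <- deconvolve(rgb_to_od(img16, eps = 257), sm)
  expect_equal(d8$amec_red$pixels, d16$amec_red$pixels, tolerance = 1e-9)
})

test_that("collinear stain matrices are rejected", {
  v <- stain_vector("a", c(0.5, 0.6, 0.4))
  v2 <- stain_vector("b", c(0.5, 0.6, 0.4) * 2)
  expect_error(stain_matrix(v, v2), "collinear")
})

test_that("stain vectors are unit norm and non-negative", {
  v <- stain_vector("x", c(3, 4, 0))
  expect_equal(sqrt(sum(v$od_rgb^2)), 1, tolerance = 1e-12)
  expect_error(stain_vector("x", c(-1, 1, 0)), "non-negative")
})

test_that("estimate_stain_vector recovers known vectors", {
  sm <- default_stain_matrix()
  v_true <- sm$basis[, 1]
  set.seed(11)
  n <- 40
  dens <- matrix(runif(n * n, 0.2, 1.2), n, n)
  od <- array(0, c(n, n, 3))
  for (k in 1:3) od[, , k] <- dens * v_true[k]
  img <- calibrated_image(od, 1, modality = "od")
  roi <- matrix(TRUE, n, n)
  # noise free: near-perfect recovery
  v <- estimate_stain_vector(img, roi)
  expect_gte(sum(v$od_rgb * v_true), 0.999)
  # with OD noise sigma = 0.02
  odn <- od + array(rnorm(length(od), 0, 0.02), dim(od))
  odn[odn < 0] <- 0
  vn <- estimate_stain_vector(calibrated_image(odn, 1, modality = "od"), roi)
  expect_gte(sum(vn$od_rgb * v_true), 0.99)
  # pure white ROI: sampling error
  white <- calibrated_image(array(255, c(20, 20, 3)), 1)
  expect_error(estimate_stain_vector(white, matrix(TRUE, 20, 20)),
               "stained pixels")
})
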