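# distances, proximity profiles and association fractions

make_disk_object <- function(cx_um, cy_um, r_um, n = 200, mpp = 0.5,
                             kind = "abeta_plaque") {
  m <- matrix(0, n, n)
  xs <- matrix(rep(0:(n - 1), each = n), n, n) * mpp
  ys <- matrix(rep(0:(n - 1), n), n, n) * mpp
  m[sqrt((xs - cx_um)^2 + (ys - cy_um)^2) <= r_um] <- 1
  objs <- detect_pathology(density_map(m, mpp, "x"), kind, threshold = 0.5,
                           min_size = 0)
  pathology_objects(objs)[[1]]
}

test_that("distance_to_object matches circle geometry and the inside rule", {
  obj <- make_disk_object(50, 50, 30)
  # centroid 55 um from the centre of a 30 um-radius plaque -> 25 um
  expect_equal(distance_to_object(c(50 + 55, 50), obj), 25, tolerance = 0.5)
  # centroid inside -> 0
  expect_equal(distance_to_object(c(60, 50), obj), 0)
  expect_equal(distance_to_object(list(x_um = 50, y_um = 50), obj), 0)
})

test_that("distances match a dense boundary-sampling oracle within 0.5 um", {
  set.seed(19)
  for (rep in 1:4) {
    n <- 160; mpp <- 0.5
    # random blob: union of a few disks
    m <- matrix(0, n, n)
    xs <- matrix(rep(0:(n - 1), each = n), n, n) * mpp
    ys <- matrix(rep(0:(n - 1), n), n, n) * mpp
    for (k in 1:3) {
      cx <- runif(1, 25, 55); cy <- runif(1, 25, 55); r <- runif(1, 6, 14)
      m[sqrt((xs - cx)^2 + (ys - cy)^2) <= r] <- 1
    }
    objs <- detect_pathology(density_map(m, mpp, "x"), "abeta_plaque",
                             threshold = 0.5, min_size = 0)
    obj <- pathology_objects(objs)[[which.max(objs$table$area_um2)]]
    for (i in 1:5) {
      p <- runif(2, 0, 79)
      d_pkg <- distance_to_object(p, obj)
      d_oracle <- brute_boundary_distance(p, obj$boundary)
      inside <- obj$inside[round(p[2] / mpp) + 1 +
                             round(p[1] / mpp) * nrow(obj$inside)]
      if (inside) d_oracle <- 0
      expect_lt(abs(d_pkg - d_oracle), 0.5)
    }
  }
})

test_that("degenerate pathology objects raise a geometry error", {
  expect_error(distance_to_object(c(0, 0), list(boundary = NULL)),
               "degenerate")
})

test_that("profile bins assign cells by distance and apply the radius rule", {
  obj <- make_disk_object(50, 50, 10)
  cells <- data.frame(
    x_um = 50 + 10 + c(5, 25, 45, 101), y_um = 50,
    label = c("IBA1+P2Y12+", "IBA1-only", "IBA1+CD68+", "IBA1+P2Y12+"))
  pr <- proximity_profile(cells, list(obj), radius = 100, bin_width = 20)
  expect_equal(unname(rowSums(pr$counts)), c(1, 1, 1, 0, 0))
  expect_equal(pr$n_excluded, 1L)
  expect_equal(pr$counts["[0,20)", "IBA1+P2Y12+"], 1L)
  expect_equal(pr$counts["[40,60)", "IBA1+CD68+"], 1L)
  # conservation: binned + excluded = total classified cells
  expect_equal(sum(pr$counts) + pr$n_excluded, nrow(cells))
  # row percentages sum to 100 where the bin is nonempty
  rs <- rowSums(pr$row_pct)
  expect_true(all(abs(rs[!is.na(rs)] - 100) < 1e-6))
  expect_error(proximity_profile(cells, list(obj), radius = 100,
                                 bin_width = 30), "divide")
  expect_warning(pr0 <- proximity_profile(cells, list(), radius = 100,
                                          bin_width = 20), "no pathology")
  expect_equal(sum(pr0$counts), 0)
})

test_that("uniform cells bin proportionally to annulus area", {
  obj <- make_disk_object(150, 150, 20, n = 600, mpp = 1)
  edges <- seq(0, 100, by = 20)
  counts <- rep(0, 5)
  set.seed(29)
  for (s in 1:20) {
    cells <- data.frame(x_um = runif(400, 20, 280),
                        y_um = runif(400, 20, 280), label = "IBA1-only")
    pr <- proximity_profile(cells, list(obj), radius = 100, bin_width = 20,
                            phenotypes = "IBA1-only")
    counts <- counts + as.vector(pr$counts)
  }
  # uniform spatial process: expected counts follow the area of each
  # annulus around the 20-um-radius plaque (first bin includes the disk)
  r0 <- 20
  w <- c((r0 + 20)^2,
         vapply(2:5, function(b) (r0 + edges[b + 1])^2 - (r0 + edges[b])^2,
                numeric(1)))
  expected <- sum(counts) * w / sum(w)
  for (b in 1:5)
    expect_lt(abs(counts[b] - expected[b]), 4 * sqrt(expected[b]))
})

test_that("profiles are invariant under global rigid motion of the scene", {
  sc <- generate_scene(small_scene_config(seed = 51), render = FALSE)
  cells <- sc$truth$cells
  cells$label <- classify_phenotype(cells)
  plq_l <- pathology_objects(scene_truth_objects(sc, "abeta_plaque"))
  # boundary-only distances so both frames use identical geometry
  plq_l <- lapply(plq_l, function(o) { o$inside <- NULL; o })
  pr1 <- proximity_profile(cells, plq_l, radius = 100, bin_width = 20)
  # rotate the whole scene by 90 degrees about the field centre
  L <- sc$truth$config$field_um
  cells2 <- cells
  cells2$x_um <- L - cells$y_um
  cells2$y_um <- cells$x_um
  plq2 <- lapply(plq_l, function(o) {
    b <- o$boundary
    o$boundary <- cbind(x_um = L - b[, "y_um"], y_um = b[, "x_um"])
    o
  })
  pr2 <- proximity_profile(cells2, plq2, radius = 100, bin_width = 20)
  expect_equal(pr2$counts, pr1$counts)
})

test_that("association fractions recover generator contact placement", {
  cfg <- small_scene_config(
    seed = 61, field_um = 320, n_cells = 40, min_separation_um = 10,
    n_plaques = 4, plaque_radius_um = c(16, 22),
    contact_fraction = c("IBA1+Ferritin+CD68+" = 0.76, "IBA1+CD68+" = 0.40),
    phenotype_proportions = c(
      "IBA1+P2Y12+" = 0.2, "IBA1-only" = 0.1, "IBA1+Ferritin+" = 0.1,
      "IBA1+Ferritin+CD68+" = 0.35, "IBA1+CD68+" = 0.25))
  sc <- generate_scene(cfg, render = FALSE)
  cells_df <- sc$truth$cells
  # rasterize truth cells as an object_set via a synthetic IBA1 render
  sc2 <- generate_scene(cfg)
  sm <- default_stain_matrix()
  run <- run_pipeline(sc2$images, pipeline_config())
  assoc <- association_summary(run$cells, run$plaques, run$tangles,
                               vessels = scene_truth_objects(sc2, "vessel"))
  tp <- assoc[assoc$phenotype == "IBA1+Ferritin+CD68+", ]
  expect_gt(tp$n, 5)
  expect_gt(tp$pct_touching_plaque, 50)   # contact placement dominates
  # missing vessels are reported as not computed, not zero
  assoc2 <- association_summary(run$cells, run$plaques, run$tangles)
  expect_true(all(is.na(assoc2$pct_vessel_associated)))
  expect_true(all(is.na(assoc2$pct_touching_tangle) |
                    assoc2$pct_touching_tangle >= 0))
})

test_that("cell polygons overlapping a plaque mask are touching", {
  obj <- make_disk_object(30, 30, 10, n = 120, mpp = 1)
  # build a fake classified object_set with one overlapping, one distant cell
  m <- matrix(0, 120, 120)
  m[29:33, 37:41] <- 1    # overlaps the plaque edge (x ~ 36-40)
  m[100:104, 100:104] <- 1
  cells <- detect_objects(density_map(m, 1, "cells"), threshold = 0.5,
                          min_area = 0)
  cells$table$label <- c("IBA1+CD68+", "IBA1+CD68+")
  plq <- detect_pathology(density_map((function() {
    mm <- matrix(0, 120, 120)
    xs <- matrix(rep(0:119, each = 120), 120, 120)
    ys <- matrix(rep(0:119, 120), 120, 120)
    mm[sqrt((xs - 30)^2 + (ys - 30)^2) <= 10] <- 1
    mm })(), 1, "Abeta"), "abeta_plaque", threshold = 0.5, min_size = 0)
  assoc <- association_summary(cells, plq)
  expect_equal(assoc[assoc$phenotype == "IBA1+CD68+", "pct_touching_pathology"],
               50)
})
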