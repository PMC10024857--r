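# synthetic scene generator: determinism, forward model, truth consistency

test_that("the same seed reproduces bit-identical scenes", {
  cfg <- small_scene_config(seed = 71)
  a <- generate_scene(cfg, destain = TRUE)
  b <- generate_scene(cfg, destain = TRUE)
  expect_identical(a$truth$cells, b$truth$cells)
  for (r in seq_along(a$images))
    expect_identical(a$images[[r]]$pixels, b$images[[r]]$pixels)
  expect_identical(a$destain_images[[3]]$pixels, b$destain_images[[3]]$pixels)
  # a different seed changes the scene
  c <- generate_scene(small_scene_config(seed = 72))
  expect_false(identical(a$images[[1]]$pixels, c$images[[1]]$pixels))
})

test_that("every generated marker vector maps back to its phenotype", {
  for (seed in c(1, 2, 3)) {
    sc <- generate_scene(small_scene_config(
      seed = seed, field_um = 320, n_cells = 30,
      gfap_conflict_fraction = 0.1),
      render = FALSE)
    labels <- classify_phenotype(sc$truth$cells)
    expect_identical(labels, sc$truth$cells$phenotype)
  }
})

test_that("rendered OD equals the forward mixing of the true densities", {
  cfg <- small_scene_config(seed = 73, od_sigma = 0, quantize = FALSE,
                            max_shift_px = 0, max_rotation_deg = 0)
  sc <- generate_scene(cfg)
  sm <- cfg$stains
  r <- match("IBA1", cfg$panel)
  C <- chromoplex:::render_chromogen(sc$truth, "IBA1", identity_transform())
  H <- chromoplex:::render_hematoxylin(sc$truth, identity_transform())
  od <- rgb_to_od(sc$images[[r]])$pixels
  recon <- forward_mix_od(list(C, H), sm$basis)
  expect_lt(max(abs(od - recon)), 1e-9)
})

test_that("infeasible packing raises a config error", {
  cfg <- small_scene_config(seed = 74, field_um = 100, n_cells = 60,
                            min_separation_um = 30)
  expect_error(generate_scene(cfg, render = FALSE), "denser than packable")
})

test_that("single-stain renders match the multiplex round content", {
  cfg <- small_scene_config(seed = 75, max_shift_px = 0, max_rotation_deg = 0,
                            od_sigma = 0)
  sc <- generate_scene(cfg)
  single <- render_single_stain(sc, "IBA1")
  r <- match("IBA1", cfg$panel)
  # identical geometry: with no misalignment or noise, the images agree
  expect_equal(single$pixels, sc$images[[r]]$pixels)
  # a blank-panel request errors; counterstain-only content renders white-ish
  expect_error(render_single_stain(sc, "CD3"), "not in the panel")
})

test_that("attraction concentrates reactive phenotypes near plaques", {
  cfg <- scene_config(field_um = 480, n_cells = 110, n_plaques = 4,
                      n_other_nuclei = 0, n_astrocytes = 0,
                      attraction = c("IBA1+P2Y12+" = 0, "IBA1-only" = 0,
                                     "IBA1+Ferritin+" = 0,
                                     "IBA1+Ferritin+CD68+" = 12,
                                     "IBA1+CD68+" = 0),
                      seed = 76)
  inner <- c(trip = 0, all = 0)
  glob <- c(trip = 0, all = 0)
  for (seed in 76:83) {
    cfg$seed <- seed
    sc <- generate_scene(cfg, render = FALSE)
    cells <- sc$truth$cells
    cells$label <- cells$phenotype
    plq <- pathology_objects(scene_truth_objects(sc, "abeta_plaque"))
    d <- chromoplex:::object_distances(cbind(cells$x_um, cells$y_um), plq)
    near <- d <= 20
    inner["trip"] <- inner["trip"] +
      sum(cells$label[near] == "IBA1+Ferritin+CD68+")
    inner["all"] <- inner["all"] + sum(near)
    glob["trip"] <- glob["trip"] + sum(cells$label == "IBA1+Ferritin+CD68+")
    glob["all"] <- glob["all"] + nrow(cells)
  }
  expect_gt(inner[["trip"]] / inner[["all"]], glob[["trip"]] / glob[["all"]])
})

test_that("diffuse speckles stay below the pathology size exclusion", {
  cfg <- small_scene_config(seed = 77, od_sigma = 0)
  sc <- generate_scene(cfg)
  sm <- default_stain_matrix()
  r <- match("Abeta", cfg$panel)
  ch <- deconvolve(rgb_to_od(sc$images[[r]]), sm)$amec_red
  all_objs <- detect_pathology(ch, "abeta_plaque", min_size = 0)
  excl <- detect_pathology(ch, "abeta_plaque", min_size = 100)
  expect_gt(nrow(all_objs$table), nrow(excl$table))   # speckles dropped
  expect_equal(nrow(excl$table), length(sc$truth$plaques))
  expect_true(all(excl$table$area_um2 >= 100))
})

test_that("scenes round-trip through the directory writer", {
  cfg <- small_scene_config(seed = 78, field_um = 96, n_cells = 4,
                            n_other_nuclei = 4, n_plaques = 1, n_tangles = 1,
                            n_astrocytes = 1, min_separation_um = 20)
  sc <- generate_scene(cfg)
  dir <- tempfile("scene")
  write_scene(sc, dir)
  f <- file.path(dir, sprintf("round_%02d_%s.tif", 1, cfg$panel[1]))
  expect_true(file.exists(f))
  img <- read_round_tiff(f, cfg$microns_per_pixel, round_id = 1)
  expect_lt(max(abs(img$pixels - sc$images[[1]]$pixels)), 1 + 1e-9)
  truth <- utils::read.csv(file.path(dir, "truth_cells.csv"))
  expect_equal(nrow(truth), 4)
  t1 <- read_transform_json(file.path(dir, "transform_round_02.json"))
  expect_equal(t1$A, sc$truth$transforms[[2]]$A, tolerance = 1e-9)
})
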