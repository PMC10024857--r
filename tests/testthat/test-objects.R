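# object detection, size exclusion and colocalization

test_that("detect_objects matches a brute-force flood fill on small fields", {
  set.seed(17)
  for (rep in 1:6) {
    bin <- matrix(runif(64 * 64) < 0.35, 64, 64)
    lab <- flood_fill_label(bin)
    objs <- detect_objects(density_map(bin * 1, 1, "x"), threshold = 0.5,
                           min_area = 0)
    expect_equal(nrow(objs$table), max(lab))
    expect_setequal(objs$table$n_px, as.integer(table(lab[lab > 0])))
  }
})

test_that("the minimum-area exclusion is applied at the stated boundary", {
  # blobs of exactly 39 and 41 px at 1 um/px, against a 40 um^2 floor
  m <- matrix(0, 40, 40)
  m[2:14, 2:4] <- 1                     # 13 x 3 = 39 px
  m[20:23, 20:29] <- 1; m[24, 20] <- 1  # 40 + 1 = 41 px
  objs <- detect_objects(density_map(m, 1, "x"), threshold = 0.5,
                         min_area = 40)
  expect_equal(nrow(objs$table), 1L)
  expect_equal(objs$table$n_px, 41L)
  # calibration scales areas: same blobs at 2 um/px are 4x larger
  objs2 <- detect_objects(density_map(m, 2, "x"), threshold = 0.5,
                          min_area = 40)
  expect_equal(nrow(objs2$table), 2L)
  expect_equal(sort(objs2$table$area_um2), c(156, 164))
})

test_that("blank channels yield an empty object set", {
  objs <- detect_objects(density_map(matrix(0, 16, 16), 1, "x"),
                         threshold = 0.5)
  expect_equal(nrow(objs$table), 0L)
  expect_length(objs$pixels, 0L)
})

test_that("centroids and boundaries are reported in micron coordinates", {
  m <- matrix(0, 30, 30)
  m[11:20, 6:15] <- 1   # rows y = 10..19, cols x = 5..14 (0-based)
  objs <- detect_objects(density_map(m, 0.5, "x"), threshold = 0.5,
                         min_area = 0)
  expect_equal(objs$table$x_um, 9.5 * 0.5)
  expect_equal(objs$table$y_um, 14.5 * 0.5)
  expect_equal(objs$table$area_um2, 100 * 0.25)
  bd <- objs$boundary[[1]]
  expect_equal(range(bd[, "x_um"]), c(5, 14) * 0.5)
  expect_equal(range(bd[, "y_um"]), c(10, 19) * 0.5)
})

test_that("a separable synthetic scene yields exactly K cell objects", {
  cfg <- small_scene_config(seed = 31, n_cells = 18, od_sigma = 0,
                            n_process_fragments = 0)
  sc <- generate_scene(cfg)
  sm <- default_stain_matrix()
  r <- match("IBA1", cfg$panel)
  ch <- deconvolve(rgb_to_od(sc$images[[r]]), sm)$amec_red
  # round-r frame: all cells are IBA1+; fragments are off
  objs <- detect_objects(ch, min_area = 40)
  expect_equal(nrow(objs$table), 18L)
})

test_that("process fragments fall below the 40 um^2 exclusion", {
  cfg <- small_scene_config(seed = 32, n_cells = 10, n_process_fragments = 12,
                            od_sigma = 0)
  sc <- generate_scene(cfg)
  sm <- default_stain_matrix()
  r <- match("IBA1", cfg$panel)
  ch <- deconvolve(rgb_to_od(sc$images[[r]]), sm)$amec_red
  with_excl <- detect_objects(ch, min_area = 40)
  without_excl <- detect_objects(ch, min_area = 0)
  expect_equal(nrow(with_excl$table), 10L)
  expect_gt(nrow(without_excl$table), 10L)
})

test_that("pathology size exclusion supports area and diameter readings", {
  m <- matrix(0, 60, 60)
  m[11:20, 11:20] <- 1    # 100 px = 100 um^2, equiv diameter ~ 11.3 um
  m[40:42, 40:42] <- 1    # 9 um^2 speckle
  dm <- density_map(m, 1, "x")
  by_area <- detect_pathology(dm, "abeta_plaque", threshold = 0.5,
                              min_size = 100, metric = "area")
  expect_equal(nrow(by_area$table), 1L)
  expect_equal(by_area$table$kind, "abeta_plaque")
  by_diam <- detect_pathology(dm, "abeta_plaque", threshold = 0.5,
                              min_size = 100, metric = "diameter")
  expect_equal(nrow(by_diam$table), 0L)
})

test_that("colocalize assigns marker vectors from ground truth", {
  cfg <- small_scene_config(seed = 33, od_sigma = 0.005)
  sc <- generate_scene(cfg)
  run <- run_pipeline(sc$images, pipeline_config())
  tab <- run$cells$table
  truth <- sc$truth$cells
  nn <- vapply(seq_len(nrow(tab)), function(i)
    which.min((truth$x_um - tab$x_um[i])^2 + (truth$y_um - tab$y_um[i])^2),
    integer(1))
  expect_lt(max(sqrt((truth$x_um[nn] - tab$x_um)^2 +
                     (truth$y_um[nn] - tab$y_um)^2)), 3)
  for (m in c("IBA1", "P2Y12", "Ferritin", "CD68", "GFAP"))
    expect_gte(mean(tab[[paste0("pos_", m)]] == truth[[m]][nn]), 0.95)
})

test_that("colocalize validates markers and empty object sets", {
  st <- compose_stack(list(list(round = 1, marker = "A",
                                chromogen = density_map(matrix(0, 8, 8), 1, "A"),
                                counterstain = density_map(matrix(0, 8, 8), 1, "h"),
                                transform = NULL)))
  objs <- detect_objects(density_map(matrix(0, 8, 8), 1, "A"), threshold = 0.5)
  out <- colocalize(objs, st, markers = "A")
  expect_equal(nrow(out$table), 0L)
  expect_error(colocalize(objs, st, markers = "missing"), "not in stack")
})
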