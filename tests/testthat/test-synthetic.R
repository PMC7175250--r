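test_that("rendering is bit-identical for a fixed spec", {
  sp <- scene_spec(image_size = 256L, n_com = 10, n_cod = 3, n_nd = 2,
                   n_noise = 2, seed = 77)
  a <- render_scene(sp)
  b <- render_scene(sp)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_identical(a$truth$instances, b$truth$instances)
  # a different seed changes the pixels
  sp2 <- sp; sp2$seed <- 78L
  expect_false(identical(render_scene(sp2)$image$pixels, a$image$pixels))
})

test_that("empty scene renders background only and segments to nothing", {
  sp <- scene_spec(image_size = 128L, n_com = 0, n_cod = 0, n_nd = 0,
                   n_noise = 0, seed = 1)
  sc <- render_scene(sp)
  expect_identical(nrow(sc$truth$instances), 0L)
  expect_true(all(sc$truth$labels == 0L))
  expect_identical(nrow(segment_crystals(sc$image)$segments), 0L)
})

test_that("realized mean crystal lengths hit the 10 and 20 µm targets", {
  sp <- scene_spec(image_size = 1536L, n_com = 100, n_cod = 30, n_nd = 0,
                   n_noise = 0, seed = 8)
  sc <- render_scene(sp)
  inst <- sc$truth$instances
  com <- mean(inst$length_um[inst$class == 0L])
  cod <- mean(inst$length_um[inst$class == 1L])
  expect_lt(abs(com - 10) / 10, 0.1)
  expect_lt(abs(cod - 20) / 20, 0.1)
})

test_that("ground-truth areas equal the rasterized instance areas", {
  sp <- clean_spec(n_com = 6, n_cod = 2, n_nd = 2, seed = 31)
  sc <- render_scene(sp)
  # non-touching scene: the label map carries every instance in full
  painted <- tabulate(sc$truth$labels[sc$truth$labels > 0],
                      nbins = nrow(sc$truth$instances))
  expect_identical(painted, as.integer(sc$truth$instances$pixel_area))
  expect_equal(sc$truth$instances$area,
               sc$truth$instances$pixel_area * sp$pixel_size^2)
})

test_that("impossible packing raises an error", {
  sp <- scene_spec(image_size = 64L, n_com = 200, n_cod = 0, n_nd = 0,
                   n_noise = 0, overlap_probability = 0, seed = 1)
  expect_error(render_scene(sp), "cannot fit")
})

test_that("training fixture has the documented size and imbalance", {
  fix <- small_fixture()
  expect_gte(nrow(fix), 400)
  counts <- table(factor(fix$class, levels = 0:3))
  expect_true(all(counts >= 5))
  expect_gt(sum(counts[c("0", "1")]) / sum(counts), 0.6)  # COM + COD dominate
  expect_identical(length(unique(fix$image_id)), 4L)
  expect_true(all(feature_names() %in% names(fix)))
  expect_true(all(is.finite(as.matrix(fix[feature_names()]))))
})

test_that("a minimal 20-crystal fixture is valid for fivefold CV", {
  fix <- make_training_fixture(n_crystals = 20, seed = 3, n_images = 2,
                               image_size = 256)
  counts <- table(factor(fix$class, levels = 0:3))
  expect_true(all(counts >= 5))
})

test_that("different seeds change pixels but keep class proportions stable", {
  f1 <- make_training_fixture(n_crystals = 150, seed = 1, n_images = 2,
                              image_size = 640)
  f2 <- make_training_fixture(n_crystals = 150, seed = 2, n_images = 2,
                              image_size = 640)
  p1 <- prop.table(table(factor(f1$class, levels = 0:3)))
  p2 <- prop.table(table(factor(f2$class, levels = 0:3)))
  expect_true(all(abs(p1 - p2) < 0.05))
  expect_false(identical(f1$area, f2$area))
})

test_that("dose series generates the full plate layout with a manifest", {
  base <- clean_spec(n_com = 6, n_cod = 2, n_nd = 1, image_size = 256L)
  sp <- dose_series_spec(concentrations_nM = c(100, 1000),
                         total_scale = c(0.8, 0.1),
                         com_size_scale = c(1, 0.8),
                         com_to_cod_shift = c(0, 0.2),
                         cod_elongation = c(1, 1.3),
                         n_experiments = 2, wells_per_sample = 2,
                         fields_per_well = 2, base_spec = base, seed = 4)
  ser <- generate_dose_series(sp)
  # 2 experiments x (control + 2 concentrations) x 2 wells x 2 fields
  expect_identical(nrow(ser$manifest), 2L * 3L * 2L * 2L)
  expect_identical(length(ser$scenes), nrow(ser$manifest))
  key <- ser$manifest[, c("experiment_id", "well_id", "field_index")]
  expect_false(anyDuplicated(key) > 0)
  # regeneration is bit-exact
  ser2 <- generate_dose_series(sp)
  i <- nrow(ser$manifest)
  expect_identical(ser$scenes[[i]]$image$pixels, ser2$scenes[[i]]$image$pixels)
  # ground-truth normalized series tracks the effect function
  gt <- truth_normalized_series(ser)
  for (ex in unique(gt$experiment_id)) {
    g <- gt[gt$experiment_id == ex, ]
    expect_equal(g$normalized_total[g$concentration_nM == 0], 100)
    expect_true(all(diff(g$normalized_total) < 0))  # monotone decreasing
  }
})

test_that("dose series written to disk reloads through the manifest", {
  base <- clean_spec(n_com = 4, n_cod = 1, n_nd = 1, image_size = 256L)
  sp <- dose_series_spec(concentrations_nM = 1000, total_scale = 0.5,
                         com_size_scale = 1, com_to_cod_shift = 0,
                         cod_elongation = 1, n_experiments = 1,
                         wells_per_sample = 1, fields_per_well = 1,
                         base_spec = base, seed = 9)
  dir <- withr::local_tempdir()
  ser <- generate_dose_series(sp, out_dir = dir)
  man <- load_manifest(file.path(dir, "manifest.csv"))
  expect_identical(nrow(man), 2L)
  img <- read_field_image(file.path(dir, man$image_path[1]), 0.32)
  i <- which(ser$manifest$image_path == man$image_path[1])
  expect_identical(img$pixels, ser$scenes[[ser$manifest$scene[i]]]$image$pixels)
})

test_that("needle elongation increases COD aspect ratio", {
  sp1 <- clean_spec(n_com = 0, n_cod = 10, n_nd = 0, seed = 55,
                    image_size = 640L)
  sp2 <- sp1; sp2$cod_elongation <- 1.8
  f <- function(sp) {
    sc <- render_scene(sp)
    seg <- segment_crystals(sc$image)
    fe <- extract_features(sc$image, seg$labels, seg$segments)
    mean(fe$major_axis / fe$minor_axis)
  }
  expect_gt(f(sp2), f(sp1))
})
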