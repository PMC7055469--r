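test_that("scene generation is bit-identical for a fixed seed", {
  a <- generate_scene(small_spec(7))
  b <- generate_scene(small_spec(7))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$annotations, b$annotations)
})

test_that("true count equals the number of rendered pods", {
  s <- generate_scene(small_spec(11, n_siliques = 8), render_image = FALSE)
  expect_equal(s$true_count, 8)
  expect_equal(length(s$silique_lengths), 8)
  expect_equal(s$placement_failures, 0)
})

test_that("mask uses only the documented class codes", {
  s <- generate_scene(small_spec(3), render_image = FALSE)
  expect_true(all(unique(as.vector(s$mask)) %in% c(0:3, 255)))
  # all four plant classes present in a populated scene
  expect_setequal(setdiff(unique(as.vector(s$mask)), 255), 0:3)
})

test_that("background pixels sit near the requested intensity", {
  s <- generate_scene(small_spec(5, background_intensity = 245, noise_sd = 2))
  bg <- s$image[, , 1][s$mask == POD_BACKGROUND]
  expect_gt(mean(bg), 240)
  expect_lt(sd(bg), 6)
})

test_that("a forced overlap pair subtends the requested angle on the mask", {
  s <- generate_scene(scene_spec(n_siliques = 2, n_overlap_pairs = 1,
                                 overlap_angle_range = c(0.2, 0.2), seed = 21),
                      render_image = FALSE)
  expect_equal(s$true_count, 2)
  cnt <- count_image(mask_to_labels(s$mask))
  expect_equal(cnt$count, 2)
  v1 <- c(cnt$siliques$vec_x[1], cnt$siliques$vec_y[1])
  v2 <- c(cnt$siliques$vec_x[2], cnt$siliques$vec_y[2])
  expect_lt(abs(pair_angle(v1, v2) - 0.2), 0.06)  # rasterisation error
})

test_that("every pod contributes one tip and one base annotation", {
  s <- generate_scene(small_spec(13, n_siliques = 5), render_image = FALSE)
  ann <- s$annotations
  expect_equal(sum(ann$class_name == "tip"), 5)
  expect_equal(sum(ann$class_name == "base"), 5)
})

test_that("annotation points lie on pixels of their own class", {
  s <- generate_scene(small_spec(17, n_siliques = 6), render_image = FALSE)
  ann <- scene_to_annotations(s, points_per_body = 2, points_per_stem = 8)
  for (j in seq_len(nrow(ann))) {
    expect_equal(class_name(s$mask[ann$y[j] + 1, ann$x[j] + 1]),
                 ann$class_name[j])
  }
})

test_that("points_per_body = 0 yields no body annotations", {
  s <- generate_scene(small_spec(19, n_siliques = 4), render_image = FALSE)
  ann <- scene_to_annotations(s, points_per_body = 0, points_per_stem = 0)
  expect_false(any(ann$class_name %in% c("body", "stem")))
})

test_that("an overfull canvas reports placement failures with the count placed", {
  s <- generate_scene(scene_spec(width = 260, height = 400, n_siliques = 30,
                                 n_overlap_pairs = 0, seed = 2),
                      render_image = FALSE)
  expect_gt(s$placement_failures, 0)
  expect_lt(s$true_count, 30)
  expect_equal(length(s$silique_lengths), s$true_count)
})

test_that("rendered pod lengths stay inside the requested range", {
  lens <- unlist(lapply(1:8, function(k)
    generate_scene(small_spec(40 + k, n_siliques = 13),
                   render_image = FALSE)$silique_lengths))
  expect_gte(length(lens), 100)
  expect_true(all(lens >= 240 - 1e-9 & lens <= 340 + 1e-9))
  expect_gt(mean(lens), 240)
  expect_lt(mean(lens), 340)
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(scene_spec(tip_fraction = 0.6, base_fraction = 0.5))
  expect_error(scene_spec(overlap_angle_range = c(0, 0.5)))
  expect_error(scene_spec(n_siliques = 1, n_overlap_pairs = 1))
})

test_that("mask_to_labels takes the majority plant class per block", {
  m <- matrix(POD_BACKGROUND, 32, 32)
  m[1:16, 1:16] <- 3L                 # pure tip block
  m[1:10, 17:32] <- 1L                # body majority over base
  m[11:16, 17:32] <- 0L
  m[17, 1] <- 2L                      # single stem pixel in its block
  lab <- mask_to_labels(m)
  expect_equal(dim(lab), c(2, 2))
  expect_equal(lab[1, 1], 3L)
  expect_equal(lab[1, 2], 1L)
  expect_equal(lab[2, 1], 2L)
  expect_equal(lab[2, 2], POD_BACKGROUND)
})

test_that("mask_to_labels breaks exact ties towards the lower class code", {
  m <- matrix(POD_BACKGROUND, 32, 32)
  m[1:8, 1:16] <- 3L
  m[9:16, 1:16] <- 0L                 # 128 tip vs 128 base
  lab <- mask_to_labels(m)
  expect_equal(lab[1, 1], 0L)
})

test_that("scene artefacts round-trip through disk", {
  s <- generate_scene(small_spec(23, n_siliques = 4))
  dir <- tempfile("scene_io_")
  paths <- write_scene(s, dir)
  expect_true(all(file.exists(paths)))
  m <- read_mask(paths[["mask"]])
  expect_identical(m, s$mask)
  ann <- read_annotations(paths[["annotations"]])
  expect_equal(nrow(ann), nrow(s$annotations))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$true_count, s$true_count)
})
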