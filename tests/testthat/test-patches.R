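test_that("annotation CSV round-trips exactly", {
  set.seed(1)
  ann <- data.frame(image_id = sprintf("img%02d", sample(5, 100, TRUE)),
                    x = sample(0:3000, 100), y = sample(0:5000, 100),
                    class_name = sample(POD_CLASSES, 100, TRUE))
  path <- tempfile(fileext = ".csv")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(back, ann)
})

test_that("unknown class names are rejected with a line number", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("image_id,x,y,class_name", "a,1,2,tip", "a,3,4,flower"), path)
  expect_error(read_annotations(path), "flower")
  expect_error(read_annotations(path), "line 3")
})

test_that("an empty annotation file yields an empty list", {
  path <- tempfile(fileext = ".csv")
  writeLines("image_id,x,y,class_name", path)
  expect_equal(nrow(read_annotations(path)), 0)
})

test_that("image split sizes follow largest-remainder rounding", {
  ids144 <- sprintf("im%03d", 1:144)
  sp <- split_images(ids144, seed = 4)
  expect_equal(lengths(sp[c("train_ids", "val_ids", "test_ids")]),
               c(train_ids = 93, val_ids = 29, test_ids = 22))
  sp100 <- split_images(sprintf("im%03d", 1:100), seed = 4)
  expect_equal(lengths(sp100[c("train_ids", "val_ids", "test_ids")]),
               c(train_ids = 65, val_ids = 20, test_ids = 15))
})

test_that("splits are disjoint, exhaustive, deterministic and order-invariant", {
  ids <- sprintf("scan_%02d", 1:37)
  a <- split_images(ids, seed = 9)
  b <- split_images(rev(ids), seed = 9)
  expect_identical(a, b)
  all_ids <- c(a$train_ids, a$val_ids, a$test_ids)
  expect_setequal(all_ids, ids)
  expect_equal(anyDuplicated(all_ids), 0)
  expect_identical(a, split_images(ids, seed = 9))
  expect_false(identical(a$train_ids, split_images(ids, seed = 10)$train_ids))
})

test_that("too few ids for the partitions is an error", {
  expect_error(split_images(c("a", "b")), "fewer")
})

test_that("training windows are centred, half-open and border-checked", {
  H <- 200; W <- 300
  img <- array(0, c(H, W, 3))
  img[, , 1] <- matrix(rep(0:(W - 1), each = H), H, W)   # encodes x
  img[, , 2] <- matrix(rep(0:(H - 1), W), H, W)          # encodes y
  p <- extract_training_patch(img, 100, 100)
  expect_equal(dim(p), c(50, 50, 3))
  expect_equal(p[1, 1, 1], 75)    # first column = x - 25
  expect_equal(p[50, 50, 1], 124) # last column = x + 24 (half-open)
  expect_equal(p[1, 1, 2], 75)
  expect_equal(p[50, 50, 2], 124)
  expect_null(extract_training_patch(img, 24, 24))
  expect_null(extract_training_patch(img, W - 24, 100))
  expect_equal(dim(extract_training_patch(img, W - 25, 100)), c(50, 50, 3))
  p_edge <- extract_training_patch(img, 25, 25)
  expect_equal(dim(p_edge), c(50, 50, 3))
})

test_that("a uniform image yields a uniform patch", {
  img <- array(87, c(100, 100, 3))
  expect_true(all(extract_training_patch(img, 50, 50) == 87))
})

test_that("augmented crops contain only source pixels and are 32x32", {
  set.seed(2)
  p50 <- array(sample(1000, 50 * 50 * 3, TRUE), c(50, 50, 3))
  for (i in 1:20) {
    a <- augment_patch(p50)
    expect_equal(dim(a), c(32, 32, 3))
    expect_true(all(a %in% p50))
  }
  expect_error(augment_patch(array(0, c(32, 32, 3))), "50x50")
})

test_that("augmentation is deterministic under a fixed RNG state", {
  p50 <- array(runif(50 * 50 * 3), c(50, 50, 3))
  a <- withr::with_seed(5, augment_patch(p50))
  b <- withr::with_seed(5, augment_patch(p50))
  expect_identical(a, b)
})

test_that("crop offsets are uniform over the 19 x 19 lattice", {
  p50 <- array(0, c(50, 50, 3))
  offs <- withr::with_seed(8, {
    t(replicate(10000, attr(augment_patch(p50), "offset")))
  })
  expect_true(all(offs >= 0 & offs <= 18))
  for (axis in 1:2) {
    tab <- tabulate(offs[, axis] + 1L, nbins = 19)
    p <- chisq.test(tab)$p.value
    expect_gt(p, 0.01)
  }
})

test_that("centre crop takes the middle 32x32 window", {
  p50 <- array(seq_len(50 * 50 * 3), c(50, 50, 3))
  cc <- center_crop(p50)
  expect_equal(cc, p50[10:41, 10:41, , drop = FALSE], ignore_attr = TRUE)
})

test_that("normalisation statistics behave per definition", {
  set.seed(3)
  x <- array(runif(32 * 32 * 3 * 40, 0, 255), c(32, 32, 3, 40))
  st <- fit_normalization(x)
  z <- apply_normalization(x, st, mode = "channel_zscore")
  for (ch in 1:3) {
    expect_lt(abs(mean(z[, , ch, ])), 1e-10)
    expect_lt(abs(sd(as.vector(z[, , ch, ])) - 1), 1e-2)
  }
  # normalising the mean patch itself under mean_patch mode gives zero
  zz <- apply_normalization(x, st, mode = "channel_zscore")
  mp_only <- apply_normalization(st$mean_patch +
                                   array(0, c(32, 32, 3)), st,
                                 mode = "mean_patch")
  expect_lt(max(abs(mp_only)), 1e-12)
})

test_that("degenerate and mismatched normalisation inputs error", {
  const <- array(100, c(32, 32, 3, 10))
  expect_error(fit_normalization(const), "constant")
  x <- array(runif(32 * 32 * 3 * 5), c(32, 32, 3, 5))
  st <- fit_normalization(array(runif(32 * 32 * 3 * 8), c(32, 32, 3, 8)))
  expect_error(apply_normalization(array(0, c(16, 16, 3, 2)), st), "shape")
})

test_that("patch datasets track per-class counts and border skips", {
  s <- generate_scene(small_spec(29, n_siliques = 5))
  ann <- scene_to_annotations(s, points_per_body = 1, points_per_stem = 6)
  ds <- build_patch_dataset(list(s), list(ann), augment = TRUE,
                            augment_per_point = 2, seed = 1)
  expect_equal(dim(ds$x)[1:3], c(32, 32, 3))
  expect_equal(dim(ds$x)[4], length(ds$y))
  expect_equal(length(ds$y), 2 * (sum(ds$counts)))
  expect_equal(sum(ds$counts) + ds$skipped, nrow(ann))
  expect_true(all(ds$y %in% 0:3))
})
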