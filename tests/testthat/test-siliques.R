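bg_labels <- function(nr = 12, nc = 12) matrix(POD_BACKGROUND, nr, nc)

test_that("regions are 8-connected within a class and area-filtered", {
  lab <- bg_labels()
  lab[2, 3:5] <- 3L                      # 3x1 tip run
  r <- extract_regions(lab, min_region_area = 1)
  expect_length(r, 1)
  expect_equal(r[[1]]$class, 3L)
  expect_equal(r[[1]]$area, 3)
  # diagonal-touching cells of one class form a single region
  lab2 <- bg_labels()
  lab2[4, 4] <- 3L
  lab2[5, 5] <- 3L
  expect_length(extract_regions(lab2, min_region_area = 1), 1)
  # min_region_area removes isolated speckle
  expect_length(extract_regions(lab2, min_region_area = 2), 1)
  lab3 <- bg_labels()
  lab3[4, 4] <- 3L
  expect_length(extract_regions(lab3, min_region_area = 2), 0)
  # adjacent cells of different classes stay separate regions
  lab4 <- bg_labels()
  lab4[6, 6] <- 3L
  lab4[6, 7] <- 1L
  expect_length(extract_regions(lab4, min_region_area = 1), 2)
})

test_that("region centroids sit at the cell-centre mean", {
  lab <- bg_labels()
  lab[3, 4:6] <- 1L
  r <- extract_regions(lab, 1)[[1]]
  expect_equal(unname(r$centroid), c(4.5, 2.5))  # x = mean(cols) - .5, y = row - .5
})

test_that("candidates require a tip, a body and a base linked through bodies", {
  lab <- draw_pod_labels(bg_labels(), 2, 2, 1, 0)
  cands <- build_candidates(extract_regions(lab, 1))
  expect_length(cands, 1)
  # tip-body with no base: not a silique
  lab2 <- bg_labels()
  lab2[2, 2] <- 3L
  lab2[3:5, 2] <- 1L
  expect_length(build_candidates(extract_regions(lab2, 1)), 0)
  # a base alone cannot seed a candidate either
  lab3 <- bg_labels()
  lab3[2, 2] <- 0L
  expect_length(build_candidates(extract_regions(lab3, 1)), 0)
})

test_that("stem regions terminate candidate growth", {
  lab <- bg_labels(20, 7)
  lab <- draw_pod_labels(lab, 2, 3, 1, 0)       # pod 1: rows 2-9 downwards
  lab[10, 3] <- 2L                              # stem between the pods
  lab <- draw_pod_labels(lab, 18, 3, -1, 0)     # pod 2: rows 18-11 upwards
  cands <- build_candidates(extract_regions(lab, 1))
  expect_length(cands, 2)
  count <- count_image(lab)
  expect_equal(count$count, 2)
})

test_that("pair_angle is the unsigned vector angle", {
  expect_equal(pair_angle(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(pair_angle(c(2, 1), c(2, 1)), 0)
  expect_equal(pair_angle(c(1, 0), c(1, 0.1)), 0.0997, tolerance = 1e-3)
  expect_equal(pair_angle(c(1, 0), c(-1, 0)), pi)
  expect_error(pair_angle(c(0, 0), c(1, 0)), "zero")
})

# two tips joined to one shared base through a V of bodies; the V half-angle
# is set by the column offset per row step; tip and base span two cells
v_shape <- function(spread) {
  lab <- bg_labels(16, 30)
  base_r <- 13; base_c <- 15
  lab[base_r, base_c] <- 0L
  lab[base_r + 1, base_c] <- 0L
  for (i in 1:8) {
    lab[base_r - i, base_c - round(i * spread)] <- 1L
    lab[base_r - i, base_c + round(i * spread)] <- 1L
  }
  for (i in 9:10) {
    lab[base_r - i, base_c - round(i * spread)] <- 3L
    lab[base_r - i, base_c + round(i * spread)] <- 3L
  }
  lab
}

test_that("the angle rule splits wide pairs and merges near-parallel ones", {
  wide <- v_shape(0.5)            # ~0.9 rad between the arms
  cands <- build_candidates(extract_regions(wide, 1))
  expect_length(cands, 1)
  expect_length(resolve_candidate(cands[[1]], extract_regions(wide, 1)), 2)
  expect_equal(count_image(wide)$count, 2)
  # the same structure is one silique under a huge threshold
  expect_equal(count_image(wide, counter_config(angle_threshold = 2))$count, 1)
})

test_that("a single tip-base pair is one silique regardless of threshold", {
  lab <- draw_pod_labels(bg_labels(), 2, 2, 1, 0)
  for (thr in c(1e-6, 0.05, 2)) {
    expect_equal(count_image(lab, counter_config(angle_threshold = thr))$count,
                 1)
  }
})

test_that("counts are non-increasing in the angle threshold", {
  s <- generate_scene(scene_spec(n_siliques = 6, n_overlap_pairs = 2,
                                 seed = 51), render_image = FALSE)
  lab <- mask_to_labels(s$mask)
  counts <- vapply(c(0.01, 0.05, 0.3, 0.8, 2),
                   function(thr) count_image(lab, counter_config(
                     angle_threshold = thr))$count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("length is the centroid distance in full-resolution pixels", {
  regions <- list(
    list(class = 3L, cells = cbind(1, 1), centroid = c(x = 3, y = 4), area = 1),
    list(class = 0L, cells = cbind(5, 1), centroid = c(x = 0, y = 0), area = 1))
  s <- list(tip = 1, base = 2,
            vector = (regions[[1]]$centroid - regions[[2]]$centroid) * 16,
            length = 80)
  len <- measure_length(s)
  expect_equal(as.numeric(len), 80)     # 3-4-5 triangle, x 16 px
  expect_true(attr(len, "valid"))
  s0 <- list(vector = c(x = 0, y = 0))
  len0 <- measure_length(s0)
  expect_equal(as.numeric(len0), 0)
  expect_false(attr(len0, "valid"))
})

test_that("measured lengths of straight synthetic pods track the truth", {
  s <- generate_scene(small_spec(53, n_siliques = 3, length_range = c(260, 300)),
                      render_image = FALSE)
  cnt <- count_image(mask_to_labels(s$mask))
  expect_equal(cnt$count, 3)
  got <- sort(cnt$siliques$length_px)
  # centroid-to-centroid spans (1 - tip/2 - base/2) of the drawn length
  want <- sort(s$silique_lengths) * (1 - 0.14 / 2 - 0.18 / 2)
  expect_true(all(abs(got - want) <= 2 * 16))
})

test_that("an empty label image counts zero siliques", {
  cnt <- count_image(bg_labels())
  expect_equal(cnt$count, 0)
  expect_equal(nrow(cnt$siliques), 0)
  expect_true(is.na(cnt$summary$mean_length_px))
})

test_that("adding a disjoint complete pod raises the count by exactly one", {
  lab <- draw_pod_labels(bg_labels(20, 20), 2, 3, 1, 0)
  base <- count_image(lab)$count
  lab2 <- draw_pod_labels(lab, 2, 12, 1, 0)
  expect_equal(count_image(lab2)$count, base + 1)
})

test_that("rotating a scene by 90 degrees leaves the count unchanged", {
  s <- generate_scene(scene_spec(n_siliques = 8, n_overlap_pairs = 1,
                                 seed = 57), render_image = FALSE)
  lab <- mask_to_labels(s$mask)
  rot <- t(lab)[ncol(lab):1, ]          # 90-degree rotation of the lattice
  expect_equal(count_image(rot)$count, count_image(lab)$count)
})

test_that("per-image records carry count and length statistics", {
  s <- generate_scene(small_spec(59, n_siliques = 5), render_image = FALSE)
  cnt <- count_image(mask_to_labels(s$mask), image_id = "scene59")
  expect_equal(cnt$summary$image_id, "scene59")
  expect_equal(cnt$summary$predicted_count, 5)
  expect_equal(cnt$summary$mean_length_px, mean(cnt$siliques$length_px))
  expect_gte(cnt$summary$min_length_px, 0)
  expect_lte(cnt$summary$min_length_px, cnt$summary$max_length_px)
})

test_that("the detection overlay marks counted silique regions", {
  lab <- draw_pod_labels(bg_labels(), 2, 2, 1, 0)
  ov <- detection_overlay(lab)
  expect_equal(sum(ov), 8)   # 2 tip + 4 body + 2 base cells
  expect_equal(dim(ov), dim(lab))
})
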