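#' Sliding-window tiling with 50% overlap
#'
#' Decomposes an image into 32x32 tiles on a stride-16 lattice: tile (i, j)
#' (0-based) covers rows `[16 i, 16 i + 32)` and columns `[16 j, 16 j + 32)`.
#' The image is padded on the bottom and right with the scene background
#' estimate (median of the corner pixels) to the next multiple of the stride,
#' so every tile is full-size and the grid covers every pixel. For a
#' dimension of size D divisible by the stride, the tile count along it is
#' `D/16 - 1`.
#'
#' @param image H x W x 3 numeric array (0-255)
#' @param patch_size tile edge (default 32)
#' @param stride lattice stride; must equal `patch_size / 2`
#' @param return_patches also return the extracted tile batch
#' @return list with `grid` (geometry: `grid_rows`, `grid_cols`,
#'   `patch_size`, `stride`, `H`, `W`, `H_pad`, `W_pad`, `pad_value`) and,
#'   when requested, `patches` (32x32x3xN array in row-major tile order
#'   `n = i * grid_cols + j`) and `padded` (the padded image)
#' @export
tile_image <- function(image, patch_size = 32, stride = 16,
                       return_patches = TRUE) {
  stopifnot(stride * 2 == patch_size)
  d <- dim(image)
  if (length(d) != 3 || d[1] < 2 || d[2] < 2) stop("degenerate image")
  H <- d[1]; W <- d[2]
  Hp <- max(2, ceiling(H / stride)) * stride
  Wp <- max(2, ceiling(W / stride)) * stride
  pad_value <- vapply(1:3, function(ch) {
    k <- min(8, H, W)
    median(c(image[1:k, 1:k, ch], image[1:k, W - k + 1:k - 0, ch],
             image[H - k + 1:k - 0, 1:k, ch], image[H - k + 1:k - 0, W - k + 1:k - 0, ch]))
  }, numeric(1))
  padded <- array(rep(pad_value, each = Hp * Wp), c(Hp, Wp, 3))
  padded[1:H, 1:W, ] <- image
  grid <- list(grid_rows = Hp / stride - 1L, grid_cols = Wp / stride - 1L,
               patch_size = patch_size, stride = stride,
               H = H, W = W, H_pad = Hp, W_pad = Wp, pad_value = pad_value)
  out <- list(grid = grid)
  if (return_patches) {
    out$patches <- extract_tiles(padded, grid, seq_len(grid$grid_rows * grid$grid_cols))
    out$padded <- padded
  }
  out
}

# extract tiles (1-based linear tile ids, row-major n = i*grid_cols + j + 1)
extract_tiles <- function(padded, grid, ids) {
  ps <- grid$patch_size
  st <- grid$stride
  x <- array(0, c(ps, ps, 3, length(ids)))
  for (k in seq_along(ids)) {
    n <- ids[k] - 1L
    i <- n %/% grid$grid_cols
    j <- n %% grid$grid_cols
    x[, , , k] <- padded[st * i + 1:ps, st * j + 1:ps, , drop = FALSE]
  }
  x
}

#' Background test for a raw tile
#'
#' A tile is background when the fraction of its pixels whose minimum channel
#' intensity reaches `white_level` exceeds `coverage_frac`; tiles with at
#' least 1% plant pixels (at the defaults) count as foreground. Operates on
#' raw (un-normalised) intensities.
#'
#' @param patch 32x32x3 array, 0-255 scale
#' @param white_level intensity from which a pixel counts as white
#' @param coverage_frac white-pixel fraction above which the tile is
#'   background
#' @return logical
#' @export
is_background <- function(patch, white_level = 230, coverage_frac = 0.99) {
  mins <- pmin(patch[, , 1], patch[, , 2], patch[, , 3])
  mean(mins >= white_level) > coverage_frac
}

#' Classify every foreground tile of an image
#'
#' Tiles the image at 50% overlap, flags background tiles by thresholding the
#' raw intensities, normalises the image with the training statistics
#' (channel z-score plus mean-patch subtraction, as during training) and runs
#' the classifier on the foreground tiles in batches.
#'
#' @param model a trained model
#' @param image H x W x 3 array (0-255)
#' @param stats normalisation statistics from the model's training run
#' @param white_level,coverage_frac background-test parameters
#' @param chunk tile batch size
#' @return a `pod_grid`: list with `probs` (grid_rows x grid_cols x 4),
#'   `foreground` (logical matrix), `grid` (geometry)
#' @export
predict_image <- function(model, image, stats, white_level = 230,
                          coverage_frac = 0.99, chunk = 64L) {
  if (is.null(stats$mean_patch)) stop("stats must come from fit_normalization()")
  tl <- tile_image(image, return_patches = FALSE)
  grid <- tl$grid
  Hp <- grid$H_pad; Wp <- grid$W_pad
  padded_raw <- array(rep(grid$pad_value, each = Hp * Wp), c(Hp, Wp, 3))
  padded_raw[1:grid$H, 1:grid$W, ] <- image
  padded_norm <- padded_raw
  for (ch in 1:3)
    padded_norm[, , ch] <- (padded_norm[, , ch] - stats$channel_means[ch]) /
      stats$channel_sds[ch]
  nt <- grid$grid_rows * grid$grid_cols
  # vectorised equivalent of is_background() over the tile lattice: white
  # pixels counted per 16 px block, then summed over each tile's 2x2 blocks
  white <- pmin(padded_raw[, , 1], padded_raw[, , 2],
                padded_raw[, , 3]) >= white_level
  st <- grid$stride
  nbr <- Hp / st; nbc <- Wp / st
  blk <- colSums(aperm(colSums(array(white, c(st, nbr, st, nbc))), c(2, 1, 3)))
  tile_white <- blk[1:(nbr - 1), 1:(nbc - 1), drop = FALSE] +
    blk[2:nbr, 1:(nbc - 1), drop = FALSE] +
    blk[1:(nbr - 1), 2:nbc, drop = FALSE] + blk[2:nbr, 2:nbc, drop = FALSE]
  fg_mat <- !(tile_white / grid$patch_size^2 > coverage_frac)
  fg <- as.logical(t(fg_mat))   # row-major tile order
  # per-sub-patch plant-pixel counts (plant regions are identified from the
  # background by pixel thresholding before any class is assigned)
  plant_blk <- st^2 - blk
  probs <- matrix(NA_real_, nt, 4)
  fg_ids <- which(fg)
  i <- 1L
  while (i <= length(fg_ids)) {
    j <- min(i + chunk - 1L, length(fg_ids))
    ids <- fg_ids[i:j]
    batch <- extract_tiles(padded_norm, grid, ids)
    batch <- batch - as.numeric(stats$mean_patch)
    probs[ids, ] <- predict_proba(model, batch, chunk = chunk)
    i <- j + 1L
  }
  structure(list(
    probs = array(t(probs), c(4, grid$grid_cols, grid$grid_rows)) |>
      aperm(c(3, 2, 1)),
    foreground = matrix(fg, grid$grid_rows, grid$grid_cols, byrow = TRUE),
    plant = plant_blk,
    grid = grid), class = "pod_grid")
}
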