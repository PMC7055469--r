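#' Read / write point annotations
#'
#' Annotations are CSV files with header `image_id,x,y,class_name`;
#' coordinates are 0-based (x = column, y = row) and `class_name` must be one
#' of base, body, stem, tip. Reading and writing are exact inverses.
#'
#' @param path CSV file path
#' @return `read_annotations` returns a data frame of annotations
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("image_id", "x", "y", "class_name")
  if (!identical(names(df)[seq_along(req)], req))
    stop("annotation CSV must have header image_id,x,y,class_name")
  if (nrow(df) == 0) {
    return(data.frame(image_id = character(0), x = numeric(0), y = numeric(0),
                      class_name = character(0)))
  }
  bad <- which(!(df$class_name %in% names(CLASS_CODES)))
  if (length(bad) > 0)
    stop(sprintf("unknown class name '%s' at line %d of %s",
                 df$class_name[bad[1]], bad[1] + 1L, path))
  badxy <- which(!is.finite(df$x) | !is.finite(df$y) | df$x < 0 | df$y < 0)
  if (length(badxy) > 0)
    stop(sprintf("malformed coordinates at line %d of %s", badxy[1] + 1L, path))
  df[, req]
}

#' @rdname read_annotations
#' @param annotations a data frame with columns image_id, x, y, class_name
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(c("image_id", "x", "y", "class_name") %in% names(annotations)))
  if (nrow(annotations) > 0 &&
      !all(annotations$class_name %in% names(CLASS_CODES)))
    stop("annotations contain unknown class names")
  write.csv(annotations[, c("image_id", "x", "y", "class_name")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split image ids into train / validation / test sets
#'
#' The split is at image level (never at patch level). Sizes follow
#' largest-remainder rounding of `fractions` with ties resolved in favour of
#' later partitions, so 144 images at (0.65, 0.20, 0.15) give sizes
#' (93, 29, 22). Ids are sorted before the seeded shuffle, making the
#' assignment invariant to input ordering.
#'
#' @param image_ids character vector of image ids
#' @param fractions length-3 fractions summing to 1
#' @param seed integer seed
#' @return list with `train_ids`, `val_ids`, `test_ids`, `fractions`, `seed`
#' @export
split_images <- function(image_ids, fractions = c(0.65, 0.20, 0.15), seed = 1) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3)
  image_ids <- unique(as.character(image_ids))
  n <- length(image_ids)
  if (n < length(fractions)) stop("fewer image ids than partitions")
  quota <- n * fractions
  sizes <- floor(quota)
  rem <- round(quota - sizes, 9)   # exact ties must compare as ties
  left <- n - sum(sizes)
  if (left > 0) {
    # largest remainder; ties go to later partitions
    ord <- order(-rem, -seq_along(rem))
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1
  }
  shuffled <- withr::with_seed(as.integer(seed),
                               sample(sort(image_ids)))
  list(train_ids = shuffled[seq_len(sizes[1])],
       val_ids = shuffled[sizes[1] + seq_len(sizes[2])],
       test_ids = shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])],
       fractions = fractions, seed = as.integer(seed))
}

#' Extract the 50x50 training window around an annotation
#'
#' The window covers rows `[y-25, y+25)` and columns `[x-25, x+25)` in
#' 0-based half-open convention. Annotations closer than 25 px to any border
#' are skipped (returns `NULL`): padding would fabricate plant tissue.
#'
#' @param image H x W x 3 numeric array (0-255)
#' @param x,y 0-based annotation coordinates (x = column, y = row)
#' @param window window edge length (default 50)
#' @return a window x window x 3 array, or `NULL` when skipped
#' @export
extract_training_patch <- function(image, x, y, window = 50) {
  half <- window / 2
  H <- dim(image)[1]; W <- dim(image)[2]
  x <- round(x); y <- round(y)
  if (y - half < 0 || x - half < 0 || y + half > H || x + half > W)
    return(NULL)
  image[(y - half + 1):(y + half), (x - half + 1):(x + half), , drop = FALSE]
}

#' Augment a 50x50 window into a 32x32 training patch
#'
#' A uniformly random 32x32 crop fully inside the window, then a horizontal
#' mirror with probability 1/2, then a rotation by k*90 degrees with k
#' uniform on {0,1,2,3}. Every output pixel exists in the source window. The
#' crop offset, mirror flag and rotation are recorded as attributes.
#'
#' @param patch50 a 50x50x3 array
#' @param out output patch edge (default 32)
#' @return a 32x32x3 array with attributes `offset`, `mirrored`, `rot_k`
#' @export
augment_patch <- function(patch50, out = 32) {
  d <- dim(patch50)
  if (length(d) != 3 || d[1] != 50 || d[2] != 50)
    stop("augment_patch expects a 50x50x3 window")
  maxoff <- d[1] - out
  ox <- sample.int(maxoff + 1L, 1L) - 1L
  oy <- sample.int(maxoff + 1L, 1L) - 1L
  p <- patch50[(oy + 1):(oy + out), (ox + 1):(ox + out), , drop = FALSE]
  mirrored <- runif(1) < 0.5
  if (mirrored) p <- p[, out:1, , drop = FALSE]
  k <- sample.int(4L, 1L) - 1L
  p <- rot90_array(p, k)
  attr(p, "offset") <- c(x = ox, y = oy)
  attr(p, "mirrored") <- mirrored
  attr(p, "rot_k") <- k
  p
}

rot90_array <- function(a, k) {
  k <- k %% 4
  if (k == 0) return(a)
  for (i in seq_len(k)) {
    # 90 degrees counter-clockwise: new[r,c] = old[c, n-r+1]
    a <- aperm(a, c(2, 1, 3))[dim(a)[2]:1, , , drop = FALSE]
  }
  a
}

#' Centred 32x32 crop of a 50x50 window
#'
#' Used for validation and test patches, which bypass augmentation.
#' @param patch50 a 50x50x3 array
#' @param out output edge
#' @return the centred crop
#' @export
center_crop <- function(patch50, out = 32) {
  d <- dim(patch50)
  off <- floor((d[1] - out) / 2)
  patch50[(off + 1):(off + out), (off + 1):(off + out), , drop = FALSE]
}

#' Normalisation statistics of a training patch set
#'
#' Channel-wise means and standard deviations plus the mean patch, all
#' computed on the training split only. The mean patch is computed on the
#' channel-standardised patches, matching how it is later subtracted.
#'
#' @param train_patches 32x32x3xN array of raw training patches (0-255)
#' @return list with `channel_means`, `channel_sds`, `mean_patch`
#' @export
fit_normalization <- function(train_patches) {
  d <- dim(train_patches)
  stopifnot(length(d) == 4, d[3] == 3)
  m <- matrix(aperm(train_patches, c(1, 2, 4, 3)), ncol = 3)
  mu <- colMeans(m)
  sds <- apply(m, 2, sd)
  if (any(sds <= 0 | !is.finite(sds)))
    stop("zero channel standard deviation; cannot normalise a constant dataset")
  z <- train_patches
  for (ch in 1:3) z[, , ch, ] <- (z[, , ch, ] - mu[ch]) / sds[ch]
  mean_patch <- apply(z, c(1, 2, 3), mean)
  list(channel_means = mu, channel_sds = sds, mean_patch = mean_patch)
}

#' Apply normalisation to patches
#'
#' `mode = "channel_zscore"` standardises each channel with the training
#' means/sds; `mode = "mean_patch"` subtracts the training mean patch;
#' `mode = "both"` (the model-input default) composes them: z-score first,
#' then mean-patch subtraction.
#'
#' @param patches 32x32x3 array or 32x32x3xN batch
#' @param stats statistics from [fit_normalization()]
#' @param mode normalisation mode
#' @return normalised array of the same shape
#' @export
apply_normalization <- function(patches, stats,
                                mode = c("both", "channel_zscore", "mean_patch")) {
  mode <- match.arg(mode)
  single <- length(dim(patches)) == 3
  if (single) dim(patches) <- c(dim(patches), 1)
  d <- dim(patches)
  if (mode %in% c("mean_patch", "both") &&
      !all(d[1:3] == dim(stats$mean_patch)))
    stop("patch shape does not match the fitted mean patch")
  if (mode %in% c("channel_zscore", "both")) {
    for (ch in 1:3)
      patches[, , ch, ] <- (patches[, , ch, ] - stats$channel_means[ch]) /
        stats$channel_sds[ch]
  }
  if (mode %in% c("mean_patch", "both"))
    patches <- patches - as.numeric(stats$mean_patch)
  if (single) dim(patches) <- d[1:3]
  patches
}

#' Build a labelled patch dataset from scenes
#'
#' Extracts 50x50 windows centred at the annotations of each scene, skipping
#' (and counting) annotations within 25 px of a border. Training scenes yield
#' `augment_per_point` augmented 32x32 crops per annotation; validation/test
#' scenes yield the single centred 32x32 crop. Per-class annotation counts
#' are recorded.
#'
#' @param scenes list of `scene_truth` objects
#' @param annotations_per_scene list of annotation data frames (one per
#'   scene), e.g. from [scene_to_annotations()]
#' @param augment augment (training) or take centred crops (validation/test)
#' @param augment_per_point augmented samples per annotation
#' @param seed seed for the augmentation draws
#' @return list with `x` (32x32x3xN raw patch array), `y` (0-based codes),
#'   `counts` (per-class annotation counts), `skipped` (border skips)
#' @export
build_patch_dataset <- function(scenes, annotations_per_scene,
                                augment = TRUE, augment_per_point = 4,
                                seed = 1) {
  stopifnot(length(scenes) == length(annotations_per_scene))
  withr::with_seed(as.integer(seed), {
    xs <- list()
    ys <- integer(0)
    skipped <- 0L
    counts <- setNames(integer(4), POD_CLASSES)
    for (i in seq_along(scenes)) {
      img <- scenes[[i]]$image
      if (is.null(img)) stop("scene was generated without an image")
      ann <- annotations_per_scene[[i]]
      for (j in seq_len(nrow(ann))) {
        p50 <- extract_training_patch(img, ann$x[j], ann$y[j])
        if (is.null(p50)) { skipped <- skipped + 1L; next }
        counts[ann$class_name[j]] <- counts[ann$class_name[j]] + 1L
        lab <- class_code(ann$class_name[j])
        if (augment) {
          for (r in seq_len(augment_per_point)) {
            xs[[length(xs) + 1]] <- augment_patch(p50)
            ys <- c(ys, lab)
          }
        } else {
          xs[[length(xs) + 1]] <- center_crop(p50)
          ys <- c(ys, lab)
        }
      }
    }
    n <- length(xs)
    x <- array(0, c(32, 32, 3, n))
    for (i in seq_len(n)) x[, , , i] <- xs[[i]]
    list(x = x, y = ys, counts = counts, skipped = skipped)
  })
}
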