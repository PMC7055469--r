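#' Majority vote for one sub-patch
#'
#' Each 16x16 sub-patch receives up to four class votes, one from every
#' foreground tile whose footprint contains it. The plurality class wins; on
#' a tie among the top classes, each tied class's probability is averaged
#' over the contributing tiles and the larger mean wins; a residual exact tie
#' falls to the lowest class code. With no foreground votes the sub-patch is
#' background.
#'
#' @param class_votes integer vector of 0-based argmax labels (length <= 4)
#' @param prob_rows matching matrix of 4-class probability vectors
#' @return the winning 0-based class code, or 255 for background
#' @export
vote_subpatch <- function(class_votes, prob_rows) {
  if (length(class_votes) == 0) return(POD_BACKGROUND)
  prob_rows <- matrix(prob_rows, ncol = 4)
  counts <- tabulate(class_votes + 1L, nbins = 4)
  top <- which(counts == max(counts))
  if (length(top) == 1) return(top - 1L)
  avg <- round(colMeans(prob_rows), 9)  # robust residual-tie comparison
  score <- rep(-Inf, 4)
  score[top] <- avg[top]
  which.max(score) - 1L
}

#' Fuse a tile prediction grid into a sub-patch label image
#'
#' The padded canvas decomposes into 16x16 sub-patches; sub-patch (r, c)
#' collects the argmax votes of the (up to four) foreground tiles covering
#' it and [vote_subpatch()] decides its label. A sub-patch is background when
#' all covering tiles were background-flagged, or when pixel-level
#' thresholding found no plant pixel inside it (plant regions are identified
#' from the background before classes are assigned; grids built without
#' pixel information skip this second rule). The per-sub-patch count of
#' contributing foreground tiles is returned alongside.
#'
#' @param grid a `pod_grid` from [predict_image()]
#' @return a `pod_labels` list: `labels` (integer matrix, codes 0-3 and 255),
#'   `votes` (contributing-tile counts, 0-4), `subpatch_px`, `grid`
#' @export
reconstruct_labels <- function(grid) {
  gr <- grid$grid$grid_rows
  gc <- grid$grid$grid_cols
  nsr <- gr + 1L
  nsc <- gc + 1L
  fg <- grid$foreground
  # tile argmax labels (1..4); ties go to the lowest class code
  pm <- matrix(grid$probs, nrow = gr * gc)  # cell (i,j) at i + gr*(j-1)
  pm0 <- pm
  pm0[is.na(pm0)] <- 0
  amax <- matrix(max.col(pm0, ties.method = "first"), gr, gc)
  votes <- lapply(1:4, function(k) matrix(0, nsr, nsc))
  psum <- lapply(1:4, function(k) matrix(0, nsr, nsc))
  fgc <- matrix(0L, nsr, nsc)
  for (di in 0:1) for (dj in 0:1) {
    rr <- (1 + di):(gr + di)
    cc <- (1 + dj):(gc + dj)
    fgc[rr, cc] <- fgc[rr, cc] + fg
    for (k in 1:4) {
      votes[[k]][rr, cc] <- votes[[k]][rr, cc] + (fg & (amax == k))
      pk <- matrix(pm0[, k], gr, gc)
      psum[[k]][rr, cc] <- psum[[k]][rr, cc] + pk * fg
    }
  }
  ncell <- nsr * nsc
  V <- vapply(votes, as.numeric, numeric(ncell))
  maxv <- pmax(V[, 1], V[, 2], V[, 3], V[, 4])
  tied <- V == maxv
  avg <- round(vapply(psum, as.numeric, numeric(ncell)) /
                 pmax(as.numeric(fgc), 1), 9)
  score <- ifelse(tied, avg, -Inf)
  lab <- max.col(score, ties.method = "first") - 1L
  lab[as.numeric(fgc) == 0] <- POD_BACKGROUND
  labels <- matrix(lab, nsr, nsc)
  if (!is.null(grid$plant)) {
    # plant regions come from pixel thresholding; a sub-patch without plant
    # pixels stays background regardless of covering-tile votes
    labels[grid$plant[seq_len(nsr), seq_len(nsc)] == 0] <- POD_BACKGROUND
  }
  attr(labels, "subpatch_px") <- grid$grid$stride
  structure(list(labels = labels, votes = fgc,
                 subpatch_px = grid$grid$stride, grid = grid$grid),
            class = "pod_labels")
}

# accept a pod_labels object or a plain label matrix
as_label_matrix <- function(labels) {
  if (inherits(labels, "pod_labels")) labels$labels else labels
}

#' Full-resolution colour overlay of a label image
#'
#' Upsamples the sub-patch labels to pixel resolution with the conventional
#' colour scheme: tip red, body green, base blue, stem white, background
#' black.
#'
#' @param labels a `pod_labels` or label matrix
#' @param subpatch_px sub-patch edge in pixels
#' @return H x W x 3 array in `[0, 1]`, suitable for [png::writePNG()]
#' @export
label_overlay <- function(labels, subpatch_px = 16) {
  lab <- as_label_matrix(labels)
  pal <- rbind(base = c(0, 0, 1), body = c(0, 1, 0),
               stem = c(1, 1, 1), tip = c(1, 0, 0))
  H <- nrow(lab) * subpatch_px
  W <- ncol(lab) * subpatch_px
  big <- lab[rep(seq_len(nrow(lab)), each = subpatch_px),
             rep(seq_len(ncol(lab)), each = subpatch_px)]
  out <- array(0, c(H, W, 3))
  for (k in 0:3) {
    sel <- big == k
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[sel] <- pal[k + 1, ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' Write a label image as a paletted single-channel PNG
#'
#' @param labels a `pod_labels` or label matrix
#' @param path output path
#' @return invisibly, the path
#' @export
write_labels <- function(labels, path) {
  lab <- as_label_matrix(labels)
  png::writePNG(lab / 255, path)
  invisible(path)
}
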