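# Small-canvas scene spec for fast unit tests (acceptance tests use defaults).
small_spec <- function(seed, n_siliques = 6, n_overlap_pairs = 0, ...) {
  scene_spec(width = 700, height = 900, n_siliques = n_siliques,
             n_overlap_pairs = n_overlap_pairs, seed = seed, ...)
}

# Build a pod_grid by hand from a probability array (gr x gc x 4) and a
# foreground matrix, for reconstruction tests without a model.
manual_grid <- function(probs, foreground = NULL, stride = 16) {
  gr <- dim(probs)[1]; gc <- dim(probs)[2]
  if (is.null(foreground)) foreground <- matrix(TRUE, gr, gc)
  probs[!array(rep(foreground, 4), dim(probs))] <- NA_real_
  structure(list(
    probs = probs, foreground = foreground,
    grid = list(grid_rows = gr, grid_cols = gc, patch_size = 2 * stride,
                stride = stride, H = (gr + 1) * stride, W = (gc + 1) * stride,
                H_pad = (gr + 1) * stride, W_pad = (gc + 1) * stride,
                pad_value = c(255, 255, 255))), class = "pod_grid")
}

# Independent brute-force oracle for sub-patch voting: enumerates, for every
# sub-patch, the tiles whose 32x32 footprint contains it, straight from pixel
# geometry, then applies the published vote rules literally.
oracle_reconstruct <- function(grid) {
  gr <- grid$grid$grid_rows; gc <- grid$grid$grid_cols
  st <- grid$grid$stride
  nsr <- gr + 1; nsc <- gc + 1
  labels <- matrix(podquant::POD_BACKGROUND, nsr, nsc)
  votes <- matrix(0L, nsr, nsc)
  for (r in seq_len(nsr)) for (c in seq_len(nsc)) {
    # sub-patch pixel extent [ (r-1)*st, r*st ) x [ (c-1)*st, c*st )
    contributing <- list()
    for (i in seq_len(gr)) for (j in seq_len(gc)) {
      tile_rows <- c(st * (i - 1), st * (i - 1) + 2 * st)
      tile_cols <- c(st * (j - 1), st * (j - 1) + 2 * st)
      if (st * (r - 1) >= tile_rows[1] && st * r <= tile_rows[2] &&
          st * (c - 1) >= tile_cols[1] && st * c <= tile_cols[2] &&
          grid$foreground[i, j])
        contributing[[length(contributing) + 1]] <- grid$probs[i, j, ]
    }
    votes[r, c] <- length(contributing)
    if (length(contributing) == 0) next
    pm <- do.call(rbind, contributing)
    cls <- apply(pm, 1, which.max)
    counts <- tabulate(cls, nbins = 4)
    top <- which(counts == max(counts))
    if (length(top) == 1) {
      labels[r, c] <- top - 1L
    } else {
      avg <- round(colMeans(pm), 9)
      sc <- rep(-Inf, 4); sc[top] <- avg[top]
      labels[r, c] <- which.max(sc) - 1L
    }
  }
  list(labels = labels, votes = votes)
}

# A straight tip-body-base pod drawn into a sub-patch label matrix; tip and
# base span two cells each so they survive the default speckle filter.
draw_pod_labels <- function(lab, r0, c0, dr, dc, n_body = 4) {
  lab[r0, c0] <- 3L                                   # tip
  lab[r0 + dr, c0 + dc] <- 3L
  for (i in seq_len(n_body)) lab[r0 + (1 + i) * dr, c0 + (1 + i) * dc] <- 1L
  lab[r0 + (n_body + 2) * dr, c0 + (n_body + 2) * dc] <- 0L  # base
  lab[r0 + (n_body + 3) * dr, c0 + (n_body + 3) * dc] <- 0L
  lab
}
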