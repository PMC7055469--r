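#' Counting configuration
#'
#' @param angle_threshold angle in radians below which two base-to-tip
#'   vectors sharing an endpoint are treated as the same silique (0.05 rad)
#' @param min_region_area minimum connected-region size in sub-patches;
#'   smaller regions are discarded as speckle
#' @param subpatch_px sub-patch edge length, converts lattice units to pixels
#' @return a `counter_config` list
#' @export
counter_config <- function(angle_threshold = 0.05, min_region_area = 2,
                           subpatch_px = 16) {
  stopifnot(angle_threshold > 0, min_region_area >= 1, subpatch_px > 0)
  structure(list(angle_threshold = angle_threshold,
                 min_region_area = min_region_area,
                 subpatch_px = subpatch_px),
            class = "counter_config")
}

#' Connected same-class regions of a label image
#'
#' 8-connected components per class; components smaller than
#' `min_region_area` sub-patches are discarded. Centroids are reported in
#' sub-patch units (x = column, y = row, cell centres at integer - 0.5).
#'
#' @param labels a `pod_labels` or plain label matrix (codes 0-3, 255)
#' @param min_region_area minimum region area in sub-patches
#' @return list of regions: `class` (0-based code), `cells` (n x 2 matrix of
#'   row/col), `centroid` (x, y), `area`; plus an `id_map` attribute (matrix
#'   of region indices, 0 = none)
#' @export
extract_regions <- function(labels, min_region_area = 2) {
  lab <- as_label_matrix(labels)
  comp <- cpp_label_components(matrix(as.integer(lab), nrow(lab), ncol(lab)),
                               as.integer(POD_BACKGROUND), 8L)
  ids <- sort(unique(comp[comp > 0]))
  regions <- list()
  id_map <- matrix(0L, nrow(lab), ncol(lab))
  for (i in ids) {
    cells <- which(comp == i, arr.ind = TRUE)
    if (nrow(cells) < min_region_area) next
    k <- length(regions) + 1L
    regions[[k]] <- list(
      class = as.integer(lab[cells[1, 1], cells[1, 2]]),
      cells = cells,
      centroid = c(x = mean(cells[, 2]) - 0.5, y = mean(cells[, 1]) - 0.5),
      area = nrow(cells))
    id_map[cells] <- k
  }
  attr(regions, "id_map") <- id_map
  regions
}

#' Candidate silique component sets
#'
#' Starting from tip regions that share a border with a body region,
#' candidates grow through 4-adjacency between pod-class regions
#' (body-body, body-base, body-tip); stem regions terminate growth, so pods
#' joined only through the stem stay separate. Every maximal grown set
#' containing at least one tip, one body and one base is a candidate.
#'
#' @param regions regions from [extract_regions()]
#' @return list of candidates, each a list with `tips`, `bodies`, `bases`
#'   (indices into `regions`)
#' @export
build_candidates <- function(regions) {
  id_map <- attr(regions, "id_map")
  n <- length(regions)
  if (n == 0) return(list())
  cls <- vapply(regions, `[[`, integer(1), "class")
  pod_classes <- c(CLASS_CODES[["base"]], CLASS_CODES[["body"]], CLASS_CODES[["tip"]])
  # 4-adjacent region pairs
  H <- nrow(id_map); W <- ncol(id_map)
  a <- c(id_map[-H, ], id_map[, -W])
  b <- c(id_map[-1, ], id_map[, -1])
  keep <- a > 0 & b > 0 & a != b
  pairs <- unique(cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep])))
  # growth edges: body <-> {body, base, tip}
  grows <- function(c1, c2) {
    bodyc <- CLASS_CODES[["body"]]
    (c1 == bodyc && c2 %in% pod_classes) || (c2 == bodyc && c1 %in% pod_classes)
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(pairs) > 0) {
    for (e in seq_len(nrow(pairs))) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      if (grows(cls[i], cls[j])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  cands <- list()
  for (r in unique(roots)) {
    members <- which(roots == r)
    tips <- members[cls[members] == CLASS_CODES[["tip"]]]
    bodies <- members[cls[members] == CLASS_CODES[["body"]]]
    bases <- members[cls[members] == CLASS_CODES[["base"]]]
    if (length(tips) >= 1 && length(bodies) >= 1 && length(bases) >= 1)
      cands[[length(cands) + 1]] <- list(tips = tips, bodies = bodies,
                                         bases = bases)
  }
  cands
}

#' Unsigned angle between two vectors
#'
#' `atan2(|u x v|, u . v)`, the angle in `[0, pi]` used by the
#' overlapping-silique splitting rule.
#'
#' @param u,v numeric length-2 vectors (nonzero)
#' @return angle in radians
#' @export
pair_angle <- function(u, v) {
  if (all(u == 0) || all(v == 0)) stop("pair_angle is undefined for a zero vector")
  atan2(abs(u[1] * v[2] - u[2] * v[1]), sum(u * v))
}

#' Resolve a candidate into silique objects
#'
#' A candidate with one tip and one base is one silique. With multiple tips
#' or bases, each tip is paired to its nearest base (Euclidean centroid
#' distance, bases may be reused). Pairings sharing a base are compared by
#' the angle between their base-to-tip vectors: an angle above
#' `cfg$angle_threshold` keeps them as distinct siliques, at or below the
#' threshold they merge into one (the longer vector retained). Pairings are
#' processed greedily in decreasing vector length.
#'
#' @param candidate a candidate from [build_candidates()]
#' @param regions the region list the candidate indexes into
#' @param cfg a [counter_config()]
#' @return list of silique objects: `tip`, `base` (region indices), `bodies`,
#'   `vector` (base-to-tip, pixel units), `length` (pixels), `merged_from`
#' @export
resolve_candidate <- function(candidate, regions, cfg = counter_config()) {
  tips <- candidate$tips
  bases <- candidate$bases
  cent <- function(i) regions[[i]]$centroid
  pairings <- lapply(tips, function(t) {
    d <- vapply(bases, function(b) sqrt(sum((cent(t) - cent(b))^2)), numeric(1))
    b <- bases[which.min(d)]
    v <- (cent(t) - cent(b)) * cfg$subpatch_px
    list(tip = t, base = b, vector = v, length = sqrt(sum(v^2)))
  })
  pairings <- pairings[order(-vapply(pairings, `[[`, numeric(1), "length"))]
  out <- list()
  for (pr in pairings) {
    merged <- FALSE
    if (pr$length > 0) {
      for (k in seq_along(out)) {
        same_end <- out[[k]]$base == pr$base || out[[k]]$tip == pr$tip
        if (same_end && out[[k]]$length > 0 &&
            pair_angle(out[[k]]$vector, pr$vector) <= cfg$angle_threshold) {
          out[[k]]$merged_from <- out[[k]]$merged_from + 1L
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) {
      out[[length(out) + 1]] <- list(tip = pr$tip, base = pr$base,
                                     bodies = candidate$bodies,
                                     vector = pr$vector, length = pr$length,
                                     merged_from = 1L)
    }
  }
  out
}

#' Length of a silique object
#'
#' Euclidean distance between the base and tip centroids in full-resolution
#' pixels. Coincident centroids give length 0 and are flagged invalid.
#'
#' @param s a silique object from [resolve_candidate()]
#' @param cfg a [counter_config()]
#' @return length in pixels, with attribute `valid`
#' @export
measure_length <- function(s, cfg = counter_config()) {
  len <- sqrt(sum(s$vector^2))
  attr(len, "valid") <- len > 0
  len
}

#' Count siliques in a label image
#'
#' Extracts same-class regions, assembles tip-body-base candidates, resolves
#' overlaps with the angle rule and reports the count plus per-silique
#' records and per-image length statistics.
#'
#' @param labels a `pod_labels` or plain label matrix
#' @param cfg a [counter_config()]
#' @param image_id identifier used in the records
#' @return list with `count`, `siliques` (data frame: centroids, vector,
#'   length, merged_from), `summary` (one-row data frame: image_id, count,
#'   mean/max/min length in pixels)
#' @export
count_image <- function(labels, cfg = counter_config(), image_id = "image") {
  regions <- extract_regions(labels, cfg$min_region_area)
  cands <- build_candidates(regions)
  sil <- list()
  for (cd in cands) sil <- c(sil, resolve_candidate(cd, regions, cfg))
  n <- length(sil)
  if (n > 0) {
    df <- do.call(rbind, lapply(sil, function(s) {
      tc <- regions[[s$tip]]$centroid * cfg$subpatch_px
      bc <- regions[[s$base]]$centroid * cfg$subpatch_px
      data.frame(image_id = image_id,
                 tip_x = tc[["x"]], tip_y = tc[["y"]],
                 base_x = bc[["x"]], base_y = bc[["y"]],
                 vec_x = s$vector[["x"]], vec_y = s$vector[["y"]],
                 length_px = s$length, merged_from = s$merged_from)
    }))
  } else {
    df <- data.frame(image_id = character(0), tip_x = numeric(0),
                     tip_y = numeric(0), base_x = numeric(0),
                     base_y = numeric(0), vec_x = numeric(0),
                     vec_y = numeric(0), length_px = numeric(0),
                     merged_from = integer(0))
  }
  summary <- data.frame(
    image_id = image_id, predicted_count = n,
    mean_length_px = if (n > 0) mean(df$length_px) else NA_real_,
    max_length_px = if (n > 0) max(df$length_px) else NA_real_,
    min_length_px = if (n > 0) min(df$length_px) else NA_real_)
  list(count = n, siliques = df, summary = summary)
}

#' Binary overlay of detected silique regions
#'
#' Marks the sub-patches of every region participating in a counted silique
#' in white, mirroring the usual detection visualisation.
#'
#' @param labels a `pod_labels` or label matrix
#' @param cfg a [counter_config()]
#' @return a matrix in `[0, 1]` at sub-patch resolution
#' @export
detection_overlay <- function(labels, cfg = counter_config()) {
  lab <- as_label_matrix(labels)
  regions <- extract_regions(lab, cfg$min_region_area)
  cands <- build_candidates(regions)
  out <- matrix(0, nrow(lab), ncol(lab))
  for (cd in cands)
    for (i in c(cd$tips, cd$bodies, cd$bases))
      out[regions[[i]]$cells] <- 1
  out
}
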