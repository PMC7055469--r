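#' Specification of a synthetic inflorescence scene
#'
#' Parametric description of a white-background scene containing one stem and
#' `n_siliques` elongated pods, each with a distinguishable tip (tapered apex
#' with a short beak), base (pedicel junction) and body. `n_overlap_pairs` of
#' the pods are placed as overlapping pairs sharing a base location, with the
#' inter-pod angle drawn from `overlap_angle_range`.
#'
#' Defaults emulate a central crop of a 300 dpi flatbed scan: pod lengths of
#' 240-340 px (2.0-2.9 cm), pod widths 8-12 px (~1 mm), near-white background
#' (245) with mild sensor noise. Organ classes are separable by local shape,
#' not colour: tip and base share the body colour.
#'
#' @param width,height canvas size in pixels
#' @param n_siliques number of pods (members of an overlapping pair count
#'   individually); must be at least `2 * n_overlap_pairs`
#' @param length_range min/max drawn pod length in pixels
#' @param pod_width_range min/max pod width in pixels
#' @param n_overlap_pairs number of shared-base overlapping pod pairs
#' @param overlap_angle_range min/max inter-pod angle of a pair, radians,
#'   within (0, pi/2)
#' @param tip_fraction,base_fraction fraction of the pod length rendered as
#'   tip / base class; their sum must lie in (0, 1)
#' @param background_intensity background level, 0-255
#' @param noise_sd additive Gaussian noise sd on the rendered image
#' @param seed integer seed; all randomness in [generate_scene()] flows from it
#' @return a `scene_spec` list
#' @export
scene_spec <- function(width = 1020, height = 1440, n_siliques = 15,
                       length_range = c(240, 340), pod_width_range = c(8, 12),
                       n_overlap_pairs = 1, overlap_angle_range = c(0.1, 0.5),
                       tip_fraction = 0.14, base_fraction = 0.18,
                       background_intensity = 245, noise_sd = 3, seed = 1) {
  stopifnot(width >= 192, height >= 192,
            n_siliques >= 0, n_overlap_pairs >= 0,
            n_siliques >= 2 * n_overlap_pairs,
            length(length_range) == 2, diff(length_range) >= 0,
            length_range[1] > 0,
            length(pod_width_range) == 2, pod_width_range[1] >= 2,
            tip_fraction > 0, base_fraction > 0,
            tip_fraction + base_fraction < 1,
            overlap_angle_range[1] > 0, overlap_angle_range[2] < pi / 2,
            diff(overlap_angle_range) >= 0,
            background_intensity > 0, background_intensity <= 255,
            noise_sd >= 0)
  structure(as.list(environment()), class = "scene_spec")
}

CLASS_CODES <- c(base = 0L, body = 1L, stem = 2L, tip = 3L)

#' Map class names to codes and back
#'
#' Label order: base = 0, body = 1, stem = 2, tip = 3; 255 = background.
#' @param x class names (for `class_code`) or codes (for `class_name`)
#' @return integer codes / character names
#' @export
class_code <- function(x) {
  out <- CLASS_CODES[x]
  if (anyNA(out)) stop("unknown class name: ", paste(x[is.na(out)], collapse = ", "))
  unname(out)
}

#' @rdname class_code
#' @export
class_name <- function(x) {
  nm <- names(CLASS_CODES)[match(x, CLASS_CODES)]
  if (anyNA(nm)) stop("unknown class code: ", paste(x[is.na(nm)], collapse = ", "))
  nm
}

# rotate a unit vector by angle a (image coordinates, y down)
rot2 <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                         sin(a) * v[1] + cos(a) * v[2])

seg_seg_dist <- function(a1, a2, b1, b2) {
  # minimum distance between two segments, via sampled projection (robust and
  # plenty accurate for collision tests at pixel scale)
  ts <- seq(0, 1, length.out = 25)
  pax <- a1[1] + ts * (a2[1] - a1[1])
  pay <- a1[2] + ts * (a2[2] - a1[2])
  u <- b2 - b1
  L2 <- sum(u^2)
  t <- if (L2 == 0) rep(0, 25) else
    pmin(1, pmax(0, ((pax - b1[1]) * u[1] + (pay - b1[2]) * u[2]) / L2))
  sqrt(min((pax - (b1[1] + t * u[1]))^2 + (pay - (b1[2] + t * u[2]))^2))
}

# A render primitive: a capsule (line segment with width, optionally tapered
# towards the far end). `class_fun(t)` maps the axial position t in [0, 1] of
# a covered pixel to its mask class code.
capsule <- function(p1, p2, width, colour, class_fun,
                    taper_from = NULL, taper_to_frac = 0.3) {
  list(p1 = p1, p2 = p2, width = width, colour = colour,
       class_fun = class_fun, taper_from = taper_from,
       taper_to_frac = taper_to_frac)
}

# Rasterise the primitives in order onto an H x W canvas. The image gets
# anti-aliased alpha blending; the mask gets hard labels (no anti-aliasing).
render_primitives <- function(prims, H, W, bg, render_image) {
  mask <- matrix(POD_BACKGROUND, H, W)
  if (render_image) {
    img_r <- matrix(bg, H, W)
    img_g <- matrix(bg, H, W)
    img_b <- matrix(bg, H, W)
  }
  for (pr in prims) {
    p1 <- pr$p1; p2 <- pr$p2
    wmax <- max(pr$width)
    xlo <- max(1L, floor(min(p1[1], p2[1]) - wmax - 1))
    xhi <- min(W, ceiling(max(p1[1], p2[1]) + wmax + 1))
    ylo <- max(1L, floor(min(p1[2], p2[2]) - wmax - 1))
    yhi <- min(H, ceiling(max(p1[2], p2[2]) + wmax + 1))
    if (xlo > xhi || ylo > yhi) next
    cs <- xlo:xhi
    rs <- ylo:yhi
    nr <- length(rs); nc <- length(cs)
    px <- matrix(cs - 0.5, nr, nc, byrow = TRUE)
    py <- matrix(rs - 0.5, nr, nc)
    u <- p2 - p1
    L2 <- sum(u^2)
    t <- if (L2 == 0) matrix(0, nr, nc) else
      pmin(1, pmax(0, ((px - p1[1]) * u[1] + (py - p1[2]) * u[2]) / L2))
    d <- sqrt((px - (p1[1] + t * u[1]))^2 + (py - (p1[2] + t * u[2]))^2)
    halfw <- pr$width / 2
    if (!is.null(pr$taper_from)) {
      f <- pmin(1, pmax(0, (t - pr$taper_from) / (1 - pr$taper_from)))
      halfw <- halfw * (1 - (1 - pr$taper_to_frac) * f)
    }
    # linear indices of the bbox cells into the H x W canvas
    lin <- rep(rs, times = nc) + H * rep(cs - 1L, each = nr)
    if (render_image) {
      cov <- pmin(1, pmax(0, 0.5 + (halfw - d)))
      sel <- which(cov > 0)
      if (length(sel)) {
        idx <- lin[sel]; cv <- cov[sel]
        img_r[idx] <- img_r[idx] * (1 - cv) + pr$colour[1] * cv
        img_g[idx] <- img_g[idx] * (1 - cv) + pr$colour[2] * cv
        img_b[idx] <- img_b[idx] * (1 - cv) + pr$colour[3] * cv
      }
    }
    ins <- which(d <= halfw)
    if (length(ins)) mask[lin[ins]] <- pr$class_fun(t[ins])
  }
  out <- list(mask = mask)
  if (render_image) out[c("img_r", "img_g", "img_b")] <-
    list(img_r, img_g, img_b)
  out
}

#' Generate a synthetic inflorescence scene with full ground truth
#'
#' Renders the stem as a gently curved thick polyline, pods as tapered
#' capsules attached to the stem through short pedicels, and (optionally)
#' overlapping pod pairs sharing a base. Returns the anti-aliased RGB image,
#' a hard per-pixel class mask (0 base, 1 body, 2 stem, 3 tip, 255
#' background), one tip and one base point annotation per pod, the true pod
#' count and the drawn pod lengths. Bit-identical output for a fixed
#' `spec$seed`.
#'
#' When the canvas cannot host all requested pods (after retry sampling) the
#' scene is returned with the pods that fit and `placement_failures > 0`.
#'
#' @param spec a [scene_spec()]
#' @param render_image set `FALSE` to skip image rendering (mask and truth
#'   only), e.g. for label-map-level experiments
#' @return a `scene_truth` list with fields `image`, `mask`, `annotations`,
#'   `true_count`, `silique_lengths`, `placement_failures`, `pods`, `spec`
#' @export
generate_scene <- function(spec, render_image = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(as.integer(spec$seed), generate_scene_impl(spec, render_image))
}

generate_scene_impl <- function(spec, render_image) {
  H <- spec$height; W <- spec$width
  margin <- 40
  stem_w <- 14
  ped_w <- 5
  # clearance rules keep distinct pods separable at the 16 px sub-patch
  # lattice: no two pods may share a block (axis clearance > 16*sqrt(2)) and
  # tip sections of different pods must not produce adjacent tip blocks
  min_sep <- 24
  tip_sep <- 60

  stem_col <- c(62, 108, 52)
  pod_col0 <- c(118, 162, 74)

  # stem: a slow sine-curved near-vertical polyline
  cx <- W / 2 + runif(1, -30, 30)
  amp <- runif(1, 10, 40)
  phase <- runif(1, 0, 2 * pi)
  ys <- seq(margin, H - margin, by = 10)
  xs <- cx + amp * sin(2 * pi * (ys - margin) / (1.6 * H) + phase)
  stem_pts <- cbind(xs, ys)
  stem_fun <- function(y) cx + amp * sin(2 * pi * (y - margin) / (1.6 * H) + phase)

  n_pairs <- spec$n_overlap_pairs
  n_single <- spec$n_siliques - 2 * n_pairs
  n_att <- n_single + n_pairs
  pods <- list()
  pair_angles <- numeric(0)
  failures <- 0L

  if (n_att > 0) {
    # attachments must sit low enough that an upward-pointing pod (steepest
    # allowed inclination) stays inside the canvas
    reach <- 0.35 * (80 + spec$length_range[2] + 9) + 10
    ay_lo <- min(margin + 40 + reach, H / 2)
    ay <- seq(ay_lo, H - margin - 50, length.out = max(n_att, 2))[seq_len(n_att)]
    ay <- ay + runif(n_att, -4, 4)
    sides <- rep_len(c(-1, 1), n_att)
    if (runif(1) < 0.5) sides <- -sides
    pair_at <- if (n_pairs > 0) sample.int(n_att, n_pairs) else integer(0)

    edge <- 34
    in_canvas <- function(p) p[1] > edge && p[1] < W - edge && p[2] > edge && p[2] < H - edge
    clear_of <- function(P0, P1, P2, dir, skip = integer(0)) {
      tn <- list(a = P1 + 0.72 * (P2 - P1), b = P2 + 9 * dir)
      for (i in seq_along(pods)) {
        if (i %in% skip) next
        q <- pods[[i]]
        if (seg_seg_dist(P0, P2, q$P1, q$P2) < min_sep) return(FALSE)
        if (seg_seg_dist(P0, P2, q$P0, q$P1) < min_sep) return(FALSE)
        tq <- list(a = q$P1 + 0.72 * (q$P2 - q$P1), b = q$P2 + 9 * q$dir)
        if (seg_seg_dist(tn$a, tn$b, tq$a, tq$b) < tip_sep) return(FALSE)
      }
      TRUE
    }

    for (a in seq_len(n_att)) {
      s <- sides[a]
      P0 <- c(stem_fun(ay[a]) + s * stem_w / 2, ay[a])
      placed_main <- NULL
      for (try in 1:80) {
        theta <- min(70, max(22, rnorm(1, 45, 10))) * pi / 180
        dir <- c(s * sin(theta), -cos(theta))
        ped_len <- runif(1, 50, 80)
        L <- if (try <= 40) runif(1, spec$length_range[1], spec$length_range[2])
             else spec$length_range[1]
        P1 <- P0 + ped_len * dir
        P2 <- P1 + L * dir
        beak <- P2 + 9 * dir
        if (!in_canvas(P2) || !in_canvas(beak) || !in_canvas(P1)) next
        if (!clear_of(P0, P1, P2, dir)) next
        placed_main <- list(P0 = P0, P1 = P1, P2 = P2, dir = dir, L = L,
                            w = runif(1, spec$pod_width_range[1], spec$pod_width_range[2]),
                            pair = NA_integer_)
        break
      }
      if (is.null(placed_main)) { failures <- failures + 1L; next }
      pods[[length(pods) + 1]] <- placed_main
      if (a %in% pair_at) {
        delta <- runif(1, spec$overlap_angle_range[1], spec$overlap_angle_range[2])
        idx_a <- length(pods)
        placed_b <- NULL
        for (try in 1:60) {
          sgn <- if (try %% 2 == 1) 1 else -1
          dirb <- rot2(placed_main$dir, sgn * delta)
          # pair members differ in length (different maturity), which also
          # keeps their tip sections in distinct radial bands on the lattice
          stag <- runif(1, 55, 85) * sample(c(-1, 1), 1)
          Lb <- max(spec$length_range[1] - 45,
                    min(spec$length_range[2] + 45, placed_main$L + stag))
          P2b <- placed_main$P1 + Lb * dirb
          beakb <- P2b + 9 * dirb
          if (!in_canvas(P2b) || !in_canvas(beakb)) next
          if (!clear_of(P0, placed_main$P1, P2b, dirb, skip = idx_a)) next
          placed_b <- list(P0 = P0, P1 = placed_main$P1, P2 = P2b, dir = dirb,
                           L = Lb,
                           w = runif(1, spec$pod_width_range[1], spec$pod_width_range[2]),
                           pair = idx_a)
          break
        }
        if (is.null(placed_b)) {
          failures <- failures + 1L
        } else {
          pods[[idx_a]]$pair <- length(pods) + 1L
          pods[[length(pods) + 1]] <- placed_b
          pair_angles <- c(pair_angles, delta)
        }
      }
    }
  }

  # primitives in paint order: stem, pedicels, then pods (pods overwrite
  # stem labels where they cross)
  tipf <- spec$tip_fraction; basef <- spec$base_fraction
  stem_class <- function(t) CLASS_CODES[["stem"]]
  tip_class <- function(t) CLASS_CODES[["tip"]]
  pod_class_fun <- function(t) {
    out <- rep(CLASS_CODES[["body"]], length(t))
    out[t < basef] <- CLASS_CODES[["base"]]
    out[t > 1 - tipf] <- CLASS_CODES[["tip"]]
    out
  }
  prims <- list()
  for (i in seq_len(nrow(stem_pts) - 1))
    prims[[length(prims) + 1]] <- capsule(stem_pts[i, ], stem_pts[i + 1, ],
                                          stem_w, stem_col, stem_class)
  for (p in pods)
    prims[[length(prims) + 1]] <- capsule(p$P0, p$P1, ped_w,
                                          stem_col * 0.9 + c(20, 10, 0),
                                          stem_class)
  # paint pods in ascending length order: where a near-parallel pair
  # physically overlaps, the longer member occludes the shorter one's tip,
  # as it would on a scanner bed
  pods_paint <- pods[order(vapply(pods, `[[`, numeric(1), "L"))]
  for (p in pods_paint) {
    col <- pmin(255, pmax(0, pod_col0 + runif(3, -8, 8)))
    prims[[length(prims) + 1]] <- capsule(p$P1, p$P2, p$w, col, pod_class_fun,
                                          taper_from = 1 - tipf,
                                          taper_to_frac = 0.35)
    prims[[length(prims) + 1]] <- capsule(p$P2, p$P2 + 7 * p$dir, 2.4, col,
                                          tip_class)
  }
  canvas <- render_primitives(prims, H, W, spec$background_intensity,
                              render_image)

  image <- if (render_image) {
    arr <- array(0, c(H, W, 3))
    arr[, , 1] <- canvas$img_r
    arr[, , 2] <- canvas$img_g
    arr[, , 3] <- canvas$img_b
    if (spec$noise_sd > 0) {
      arr <- arr + rnorm(length(arr), sd = spec$noise_sd)
      arr[arr < 0] <- 0
      arr[arr > 255] <- 255
    }
    arr
  } else NULL

  image_id <- sprintf("scene_seed%d", spec$seed)
  ann <- pod_end_annotations(canvas$mask, pods, tipf, basef, image_id)

  structure(list(image = image, mask = canvas$mask, annotations = ann,
                 stem_pts = stem_pts,
                 true_count = length(pods),
                 silique_lengths = vapply(pods, `[[`, numeric(1), "L"),
                 placement_failures = failures,
                 pair_angles = pair_angles,
                 pods = pods, image_id = image_id, spec = spec),
            class = "scene_truth")
}

# one tip and one base point per pod, snapped onto a pixel of the right class
pod_end_annotations <- function(mask, pods, tipf, basef, image_id) {
  rows <- lapply(pods, function(p) {
    tip_pt <- p$P1 + (1 - tipf / 2) * p$L * p$dir
    # base clicks land on the proximal section near the silique-pedicel
    # junction, scattered as a human annotator's clicks are
    nrm <- c(-p$dir[2], p$dir[1])
    base_pt <- p$P1 + runif(1, 2, 8) * p$dir +
      runif(1, -p$w / 3, p$w / 3) * nrm
    tp <- snap_to_class(mask, tip_pt, CLASS_CODES[["tip"]])
    bp <- snap_to_class(mask, base_pt, CLASS_CODES[["base"]])
    rbind(
      if (!is.null(tp)) data.frame(image_id = image_id, x = tp[1], y = tp[2],
                                   class_name = "tip"),
      if (!is.null(bp)) data.frame(image_id = image_id, x = bp[1], y = bp[2],
                                   class_name = "base")
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(image_id = character(0), x = numeric(0), y = numeric(0),
                      class_name = character(0))
  out
}

# nearest pixel (0-based x, y) of the requested class within `radius` of pt
snap_to_class <- function(mask, pt, code, radius = 16) {
  x0 <- floor(pt[1]); y0 <- floor(pt[2])
  H <- nrow(mask); W <- ncol(mask)
  cs <- max(1, x0 + 1 - radius):min(W, x0 + 1 + radius)
  rs <- max(1, y0 + 1 - radius):min(H, y0 + 1 + radius)
  sub <- mask[rs, cs, drop = FALSE]
  hit <- which(sub == code, arr.ind = TRUE)
  if (nrow(hit) == 0) return(NULL)
  px <- cs[hit[, 2]] - 1L
  py <- rs[hit[, 1]] - 1L
  d2 <- (px - pt[1] + 0.5)^2 + (py - pt[2] + 0.5)^2
  i <- which.min(d2)
  c(px[i], py[i])
}

#' Point annotations for a scene
#'
#' Mirrors sparse manual annotation: every pod gets one tip and one base
#' point (at the pod-end centroids, snapped onto the mask); pod bodies get
#' `points_per_body` points each, sampled along the body section; the stem
#' gets `points_per_stem` points per scene, sampled from stem-class pixels.
#' Classes absent from the scene yield no annotations, with a warning.
#'
#' @param truth a `scene_truth` from [generate_scene()]
#' @param points_per_body body points sampled per pod
#' @param points_per_stem stem points sampled per scene
#' @param seed seed for the sampling (default derived from the scene seed)
#' @return a data frame of point annotations (image_id, x, y, class_name)
#' @export
scene_to_annotations <- function(truth, points_per_body = 1,
                                 points_per_stem = 10, seed = NULL) {
  stopifnot(inherits(truth, "scene_truth"))
  if (is.null(seed)) seed <- truth$spec$seed + 1000L
  withr::with_seed(as.integer(seed), {
    out <- truth$annotations
    basef <- truth$spec$base_fraction
    tipf <- truth$spec$tip_fraction
    if (points_per_body > 0) {
      # clicks land anywhere on the organ, not on its midline: draw an axial
      # position and a lateral offset across the pod width, then snap to a
      # body pixel
      for (p in truth$pods) {
        ts <- runif(points_per_body, basef + 0.06, 1 - tipf - 0.06)
        for (t in ts) {
          lateral <- runif(1, -p$w / 2, p$w / 2)
          nrm <- c(-p$dir[2], p$dir[1])
          pt <- p$P1 + t * p$L * p$dir + lateral * nrm
          bp <- snap_to_class(truth$mask, pt, CLASS_CODES[["body"]])
          if (!is.null(bp))
            out <- rbind(out, data.frame(image_id = truth$image_id,
                                         x = bp[1], y = bp[2],
                                         class_name = "body"))
        }
      }
      if (length(truth$pods) > 0 && !any(out$class_name == "body"))
        warning("no body pixels available to annotate")
    }
    if (points_per_stem > 0) {
      sp <- truth$stem_pts
      if (is.null(sp) || !any(truth$mask == CLASS_CODES[["stem"]])) {
        warning("stem class absent from scene; no stem annotations")
      } else {
        take <- sp[sample.int(nrow(sp), min(points_per_stem, nrow(sp))), ,
                   drop = FALSE]
        for (i in seq_len(nrow(take))) {
          pt <- take[i, ] + runif(2, -7, 7)
          st <- snap_to_class(truth$mask, pt, CLASS_CODES[["stem"]], radius = 10)
          if (!is.null(st))
            out <- rbind(out, data.frame(image_id = truth$image_id,
                                         x = st[1], y = st[2],
                                         class_name = "stem"))
        }
      }
    }
    rownames(out) <- NULL
    out
  })
}

#' Down-sample a per-pixel mask to the sub-patch label lattice
#'
#' Each 16x16 block (the sub-patch size of the reconstruction stage) becomes
#' one cell: background (255) when the block holds no plant pixel, otherwise
#' the majority plant class within the block (ties resolved to the lowest
#' class code). The mask is padded with background on the bottom/right to the
#' lattice size used by [tile_image()].
#'
#' @param mask H x W integer mask with codes 0-3 and 255
#' @param subpatch_px sub-patch edge length in pixels
#' @return an integer label matrix with attribute `subpatch_px`
#' @export
mask_to_labels <- function(mask, subpatch_px = 16) {
  H <- nrow(mask); W <- ncol(mask)
  Hp <- max(2, ceiling(H / subpatch_px)) * subpatch_px
  Wp <- max(2, ceiling(W / subpatch_px)) * subpatch_px
  m <- matrix(POD_BACKGROUND, Hp, Wp)
  m[1:H, 1:W] <- mask
  nbr <- Hp / subpatch_px
  nbc <- Wp / subpatch_px
  counts <- array(0, c(nbr, nbc, 4))
  for (k in 0:3) {
    a <- array(m == k, c(subpatch_px, nbr, subpatch_px, nbc))
    b <- colSums(a)                       # (nbr, subpatch_px, nbc)
    counts[, , k + 1] <- colSums(aperm(b, c(2, 1, 3)))
  }
  total <- counts[, , 1] + counts[, , 2] + counts[, , 3] + counts[, , 4]
  lab <- max.col(matrix(counts, ncol = 4), ties.method = "first") - 1L
  lab <- matrix(lab, nbr, nbc)
  lab[total == 0] <- POD_BACKGROUND
  attr(lab, "subpatch_px") <- subpatch_px
  lab
}

#' Write scene artefacts to disk
#'
#' Image as RGB PNG, mask as single-channel PNG carrying the class codes,
#' annotations as CSV and a truth summary as JSON.
#'
#' @param truth a `scene_truth`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_scene <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- truth$image_id
  paths <- c(image = file.path(dir, paste0(id, ".png")),
             mask = file.path(dir, paste0(id, "_mask.png")),
             annotations = file.path(dir, paste0(id, "_annotations.csv")),
             truth = file.path(dir, paste0(id, "_truth.json")))
  if (!is.null(truth$image))
    png::writePNG(truth$image / 255, paths[["image"]])
  png::writePNG(truth$mask / 255, paths[["mask"]])
  write_annotations(truth$annotations, paths[["annotations"]])
  jsonlite::write_json(
    list(image_id = id, true_count = truth$true_count,
         silique_lengths = truth$silique_lengths,
         placement_failures = truth$placement_failures,
         pair_angles = truth$pair_angles,
         spec = truth$spec[setdiff(names(truth$spec), c())]),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read back a mask PNG written by [write_scene()]
#' @param path PNG path
#' @return integer mask matrix
#' @export
read_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}
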