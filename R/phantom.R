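# Synthetic phantom generator: branching vessel trees rendered as binary
# masks with ground-truth sidecars. The generator emulates the statistical
# structure the pipeline assumes -- vessel widths of a few to ~15 px,
# bounded rigid inter-frame translation, focal narrowings (static stenosis)
# and periodic narrowings over several frames (myocardial bridge /
# milking effect). Rendering stamps a disc of diameter equal to the local
# width at every 1-px-spaced centerline sample, so the width is known
# analytically at every sample.

#' Construct and validate a phantom specification
#'
#' @param image_height,image_width Image size in pixels.
#' @param segments List of segment specs; each a list with `points` (k x 2
#'   matrix of (x, y) polyline control points), `base_width` (px, >= 3) and
#'   `parent` (segment index or NA). Child polylines must start within 10
#'   Manhattan px of the parent's last control point.
#' @param motion_per_frame Rigid translation (dx, dy) applied per frame.
#' @param n_frames Number of frames (>= 1).
#' @param stenoses List of lesion specs; each a list with `segment` (index),
#'   `position` (arc-length fraction in (0,1)), `severity` (fraction in
#'   (0,1)), `extent` (px), `periodic` (logical) and `period_frames`.
#' @param seed Integer recorded in the spec (the generator itself is
#'   deterministic; the seed seeds the random layout helpers).
#' @return A validated phantom spec (class `phantom_spec`).
#' @export
phantom_spec <- function(image_height, image_width, segments,
                         motion_per_frame = c(0, 0), n_frames = 1L,
                         stenoses = list(), seed = 1L) {
  fail <- function(field, msg) stop(sprintf("invalid phantom spec: %s %s", field, msg))
  if (image_height < 16 || image_width < 16) fail("image size", "must be >= 16 px")
  if (n_frames < 1) fail("n_frames", "must be >= 1")
  if (length(segments) == 0L) fail("segments", "must be non-empty")
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    if (is.null(s$points) || nrow(s$points) < 2L)
      fail(sprintf("segments[[%d]]$points", i), "needs >= 2 control points")
    if (is.null(s$base_width) || s$base_width < 3)
      fail(sprintf("segments[[%d]]$base_width", i), "must be >= 3 px")
    if (!is.null(s$parent) && !is.na(s$parent)) {
      p <- s$parent
      if (p < 1L || p > length(segments) || p == i)
        fail(sprintf("segments[[%d]]$parent", i), "is not a valid segment index")
      pend <- segments[[p]]$points[nrow(segments[[p]]$points), ]
      if (sum(abs(s$points[1L, ] - pend)) > 10)
        fail(sprintf("segments[[%d]]$points", i),
             "must start within 10 Manhattan px of the parent endpoint")
    } else {
      segments[[i]]$parent <- NA_integer_
    }
  }
  for (j in seq_along(stenoses)) {
    st <- stenoses[[j]]
    if (is.null(st$segment) || st$segment < 1L || st$segment > length(segments))
      fail(sprintf("stenoses[[%d]]$segment", j), "is not a valid segment index")
    if (is.null(st$severity) || st$severity <= 0 || st$severity >= 1)
      fail(sprintf("stenoses[[%d]]$severity", j), "must be strictly between 0 and 1")
    if (is.null(st$position) || st$position <= 0 || st$position >= 1)
      fail(sprintf("stenoses[[%d]]$position", j), "must be strictly between 0 and 1")
    if (is.null(st$extent) || st$extent <= 0)
      fail(sprintf("stenoses[[%d]]$extent", j), "must be positive")
    if (is.null(st$periodic)) stenoses[[j]]$periodic <- FALSE
    if (isTRUE(st$periodic) && (is.null(st$period_frames) || st$period_frames < 2))
      fail(sprintf("stenoses[[%d]]$period_frames", j), "must be >= 2 for a periodic lesion")
  }
  if (sum(abs(motion_per_frame)) >= 65)
    warning("per-frame motion magnitude >= 65 px; inter-frame matching will fail by design")
  structure(list(
    image_height = as.integer(image_height), image_width = as.integer(image_width),
    segments = segments, motion_per_frame = as.numeric(motion_per_frame),
    n_frames = as.integer(n_frames), stenoses = stenoses, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Resample a polyline at ~1 px arc-length spacing; returns samples (x, y)
# and their cumulative arc length.
densify_polyline <- function(points, spacing = 1) {
  pts <- matrix(as.numeric(points), ncol = 2L)
  seg_len <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  total <- sum(seg_len)
  s <- seq(0, total, by = spacing)
  if (s[length(s)] < total) s <- c(s, total)
  cum <- c(0, cumsum(seg_len))
  xy <- matrix(NA_real_, length(s), 2L)
  for (i in seq_along(s)) {
    j <- findInterval(s[i], cum, rightmost.closed = TRUE)
    j <- min(j, nrow(pts) - 1L)
    t <- if (seg_len[j] > 0) (s[i] - cum[j]) / seg_len[j] else 0
    xy[i, ] <- pts[j, ] + t * (pts[j + 1L, ] - pts[j, ])
  }
  list(xy = xy, arclen = s, total = total)
}

# Time modulation of a lesion's severity at frame t (0-based): static
# lesions hold their severity; periodic lesions follow a raised cosine in
# time with maximum severity at t = 0 and zero at half period.
lesion_severity_at <- function(st, frame) {
  if (isTRUE(st$periodic)) {
    st$severity * (1 + cos(2 * pi * frame / st$period_frames)) / 2
  } else {
    st$severity
  }
}

# Per-sample width of a segment at a frame: base width with raised-cosine
# dips for each lesion on the segment.
segment_widths_at <- function(spec, seg_idx, dens, frame) {
  w <- rep(spec$segments[[seg_idx]]$base_width, nrow(dens$xy))
  for (st in spec$stenoses) {
    if (st$segment != seg_idx) next
    sev <- lesion_severity_at(st, frame)
    if (sev <= 0) next
    center <- st$position * dens$total
    d <- abs(dens$arclen - center)
    inside <- d <= st$extent / 2
    dip <- numeric(length(w))
    dip[inside] <- sev * 0.5 * (1 + cos(2 * pi * d[inside] / st$extent))
    w <- w * (1 - dip)
  }
  w
}

#' Render one phantom frame as a binary mask
#'
#' @param spec A [phantom_spec()].
#' @param frame 0-based frame index, less than `n_frames`.
#' @return An integer 0/1 mask of the spec's image size.
#' @export
render_vessel_mask <- function(spec, frame = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (frame < 0L || frame >= spec$n_frames) stop("frame outside n_frames")
  H <- spec$image_height; W <- spec$image_width
  m <- matrix(0L, H, W)
  off <- frame * spec$motion_per_frame
  for (i in seq_along(spec$segments)) {
    dens <- densify_polyline(spec$segments[[i]]$points)
    wid <- segment_widths_at(spec, i, dens, frame)
    xs <- dens$xy[, 1L] + off[1L]
    ys <- dens$xy[, 2L] + off[2L]
    for (k in seq_len(nrow(dens$xy))) {
      rad <- wid[k] / 2
      r0 <- max(1L, floor(ys[k] - rad) + 1L)
      r1 <- min(H, ceiling(ys[k] + rad) + 1L)
      c0 <- max(1L, floor(xs[k] - rad) + 1L)
      c1 <- min(W, ceiling(xs[k] + rad) + 1L)
      if (r0 > r1 || c0 > c1) next
      rr <- r0:r1; cc <- c0:c1
      dy2 <- ((rr - 1L) - ys[k])^2
      dx2 <- ((cc - 1L) - xs[k])^2
      hit <- outer(dy2, dx2, `+`) <= rad^2
      m[rr, cc][hit] <- 1L
    }
  }
  m
}

#' Generate a phantom mask sequence with ground truth
#'
#' Frame t is frame 0 translated by t times the per-frame motion, with
#' lesion widths modulated in time. The truth sidecar holds, per frame, the
#' sampled centerlines, per-sample widths, parent edges, cross-frame
#' correspondence ids, bifurcation and endpoint coordinates, and per-lesion
#' stenosis degree; each lesion carries its bridge flag (periodic).
#'
#' @param spec A [phantom_spec()].
#' @return A list with `masks` (list of 0/1 matrices) and `truth`.
#' @export
make_sequence <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$image_height; W <- spec$image_width
  masks <- lapply(seq_len(spec$n_frames) - 1L, function(t) render_vessel_mask(spec, t))
  frames <- vector("list", spec$n_frames)
  n_children <- integer(length(spec$segments))
  for (s in spec$segments) if (!is.na(s$parent)) n_children[s$parent] <- n_children[s$parent] + 1L
  for (t in seq_len(spec$n_frames) - 1L) {
    off <- t * spec$motion_per_frame
    segs <- vector("list", length(spec$segments))
    for (i in seq_along(spec$segments)) {
      dens <- densify_polyline(spec$segments[[i]]$points)
      cl <- sweep(dens$xy, 2L, -off)
      clipped <- cl[, 1L] < 0 | cl[, 1L] > W - 1 | cl[, 2L] < 0 | cl[, 2L] > H - 1
      segs[[i]] <- list(
        centerline = cl,
        widths = segment_widths_at(spec, i, dens, t),
        parent = spec$segments[[i]]$parent,
        correspondence_id = i,
        clipped_start = clipped[1L],
        clipped_end = clipped[length(clipped)]
      )
    }
    bif <- matrix(NA_real_, 0L, 2L)
    for (i in which(n_children >= 2L)) {
      pts <- spec$segments[[i]]$points
      bif <- rbind(bif, pts[nrow(pts), ] + off)
    }
    lesions <- lapply(spec$stenoses, function(st) {
      list(segment = st$segment, degree = lesion_severity_at(st, t),
           bridge = isTRUE(st$periodic))
    })
    frames[[t + 1L]] <- list(segments = segs, bifurcations = bif, lesions = lesions)
  }
  truth <- list(
    n_frames = spec$n_frames,
    image_height = H, image_width = W,
    motion_per_frame = spec$motion_per_frame,
    seed = spec$seed,
    frames = frames,
    lesion_bridge = vapply(spec$stenoses, function(st) isTRUE(st$periodic), logical(1L))
  )
  list(masks = masks, truth = truth)
}

#' Write a phantom sequence to disk
#'
#' Masks are written as 8-bit 0/255 PNG files named `frame_%04d.png`; the
#' truth sidecar is one JSON file `truth.json`.
#'
#' @param dir_path Writable directory (created when absent).
#' @param masks List of 0/1 masks.
#' @param truth Truth sidecar from [make_sequence()].
#' @return Invisibly, the written file paths.
#' @export
write_phantom <- function(dir_path, masks, truth) {
  if (length(masks) == 0L) stop("no frames to write")
  if (!dir.exists(dir_path)) dir.create(dir_path, recursive = TRUE)
  paths <- character(0L)
  for (i in seq_along(masks)) {
    p <- file.path(dir_path, sprintf("frame_%04d.png", i - 1L))
    png::writePNG(matrix(as.double(masks[[i]]), nrow(masks[[i]])), p)
    paths <- c(paths, p)
  }
  tp <- file.path(dir_path, "truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tp))
}

#' Read a phantom specification from YAML
#'
#' The file mirrors the [phantom_spec()] arguments: `image_height`,
#' `image_width`, `n_frames`, `motion_per_frame` (list of two numbers),
#' `seed`, `segments` (each with `points` as a list of \[x, y\] pairs,
#' `base_width`, optional `parent`) and `stenoses`.
#'
#' @param path YAML file path.
#' @return A validated [phantom_spec()].
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  segs <- lapply(y$segments, function(s) {
    list(points = do.call(rbind, lapply(s$points, as.numeric)),
         base_width = s$base_width,
         parent = if (is.null(s$parent)) NA_integer_ else as.integer(s$parent))
  })
  sten <- lapply(y$stenoses, function(st) {
    list(segment = as.integer(st$segment), position = st$position,
         severity = st$severity, extent = st$extent,
         periodic = isTRUE(st$periodic),
         period_frames = if (is.null(st$period_frames)) 1L else as.integer(st$period_frames))
  })
  phantom_spec(
    image_height = y$image_height, image_width = y$image_width,
    segments = segs,
    motion_per_frame = if (is.null(y$motion_per_frame)) c(0, 0) else as.numeric(y$motion_per_frame),
    n_frames = if (is.null(y$n_frames)) 1L else as.integer(y$n_frames),
    stenoses = sten,
    seed = if (is.null(y$seed)) 1L else as.integer(y$seed)
  )
}

# ---- seeded layout helpers ---------------------------------------------

# Run expr with a private RNG stream derived from `seed`, restoring the
# caller's RNG state afterwards.
with_phantom_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Straight-vessel phantom spec
#'
#' One straight vessel of a given width and orientation through the image
#' centre; handy for diameter-recovery studies.
#'
#' @param width Vessel width in px.
#' @param angle_deg Orientation in degrees (0 = horizontal).
#' @param length Vessel length in px.
#' @param size Image side in px.
#' @param ... Passed to [phantom_spec()] (e.g. stenoses, motion, n_frames).
#' @return A [phantom_spec()].
#' @export
straight_vessel_spec <- function(width = 5, angle_deg = 0, length = 80,
                                 size = 128L, ...) {
  th <- angle_deg * pi / 180
  # integer centre so axis-aligned vessels of odd width rasterize symmetric
  ctr <- rep(floor((size - 1) / 2), 2L)
  d <- c(cos(th), sin(th))
  p0 <- ctr - d * length / 2
  p1 <- ctr + d * length / 2
  phantom_spec(size, size,
               segments = list(list(points = rbind(p0, p1), base_width = width,
                                    parent = NA)),
               ...)
}

#' Random branching-tree phantom spec
#'
#' Generates a seeded random ternary tree layout: a root vessel entering
#' near the upper-left corner and growing down-right, with internal nodes
#' branching into two or three children at divergent angles. Arm lengths
#' are at least ~25 px and widths at least 3 px, shrinking with depth.
#'
#' @param seed Integer seed for the layout.
#' @param n_internal Number of branching (internal) nodes (>= 0).
#' @param size Image side in px.
#' @param ... Passed to [phantom_spec()].
#' @return A [phantom_spec()].
#' @export
random_tree_spec <- function(seed = 1L, n_internal = 2L, size = 224L, ...) {
  with_phantom_rng(seed, {
    sample_line <- function(p0, p1) {
      t <- seq(0, 1, length.out = 24L)
      cbind(p0[1L] + t * (p1[1L] - p0[1L]), p0[2L] + t * (p1[2L] - p0[2L]))
    }
    segs <- list()
    seg_samples <- list()
    # minimum clearance between the new arm and every non-adjacent existing
    # segment: half-widths plus a guard band, so junctions stay unambiguous
    clear_of <- function(p0, p1, w, parent_idx) {
      pts <- sample_line(p0, p1)
      for (i in seq_along(segs)) {
        other <- seg_samples[[i]]
        need <- (w + segs[[i]]$base_width) / 2 + 5
        d <- vapply(seq_len(nrow(pts)), function(k) {
          min(sqrt((other[, 1L] - pts[k, 1L])^2 + (other[, 2L] - pts[k, 2L])^2))
        }, numeric(1L))
        # ignore the shared attachment neighbourhood
        near_attach <- sqrt((pts[, 1L] - p0[1L])^2 + (pts[, 2L] - p0[2L])^2) <
          need + 6
        if (any(d < need & !near_attach)) return(FALSE)
      }
      TRUE
    }
    root_ang <- runif(1, 35, 55) * pi / 180
    root_len <- runif(1, 35, 50)
    p0 <- c(runif(1, 10, 16), runif(1, 10, 16))
    p1 <- p0 + root_len * c(cos(root_ang), sin(root_ang))
    segs[[1L]] <- list(points = rbind(p0, p1), base_width = round(runif(1, 8, 9)),
                       parent = NA)
    seg_samples[[1L]] <- sample_line(p0, p1)
    open <- list(list(at = p1, ang = root_ang, width = segs[[1L]]$base_width,
                      parent = 1L))
    splits <- 0L
    while (splits < n_internal && length(open) > 0L) {
      leaf <- open[[1L]]
      open <- open[-1L]
      placed <- FALSE
      for (try in 1:25) {
        half <- runif(1, 24, 34) * pi / 180
        angs <- leaf$ang + c(-half, half) + runif(2, -0.04, 0.04)
        lens <- runif(2, 30, 42)
        ws <- pmax(3, round(leaf$width - runif(2, 1.5, 3)))
        q1s <- lapply(1:2, function(j) leaf$at + lens[j] * c(cos(angs[j]), sin(angs[j])))
        inside <- all(vapply(q1s, function(q) all(q >= 8 & q <= size - 9), logical(1L)))
        if (!inside) next
        ok <- clear_of(leaf$at, q1s[[1L]], ws[1L], leaf$parent) &&
          clear_of(leaf$at, q1s[[2L]], ws[2L], leaf$parent)
        # the two siblings must also clear each other away from the fork
        sib_d <- sqrt(sum((q1s[[1L]] - q1s[[2L]])^2))
        if (ok && sib_d > (ws[1L] + ws[2L]) / 2 + 10) {
          for (j in 1:2) {
            segs[[length(segs) + 1L]] <- list(points = rbind(leaf$at, q1s[[j]]),
                                              base_width = ws[j], parent = leaf$parent)
            seg_samples[[length(seg_samples) + 1L]] <- sample_line(leaf$at, q1s[[j]])
            open[[length(open) + 1L]] <- list(at = q1s[[j]], ang = angs[j],
                                              width = ws[j], parent = length(segs))
          }
          placed <- TRUE
          break
        }
      }
      if (placed) splits <- splits + 1L
    }
    phantom_spec(size, size, segments = segs, seed = seed, ...)
  })
}

#' Single-vessel bridge/stenosis phantom sequence spec
#'
#' One long vessel with a focal lesion, either periodic (a milking-effect
#' myocardial bridge surrogate) or static (an ordinary stenosis), under
#' bounded rigid motion.
#'
#' @param seed Integer seed for the layout.
#' @param periodic TRUE for a periodic (bridge) lesion.
#' @param severity Lesion severity fraction.
#' @param period_frames Period of the narrowing cycle in frames.
#' @param n_frames Sequence length.
#' @param size Image side in px.
#' @return A [phantom_spec()].
#' @export
bridge_case_spec <- function(seed = 1L, periodic = TRUE, severity = 0.5,
                             period_frames = 6L, n_frames = 12L, size = 160L) {
  with_phantom_rng(seed, {
    # gently curved vessel (coronary segments are never perfectly straight;
    # a straight run at exactly 45 degrees is also a degenerate orientation
    # for two-subiteration thinning, which erodes such limbs severely)
    ang <- runif(1, 20, 70) * pi / 180
    bend <- runif(1, 12, 20) * pi / 180 * sample(c(-1, 1), 1L)
    len1 <- runif(1, 50, 60); len2 <- runif(1, 50, 60)
    w <- round(runif(1, 9, 12))
    p0 <- c(runif(1, 14, 24), runif(1, 14, 24))
    p1 <- p0 + len1 * c(cos(ang), sin(ang))
    p2 <- p1 + len2 * c(cos(ang + bend), sin(ang + bend))
    motion <- c(sample(1:2, 1L), sample(1:2, 1L))
    phantom_spec(size, size,
                 segments = list(list(points = rbind(p0, p1, p2), base_width = w,
                                      parent = NA)),
                 motion_per_frame = motion, n_frames = n_frames,
                 stenoses = list(list(segment = 1L,
                                      position = runif(1, 0.4, 0.6),
                                      severity = severity, extent = 24,
                                      periodic = periodic,
                                      period_frames = period_frames)),
                 seed = seed)
  })
}
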