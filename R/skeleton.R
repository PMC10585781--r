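# Skeletonization and keypoint analysis.
#
# The thinning operator is the two-subiteration Zhang-Suen scheme: a
# foreground pixel is deleted when its neighbourhood (p2 above, p3..p9
# clockwise) satisfies
#   subiteration 1: 2 <= N(p1) <= 6, S(p1) = 1, p2*p4*p6 = 0, p4*p6*p8 = 0
#   subiteration 2: 2 <= N(p1) <= 6, S(p1) = 1, p2*p4*p8 = 0, p2*p6*p8 = 0
# where N counts foreground 8-neighbours and S counts 0->1 transitions in
# the cyclic neighbour sequence. Deletions within a subiteration are
# simultaneous; iteration stops when a full pass deletes nothing.

#' Thin a binary mask to a single-pixel skeleton
#'
#' @param mask A binary matrix (see [as_mask()]).
#' @return An integer 0/1 matrix of the same dimensions, single pixel wide.
#' @export
#' @examples
#' m <- matrix(0L, 9, 21); m[4:6, 2:20] <- 1L
#' sk <- thin(m)
thin <- function(mask) {
  m <- as_mask(mask)
  repeat {
    deleted <- 0L
    for (sub in 1:2) {
      nb <- neighbor_mats(m)
      N <- neighbor_count(nb)
      S <- transition_count(nb)
      if (sub == 1L) {
        cond <- nb$p2 * nb$p4 * nb$p6 == 0L & nb$p4 * nb$p6 * nb$p8 == 0L
      } else {
        cond <- nb$p2 * nb$p4 * nb$p8 == 0L & nb$p2 * nb$p6 * nb$p8 == 0L
      }
      del <- m == 1L & N >= 2L & N <= 6L & S == 1L & cond
      if (any(del)) {
        m[del] <- 0L
        deleted <- deleted + sum(del)
      }
    }
    if (deleted == 0L) break
  }
  m
}

#' Remove staircase corner pixels from a skeleton
#'
#' Deletes corner pixels of two-pixel staircase steps: a skeleton pixel is a
#' candidate when it has foreground neighbours directly above and to the
#' left, or directly above and to the right (the corner sits below-right or
#' below-left of the step). One sequential pass in row-major order; a
#' deletion is skipped when it would disconnect the local neighbourhood.
#'
#' @param skel A thinned skeleton matrix.
#' @return Skeleton matrix with staircase corners removed.
#' @export
remove_staircase <- function(skel) {
  m <- as_mask(skel)
  H <- nrow(m); W <- ncol(m)
  idx <- which(m == 1L)
  # row-major scan order (top-to-bottom, left-to-right)
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  ord <- order(rr, cc)
  for (k in ord) {
    r <- rr[k]; c <- cc[k]
    if (m[r, c] != 1L) next
    nbv <- pixel_neighborhood(m, r, c)
    above <- nbv[["p2"]]; left <- nbv[["p8"]]; right <- nbv[["p4"]]
    if ((above == 1L && left == 1L) || (above == 1L && right == 1L)) {
      if (ring_connected_without_center(nbv)) m[r, c] <- 0L
    }
  }
  m
}

#' Detect skeleton endpoints and intersections
#'
#' Endpoints are skeleton pixels with exactly one foreground 8-neighbour.
#' Intersection pixels must have at least three foreground 8-neighbours and
#' satisfy the four triple-sum conditions p3+p4+p5 <= 1, p5+p6+p7 <= 1,
#' p7+p8+p9 <= 1 and p9+p2+p3 <= 1, which reject pixels merely adjacent to
#' a junction. Adjacent pixels that all qualify are merged to the pixel
#' nearest their centroid.
#'
#' The triple-sum conditions are incomplete: a fork whose arms leave
#' through diagonally adjacent ring positions has no qualifying pixel at
#' all. For junction clusters (connected pixels with >= 3 neighbours and a
#' crossing number of >= 3 somewhere in the cluster) containing no
#' qualifying pixel, the cluster pixel with crossing number >= 3 nearest
#' the cluster centroid is reported instead, so every true bifurcation
#' yields exactly one intersection.
#'
#' @param skel A single-pixel skeleton matrix.
#' @return A list with `endpoints` and `intersections`, each an n x 2 matrix
#'   of (x, y) coordinates (0-based, x = column).
#' @export
detect_keypoints <- function(skel) {
  m <- as_mask(skel)
  nb <- neighbor_mats(m)
  N <- neighbor_count(nb)
  S <- transition_count(nb)
  ep <- which(m == 1L & N == 1L)
  eq8 <- m == 1L & N >= 3L &
    (nb$p3 + nb$p4 + nb$p5) <= 1L &
    (nb$p5 + nb$p6 + nb$p7) <= 1L &
    (nb$p7 + nb$p8 + nb$p9) <= 1L &
    (nb$p9 + nb$p2 + nb$p3) <= 1L
  H <- nrow(m)
  to_xy <- function(idx) {
    rc_to_xy(((idx - 1L) %% H) + 1L, ((idx - 1L) %/% H) + 1L)
  }
  bp <- branch_pixels(m)
  inter <- matrix(NA_integer_, 0L, 2L)
  colnames(inter) <- c("x", "y")
  pick_near_centroid <- function(idx) {
    gxy <- to_xy(idx)
    if (nrow(gxy) == 1L) return(gxy)
    ctr <- colMeans(gxy)
    d <- (gxy[, 1L] - ctr[1L])^2 + (gxy[, 2L] - ctr[2L])^2
    best <- which(d == min(d))
    if (length(best) > 1L) best <- best[order(gxy[best, 2L], gxy[best, 1L])][1L]
    gxy[best, , drop = FALSE]
  }
  if (length(bp) > 0L) {
    sel <- matrix(0L, H, ncol(m))
    sel[bp] <- 1L
    lab <- label_components(sel)
    for (g in seq_len(lab$n)) {
      gi <- which(lab$labels == g)
      in_eq8 <- gi[eq8[gi]]
      if (length(in_eq8) > 0L) {
        inter <- rbind(inter, pick_near_centroid(in_eq8))
      } else {
        cross <- gi[S[gi] >= 3L]
        if (length(cross) > 0L) inter <- rbind(inter, pick_near_centroid(cross))
      }
    }
  }
  # qualifying pixels outside any junction cluster (possible in principle)
  loose <- which(eq8)
  loose <- loose[!(loose %in% bp)]
  if (length(loose) > 0L) inter <- rbind(inter, to_xy(loose))
  list(
    endpoints = to_xy(ep),
    intersections = inter
  )
}

# Junction candidates, cluster-based. Candidate pixels have >= 3 skeleton
# neighbours; an 8-connected cluster of candidates is a junction only when
# it contains at least one pixel whose crossing number S(p1) (0->1
# transitions around the ring, i.e. distinct incident branches) is >= 3.
# This cuts whole junction clusters -- a fork often spreads over 2-3 pixels
# of which only one shows S >= 3 -- while leaving isolated staircase
# corners (N = 3 but S = 2, both extra neighbours on the same branch)
# alone. Used as cut points during path tracing so that tracing stays
# well-defined even at junction geometries the strict intersection
# conditions reject.
branch_pixels <- function(skel) {
  m <- as_mask(skel)
  nb <- neighbor_mats(m)
  N <- neighbor_count(nb)
  S <- transition_count(nb)
  cand <- m == 1L & N >= 3L
  if (!any(cand)) return(integer(0L))
  seed <- cand & S >= 3L
  if (!any(seed)) return(integer(0L))
  lab <- label_components(matrix(as.integer(cand), nrow(m), ncol(m)))
  good <- unique(lab$labels[seed])
  which(cand & lab$labels %in% good)
}

#' Split a skeleton into centerline paths at intersections
#'
#' The skeleton is partitioned at intersection keypoints (and at any pixel
#' with three or more skeleton neighbours); each remaining arc becomes an
#' ordered pixel path. Junction pixels are shared: they are appended to
#' every incident path but excluded from its length. A cyclic component
#' without keypoints is emitted as a single closed path with a warning.
#'
#' @param skel A single-pixel skeleton matrix.
#' @param kps Keypoints from [detect_keypoints()].
#' @param frame_index Frame number stored on each path (0-based).
#' @return A list of centerline paths; each is a list with `pixels` (n x 2
#'   (x, y) matrix), `junction_start`, `junction_end`, `closed`,
#'   `frame_index`.
#' @export
split_segments <- function(skel, kps = detect_keypoints(skel), frame_index = 0L) {
  m <- as_mask(skel)
  H <- nrow(m); W <- ncol(m)
  cut <- matrix(0L, H, W)
  if (nrow(kps$intersections) > 0L) {
    rc <- xy_to_rc(kps$intersections)
    cut[cbind(rc[, 1L], rc[, 2L])] <- 1L
  }
  cut[branch_pixels(m)] <- 1L
  cut <- cut * m
  # absorb 1-2 px arcs that merely bridge pixels of the same junction
  # cluster (thinning can leave tiny loops and fragments at a fork); they
  # belong to the junction, not to any vessel
  repeat {
    arcs <- m * (1L - cut)
    lab0 <- label_components(arcs)
    absorbed <- FALSE
    for (g in seq_len(lab0$n)) {
      gi <- which(lab0$labels == g)
      if (length(gi) > 2L) next
      rc <- cbind(((gi - 1L) %% H) + 1L, ((gi - 1L) %/% H) + 1L)
      n_adj_cut <- 0L
      for (q in seq_len(nrow(rc))) {
        for (dr in -1L:1L) for (dc in -1L:1L) {
          if (dr == 0L && dc == 0L) next
          rr <- rc[q, 1L] + dr; cc <- rc[q, 2L] + dc
          if (rr >= 1L && rr <= H && cc >= 1L && cc <= W && cut[rr, cc] == 1L)
            n_adj_cut <- n_adj_cut + 1L
        }
      }
      if (n_adj_cut >= 2L) {
        cut[gi] <- 1L
        absorbed <- TRUE
      }
    }
    if (!absorbed) break
  }
  arcs <- m * (1L - cut)
  lab <- label_components(arcs)
  paths <- list()
  to_xy1 <- function(idx) rc_to_xy(((idx - 1L) %% H) + 1L, ((idx - 1L) %/% H) + 1L)

  nb8 <- function(r, c) {
    out <- matrix(NA_integer_, 0L, 2L)
    for (dr in -1L:1L) for (dc in -1L:1L) {
      if (dr == 0L && dc == 0L) next
      rr2 <- r + dr; cc2 <- c + dc
      if (rr2 >= 1L && rr2 <= H && cc2 >= 1L && cc2 <= W)
        out <- rbind(out, c(rr2, cc2))
    }
    out
  }

  for (g in seq_len(lab$n)) {
    gi <- which(lab$labels == g)
    gset <- matrix(0L, H, W); gset[gi] <- 1L
    # degree within the arc
    deg <- vapply(gi, function(j) {
      r <- ((j - 1L) %% H) + 1L; c <- ((j - 1L) %/% H) + 1L
      nbs <- nb8(r, c)
      sum(gset[nbs])
    }, integer(1L))
    ends <- gi[deg <= 1L]
    closed <- FALSE
    if (length(ends) == 0L) {
      closed <- TRUE
      warning("cyclic skeleton component without keypoints; emitting closed path")
      xy <- to_xy1(gi)
      start_i <- gi[order(xy[, 2L], xy[, 1L])][1L]
    } else {
      exy <- to_xy1(ends)
      man <- abs(exy[, 1L]) + abs(exy[, 2L])
      o <- order(man, exy[, 2L], exy[, 1L])
      start_i <- ends[o[1L]]
    }
    # trace
    visited <- matrix(FALSE, H, W)
    path_rc <- matrix(NA_integer_, 0L, 2L)
    cur <- start_i
    repeat {
      r <- ((cur - 1L) %% H) + 1L; c <- ((cur - 1L) %/% H) + 1L
      visited[r, c] <- TRUE
      path_rc <- rbind(path_rc, c(r, c))
      nbs <- nb8(r, c)
      cand <- nbs[gset[nbs] == 1L & !visited[nbs], , drop = FALSE]
      if (nrow(cand) == 0L) break
      if (nrow(cand) > 1L) {
        # prefer 4-adjacent continuation, then deterministic (y, x)
        four <- abs(cand[, 1L] - r) + abs(cand[, 2L] - c) == 1L
        cand <- cand[order(!four, cand[, 1L], cand[, 2L]), , drop = FALSE]
      }
      cur <- (cand[1L, 2L] - 1L) * H + cand[1L, 1L]
    }
    pix <- rc_to_xy(path_rc[, 1L], path_rc[, 2L])
    # attach adjacent cut (junction) pixels at both ends
    junction_start <- FALSE; junction_end <- FALSE
    attach_junction <- function(rc_end) {
      nbs <- nb8(rc_end[1L], rc_end[2L])
      jn <- nbs[cut[nbs] == 1L, , drop = FALSE]
      if (nrow(jn) == 0L) return(NULL)
      if (nrow(jn) > 1L) {
        four <- abs(jn[, 1L] - rc_end[1L]) + abs(jn[, 2L] - rc_end[2L]) == 1L
        jn <- jn[order(!four, jn[, 1L], jn[, 2L]), , drop = FALSE]
      }
      jn[1L, ]
    }
    if (!closed) {
      j1 <- attach_junction(path_rc[1L, ])
      if (!is.null(j1)) {
        pix <- rbind(rc_to_xy(j1[1L], j1[2L]), pix)
        junction_start <- TRUE
      }
      j2 <- attach_junction(path_rc[nrow(path_rc), ])
      if (!is.null(j2)) {
        # avoid degenerate duplicate when the arc is a single pixel with one
        # junction neighbour already attached at the start
        if (is.null(j1) || any(j2 != j1) || nrow(path_rc) > 1L) {
          if (is.null(j1) || !(j2[1L] == j1[1L] && j2[2L] == j1[2L] && nrow(path_rc) == 1L)) {
            pix <- rbind(pix, rc_to_xy(j2[1L], j2[2L]))
            junction_end <- TRUE
          }
        }
      }
    }
    paths[[length(paths) + 1L]] <- list(
      pixels = pix,
      junction_start = junction_start,
      junction_end = junction_end,
      closed = closed,
      frame_index = as.integer(frame_index)
    )
  }
  # deterministic order: by start pixel (y, x)
  if (length(paths) > 1L) {
    starts <- t(vapply(paths, function(p) p$pixels[1L, ], numeric(2L)))
    paths <- paths[order(starts[, 2L], starts[, 1L])]
  }
  paths
}

#' Length of a centerline path in pixels
#'
#' Counts the path's own skeleton pixels; junction pixels shared with
#' adjoining paths are excluded so that segment lengths sum consistently
#' over the tree.
#'
#' @param path A centerline path from [split_segments()].
#' @return Integer pixel count.
#' @export
path_length <- function(path) {
  nrow(path$pixels) - as.integer(isTRUE(path$junction_start)) -
    as.integer(isTRUE(path$junction_end))
}

#' Remove burr paths
#'
#' Paths shorter than `min_len` pixels (default 6, strict less-than) are
#' spurious skeleton branches created by edge noise or thinning artifacts
#' and are dropped. A burr is a spur: it has at least one free (non-
#' junction) end. Short arcs running junction-to-junction are interior
#' vessel pieces and are kept.
#'
#' @param paths List of centerline paths.
#' @param min_len Minimum length kept, in pixels.
#' @return Filtered list of paths.
#' @export
remove_burrs <- function(paths, min_len = 6L) {
  if (length(paths) == 0L) return(paths)
  keep <- vapply(paths, function(p) {
    interior <- isTRUE(p$junction_start) && isTRUE(p$junction_end)
    path_length(p) >= min_len || interior || isTRUE(p$closed)
  }, logical(1L))
  paths[keep]
}

# Rebuild a skeleton grid from a list of paths.
paths_to_mask <- function(paths, dims) {
  m <- matrix(0L, dims[1L], dims[2L])
  for (p in paths) {
    rc <- xy_to_rc(p$pixels)
    m[cbind(rc[, 1L], rc[, 2L])] <- 1L
  }
  m
}

#' Repair a skeleton after burr removal
#'
#' Burr removal can delete a short interior piece that actually connected
#' two real vessels. The deleted set (original minus deburred) is scanned;
#' a deleted component is restored when it re-connects two endpoints of the
#' deburred skeleton that both lie within 2 pixels of a former intersection.
#' Terminal spurs touch at most one such endpoint and stay removed.
#'
#' @param original Skeleton before burr removal.
#' @param deburred Skeleton after burr removal (same dimensions).
#' @return Repaired skeleton matrix.
#' @export
repair <- function(original, deburred) {
  orig <- as_mask(original); deb <- as_mask(deburred)
  if (!mask_dims_equal(orig, deb)) stop("skeleton dimensions differ")
  deleted <- orig * (1L - deb)
  if (!any(deleted == 1L)) return(deb)
  H <- nrow(orig)
  # former intersections: strict keypoints plus any branch pixel of the
  # original skeleton
  kp <- detect_keypoints(orig)
  bp <- branch_pixels(orig)
  former <- kp$intersections
  if (length(bp) > 0L) {
    former <- rbind(former, rc_to_xy(((bp - 1L) %% H) + 1L, ((bp - 1L) %/% H) + 1L))
  }
  if (nrow(former) == 0L) return(deb)
  # endpoints of the deburred skeleton near former intersections
  epd <- detect_keypoints(deb)$endpoints
  if (nrow(epd) == 0L) return(deb)
  near_former <- vapply(seq_len(nrow(epd)), function(i) {
    any(pmax(abs(former[, 1L] - epd[i, 1L]), abs(former[, 2L] - epd[i, 2L])) <= 2L)
  }, logical(1L))
  epd <- epd[near_former, , drop = FALSE]
  if (nrow(epd) < 2L) return(deb)
  lab <- label_components(deleted)
  out <- deb
  for (g in seq_len(lab$n)) {
    gi <- which(lab$labels == g)
    gxy <- rc_to_xy(((gi - 1L) %% H) + 1L, ((gi - 1L) %/% H) + 1L)
    touches <- vapply(seq_len(nrow(epd)), function(i) {
      any(pmax(abs(gxy[, 1L] - epd[i, 1L]), abs(gxy[, 2L] - epd[i, 2L])) <= 1L)
    }, logical(1L))
    if (sum(touches) >= 2L) out[gi] <- 1L
  }
  out
}

#' Full skeletonization stage for one mask
#'
#' Runs thinning, staircase removal, keypoint detection, segment splitting,
#' burr removal and repair, then re-detects keypoints and re-splits on the
#' repaired skeleton.
#'
#' @param mask A binary mask.
#' @param config Pipeline configuration, see [angio_config()].
#' @param frame_index Frame number stored on paths.
#' @return List with `skeleton`, `keypoints`, `paths`.
#' @export
skeletonize <- function(mask, config = angio_config(), frame_index = 0L) {
  m <- as_mask(mask)
  sk <- remove_staircase(thin(m))
  kp <- detect_keypoints(sk)
  paths <- split_segments(sk, kp, frame_index)
  keep <- vapply(paths, function(p) {
    interior <- isTRUE(p$junction_start) && isTRUE(p$junction_end)
    path_length(p) >= config$burr_min_len || interior || isTRUE(p$closed)
  }, logical(1L))
  # deburr by deleting the burr paths' own pixels; junction pixels (shared)
  # and absorbed junction clusters stay in place
  deb <- sk
  burrs <- which(!keep)
  for (bi in burrs) {
    p <- paths[[bi]]
    own <- p$pixels
    if (isTRUE(p$junction_start)) own <- own[-1L, , drop = FALSE]
    if (isTRUE(p$junction_end) && nrow(own) > 0L) own <- own[-nrow(own), , drop = FALSE]
    if (nrow(own) > 0L) {
      rc <- xy_to_rc(own)
      deb[cbind(rc[, 1L], rc[, 2L])] <- 0L
    }
  }
  rep_sk <- repair(sk, deb)
  kp2 <- detect_keypoints(rep_sk)
  paths2 <- split_segments(rep_sk, kp2, frame_index)
  list(skeleton = rep_sk, keypoints = kp2, paths = paths2)
}
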