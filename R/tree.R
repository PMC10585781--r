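# Per-frame ternary vessel tree built from spatial relations: a segment
# becomes a child of a node when the Manhattan distance between the node's
# end point and the candidate's start point is within a threshold (10 px by
# default); each node keeps at most three children; child order follows the
# sign of the cross product of (parent end, child starts).

#' Manhattan distance between two pixel coordinates
#'
#' @param end,start Length-2 (x, y) vectors.
#' @return d_n = |x_s - x_e| + |y_s - y_e| in pixels.
#' @export
spatial_distance <- function(end, start) {
  abs(start[1L] - end[1L]) + abs(start[2L] - end[2L])
}

#' Find the catheter-proximal root segment
#'
#' The catheter enters near the upper-left image corner, so the root is the
#' segment whose start point minimizes the Manhattan distance to the image
#' origin; ties break by smaller y then smaller x.
#'
#' @param segments List of vessel segments.
#' @return Index into `segments` of the root.
#' @export
find_root <- function(segments) {
  if (length(segments) == 0L) stop("no segments to root")
  starts <- t(vapply(segments, function(s) as.numeric(s$start), numeric(2L)))
  man <- abs(starts[, 1L]) + abs(starts[, 2L])
  order(man, starts[, 2L], starts[, 1L])[1L]
}

#' Order children counterclockwise around the parent end point
#'
#' For two child start points p2, p3 and parent end p1 the sign of
#' V = (x2-x1)(y3-y2) - (y2-y1)(x3-x2) decides the order: V > 0 puts p2
#' first, V < 0 puts p3 first. Three children are ordered by applying the
#' same comparison pairwise. Collinear ties (V = 0) order by ascending x
#' then y. The sign is evaluated in image coordinates (y down) exactly as
#' the formula reads.
#'
#' @param p1 Parent end point (x, y).
#' @param child_starts List or n x 2 matrix of child start points (1-3).
#' @return Integer permutation of the children.
#' @export
order_children <- function(p1, child_starts) {
  if (is.list(child_starts)) child_starts <- do.call(rbind, child_starts)
  child_starts <- matrix(as.numeric(child_starts), ncol = 2L)
  k <- nrow(child_starts)
  if (k <= 1L) return(seq_len(k))
  cross_v <- function(a, b) {
    (a[1L] - p1[1L]) * (b[2L] - a[2L]) - (a[2L] - p1[2L]) * (b[1L] - a[1L])
  }
  before <- function(i, j) {
    v <- cross_v(child_starts[i, ], child_starts[j, ])
    if (v > 0) return(TRUE)
    if (v < 0) return(FALSE)
    xi <- child_starts[i, ]; xj <- child_starts[j, ]
    if (xi[1L] != xj[1L]) return(xi[1L] < xj[1L])
    xi[2L] <= xj[2L]
  }
  ord <- seq_len(k)
  # insertion sort with the pairwise comparator (k <= 3)
  for (i in 2L:k) {
    j <- i
    while (j > 1L && before(ord[j], ord[j - 1L])) {
      tmp <- ord[j]; ord[j] <- ord[j - 1L]; ord[j - 1L] <- tmp
      j <- j - 1L
    }
  }
  ord
}

#' Build the ternary vessel tree for one frame
#'
#' Breadth-first from the catheter root: an unassigned segment becomes a
#' child when the Manhattan distance from the parent's end to its start is
#' at most `d_n_threshold`; with more than three candidates the three
#' nearest are kept. Segments left unattached become additional roots of a
#' forest. IDs are reassigned top-to-bottom in breadth-first order (level by
#' level, children in geometric order), so smaller IDs are
#' earlier-developing vessels.
#'
#' @param segments List of vessel segments of one frame.
#' @param d_n_threshold Attachment threshold in pixels (inclusive).
#' @return A list with `nodes` (per new id: `segment`, `parent`, `children`,
#'   `level`), `root_ids`, and `segments` relabelled with the new ids.
#' @export
build_tree <- function(segments, d_n_threshold = 10) {
  n <- length(segments)
  if (n == 0L) return(list(nodes = list(), root_ids = integer(0L), segments = list()))
  assigned <- rep(FALSE, n)
  parent_of <- rep(NA_integer_, n)     # index into segments
  children_of <- vector("list", n)
  level_of <- rep(NA_integer_, n)
  root_idx <- integer(0L)
  bfs_order <- integer(0L)

  while (any(!assigned)) {
    rem <- which(!assigned)
    r <- rem[find_root(segments[rem])]
    root_idx <- c(root_idx, r)
    assigned[r] <- TRUE
    level_of[r] <- 0L
    queue <- r
    bfs_order <- c(bfs_order, r)
    while (length(queue) > 0L) {
      node <- queue[1L]; queue <- queue[-1L]
      rem <- which(!assigned)
      if (length(rem) == 0L) next
      pend <- as.numeric(segments[[node]]$end)
      d <- vapply(rem, function(i) {
        spatial_distance(pend, as.numeric(segments[[i]]$start))
      }, numeric(1L))
      cand <- rem[d <= d_n_threshold]
      dcand <- d[d <= d_n_threshold]
      if (length(cand) == 0L) next
      if (length(cand) > 3L) {
        o <- order(dcand)[1:3]
        cand <- cand[o]
      }
      # order children by a point a few pixels along each child: the start
      # points proper sit on the shared junction and carry no direction
      rep_point <- function(seg) {
        if (!is.null(seg$path)) {
          px <- seg$path$pixels
          as.numeric(px[min(12L, nrow(px)), ])
        } else {
          as.numeric(seg$start)
        }
      }
      starts <- t(vapply(cand, function(i) rep_point(segments[[i]]), numeric(2L)))
      ord <- order_children(pend, starts)
      cand <- cand[ord]
      for (ci in cand) {
        assigned[ci] <- TRUE
        parent_of[ci] <- node
        level_of[ci] <- level_of[node] + 1L
        children_of[[node]] <- c(children_of[[node]], ci)
        queue <- c(queue, ci)
        bfs_order <- c(bfs_order, ci)
      }
    }
  }

  # new ids in BFS order
  new_id <- integer(n)
  new_id[bfs_order] <- seq_len(n)
  nodes <- vector("list", n)
  segs_out <- vector("list", n)
  for (i in seq_len(n)) {
    id <- new_id[i]
    seg <- segments[[i]]
    seg$id <- id
    segs_out[[id]] <- seg
    nodes[[id]] <- list(
      segment = seg,
      parent = if (is.na(parent_of[i])) NA_integer_ else new_id[parent_of[i]],
      children = if (is.null(children_of[[i]])) integer(0L) else new_id[children_of[[i]]],
      level = level_of[i]
    )
  }
  list(nodes = nodes, root_ids = sort(new_id[root_idx]), segments = segs_out)
}

#' Leaf (peripheral) status of every tree node
#'
#' @param tree A vessel tree from [build_tree()].
#' @return Logical vector indexed by node id; TRUE for leaves.
#' @export
is_peripheral <- function(tree) {
  vapply(tree$nodes, function(nd) length(nd$children) == 0L, logical(1L))
}
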