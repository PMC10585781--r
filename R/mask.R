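#' @keywords internal
"_PACKAGE"

# Coordinate convention used throughout the package: x = column, y = row,
# 0-based, origin at the top-left pixel, y increasing downwards. Internal
# matrix indexing is the usual R [row, col] 1-based; the two helpers below
# are the only place the conversion happens.

rc_to_xy <- function(r, c) cbind(x = c - 1L, y = r - 1L)

xy_to_rc <- function(xy) cbind(r = xy[, 2L] + 1L, c = xy[, 1L] + 1L)

#' Coerce to a binary vessel mask
#'
#' A mask is an integer matrix with values in \{0, 1\}; rows are image rows
#' (y), columns are image columns (x). Any non-zero entry is treated as
#' vessel foreground.
#'
#' @param m A numeric or logical matrix.
#' @return An integer 0/1 matrix of the same dimensions.
#' @export
as_mask <- function(m) {
  if (!is.matrix(m)) stop("mask must be a matrix")
  if (nrow(m) < 3L || ncol(m) < 3L) stop("mask must be at least 3x3")
  out <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  out
}

# Neighbour matrices for the 8-neighbourhood, labelled p2..p9 with p2
# directly above the centre pixel and the rest clockwise:
#   p9 p2 p3
#   p8 p1 p4
#   p7 p6 p5
# Offsets are (dr, dc) of the neighbour relative to the centre.
.NB_OFFSETS <- list(
  p2 = c(-1L, 0L), p3 = c(-1L, 1L), p4 = c(0L, 1L), p5 = c(1L, 1L),
  p6 = c(1L, 0L), p7 = c(1L, -1L), p8 = c(0L, -1L), p9 = c(-1L, -1L)
)

# Matrix whose [r, c] entry is m[r + dr, c + dc], zero outside the image.
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  rs <- max(1L, 1L - dr):min(H, H - dr)
  cs <- max(1L, 1L - dc):min(W, W - dc)
  if (length(rs) > 0L && length(cs) > 0L)
    out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

# List of the eight neighbour-value matrices p2..p9.
neighbor_mats <- function(m) {
  lapply(.NB_OFFSETS, function(o) shift_mat(m, o[1L], o[2L]))
}

# N(p1): number of foreground 8-neighbours, per pixel.
neighbor_count <- function(nb) Reduce(`+`, nb)

# S(p1): number of 0->1 transitions in the cyclic sequence p2,p3,...,p9,p2.
transition_count <- function(nb) {
  ord <- c("p2", "p3", "p4", "p5", "p6", "p7", "p8", "p9", "p2")
  s <- 0L
  for (i in seq_len(8L)) {
    s <- s + as.integer(nb[[ord[i]]] == 0L & nb[[ord[i + 1L]]] == 1L)
  }
  s
}

# Values of the 8-neighbourhood of a single pixel (1-based r, c), ordered
# p2..p9; pixels outside the image count as background.
pixel_neighborhood <- function(m, r, c) {
  H <- nrow(m); W <- ncol(m)
  vapply(.NB_OFFSETS, function(o) {
    rr <- r + o[1L]; cc <- c + o[2L]
    if (rr < 1L || rr > H || cc < 1L || cc > W) 0L else as.integer(m[rr, cc] != 0L)
  }, integer(1L))
}

# 8-connected component labelling by flood fill (stack-based).
label_components <- function(m) {
  H <- nrow(m); W <- ncol(m)
  lab <- matrix(0L, H, W)
  cur <- 0L
  idx <- which(m != 0L)
  for (i in idx) {
    if (lab[i] != 0L) next
    cur <- cur + 1L
    stack <- i
    lab[i] <- cur
    while (length(stack) > 0L) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((j - 1L) %% H) + 1L
      c <- ((j - 1L) %/% H) + 1L
      for (dr in -1L:1L) for (dc in -1L:1L) {
        if (dr == 0L && dc == 0L) next
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > H || cc < 1L || cc > W) next
        k <- (cc - 1L) * H + rr
        if (m[k] != 0L && lab[k] == 0L) {
          lab[k] <- cur
          stack <- c(stack, k)
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

# TRUE if removing the centre pixel keeps its foreground 8-neighbours in a
# single 8-connected cluster within the 3x3 ring (simple-point check used as
# the connectivity guard during staircase removal).
ring_connected_without_center <- function(nbvals) {
  # offsets of p2..p9 around the centre
  offs <- matrix(c(-1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L,
                   1L, 0L, 1L, -1L, 0L, -1L, -1L, -1L),
                 ncol = 2L, byrow = TRUE)
  on <- which(nbvals == 1L)
  if (length(on) <= 1L) return(length(on) == 1L)
  pts <- offs[on, , drop = FALSE]
  # flood fill over Chebyshev-adjacent foreground ring positions
  seen <- logical(nrow(pts))
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack) > 0L) {
    i <- stack[length(stack)]; stack <- stack[-length(stack)]
    adj <- which(!seen &
                   pmax(abs(pts[, 1L] - pts[i, 1L]),
                        abs(pts[, 2L] - pts[i, 2L])) <= 1L)
    seen[adj] <- TRUE
    stack <- c(stack, adj)
  }
  all(seen)
}

mask_dims_equal <- function(a, b) all(dim(a) == dim(b))
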