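# Per-vessel description: local least-squares line fits along the
# centerline, diameters measured along the local normal, start/end
# coordinates and pixel length.

#' Least-squares line through a short centerline window
#'
#' Minimizes sum (a*x_i + b - y_i)^2. When the window has (numerically) no
#' x-spread the fit is repeated with the axes swapped and `axis_swapped` is
#' set; `a` and `b` then describe x = a*y + b.
#'
#' @param points An n x 2 matrix of (x, y), 2 to 5 rows.
#' @return A list with `a`, `b`, `axis_swapped`.
#' @export
fit_local_line <- function(points) {
  pts <- unique(as.matrix(points))
  if (nrow(pts) < 2L) stop("need at least 2 distinct points for a line fit")
  x <- pts[, 1L]; y <- pts[, 2L]
  if (diff(range(x)) < 1e-6) {
    # near-vertical: fit x as a function of y
    a <- sum((y - mean(y)) * (x - mean(x))) / sum((y - mean(y))^2)
    b <- mean(x) - a * mean(y)
    return(list(a = a, b = b, axis_swapped = TRUE))
  }
  a <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b <- mean(y) - a * mean(x)
  list(a = a, b = b, axis_swapped = FALSE)
}

# Unit normal (perpendicular to the fitted line) in (x, y) components.
line_normal <- function(fit) {
  if (fit$axis_swapped) {
    dirv <- c(fit$a, 1)   # d(x,y)/dy along the line x = a*y + b
  } else {
    dirv <- c(1, fit$a)
  }
  n <- c(-dirv[2L], dirv[1L])
  n / sqrt(sum(n^2))
}

# Bilinear interpolation of the mask at continuous (x, y); outside -> 0.
bilinear_mask <- function(mask, x, y) {
  H <- nrow(mask); W <- ncol(mask)
  # continuous row/col (1-based centres at integers)
  rr <- y + 1; cc <- x + 1
  r0 <- floor(rr); c0 <- floor(cc)
  fr <- rr - r0; fc <- cc - c0
  val <- function(r, c) {
    if (r < 1 || r > H || c < 1 || c > W) 0 else as.numeric(mask[r, c])
  }
  v00 <- val(r0, c0); v01 <- val(r0, c0 + 1)
  v10 <- val(r0 + 1, c0); v11 <- val(r0 + 1, c0 + 1)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

# March from (x0, y0) along direction d (unit) until the interpolated mask
# value drops below 0.5; returns the sub-pixel distance to the 0.5 crossing,
# or NA when the cap is reached.
march_to_edge <- function(mask, x0, y0, d, step = 0.25, cap = 50) {
  s_prev <- 0
  v_prev <- bilinear_mask(mask, x0, y0)
  if (v_prev < 0.5) return(NA_real_)
  s <- step
  while (s <= cap) {
    v <- bilinear_mask(mask, x0 + d[1L] * s, y0 + d[2L] * s)
    if (v < 0.5) {
      t <- (v_prev - 0.5) / (v_prev - v)
      return(s_prev + t * (s - s_prev))
    }
    s_prev <- s; v_prev <- v
    s <- s + step
  }
  NA_real_
}

#' Vessel diameter at one centerline sample
#'
#' Fits a line to the centerline window around `index` (window of
#' `fit_window` pixels, truncated at path ends), takes the normal through
#' the sample, and marches in both directions with bilinear interpolation
#' until the mask is exited at the 0.5 level. The diameter is the Euclidean
#' distance between the two exit points.
#'
#' @param mask Source binary mask.
#' @param path Centerline path from [split_segments()].
#' @param index 1-based index into the path pixels.
#' @param fit_window Window size for the local line fit (default 5).
#' @param step March step in pixels.
#' @param cap Maximum march distance per side, in pixels.
#' @return Diameter in pixels, or NA when the normal never exits within the
#'   cap or the sample lies outside the mask.
#' @export
diameter_at <- function(mask, path, index, fit_window = 5L, step = 0.25, cap = 50) {
  pix <- path$pixels
  n <- nrow(pix)
  if (index < 1L || index > n) stop("index outside path")
  half <- (fit_window - 1L) %/% 2L
  lo <- max(1L, index - half); hi <- min(n, index + half)
  win <- pix[lo:hi, , drop = FALSE]
  if (nrow(unique(win)) < 2L) return(NA_real_)
  fit <- fit_local_line(win)
  nv <- line_normal(fit)
  x0 <- pix[index, 1L]; y0 <- pix[index, 2L]
  e1 <- march_to_edge(mask, x0, y0, nv, step, cap)
  e2 <- march_to_edge(mask, x0, y0, -nv, step, cap)
  if (is.na(e1) || is.na(e2)) return(NA_real_)
  unname(e1 + e2)
}

#' Diameter profile of a vessel segment
#'
#' Evaluates [diameter_at()] at every path index except samples within
#' `junction_exclusion` pixels (Chebyshev) of an intersection keypoint,
#' where the two-edge assumption fails. Missing values are dropped with
#' positions preserved.
#'
#' @param mask Source binary mask.
#' @param path Centerline path.
#' @param intersections Optional m x 2 matrix of intersection (x, y)
#'   coordinates to exclude around; defaults to the path's own junction end
#'   pixels.
#' @param config Pipeline configuration, see [angio_config()].
#' @return A list with `values` (diameters, px) and `positions` (1-based
#'   path indices).
#' @export
profile_segment <- function(mask, path, intersections = NULL,
                            config = angio_config()) {
  pix <- path$pixels
  n <- nrow(pix)
  excl <- config$junction_exclusion
  if (is.null(intersections)) {
    intersections <- matrix(NA_real_, 0L, 2L)
    if (isTRUE(path$junction_start))
      intersections <- rbind(intersections, pix[1L, ])
    if (isTRUE(path$junction_end))
      intersections <- rbind(intersections, pix[n, ])
  }
  keep <- rep(TRUE, n)
  if (nrow(intersections) > 0L) {
    for (i in seq_len(n)) {
      cheb <- pmax(abs(intersections[, 1L] - pix[i, 1L]),
                   abs(intersections[, 2L] - pix[i, 2L]))
      if (any(cheb <= excl)) keep[i] <- FALSE
    }
  }
  pos <- which(keep)
  if (length(pos) == 0L) stop("no diameter samples outside the junction exclusion zone")
  vals <- vapply(pos, function(i) {
    diameter_at(mask, path, i, config$line_fit_N, config$normal_step,
                config$normal_search_cap)
  }, numeric(1L))
  ok <- !is.na(vals)
  if (!any(ok)) stop("all diameter samples missing for segment")
  list(values = vals[ok], positions = pos[ok])
}

# Canonical orientation: start = the path endpoint Manhattan-closer to the
# image origin (ties: smaller y, then smaller x). Matching and tree
# construction both assume a consistent start/end convention.
orient_path <- function(path) {
  pix <- path$pixels
  a <- pix[1L, ]; b <- pix[nrow(pix), ]
  da <- sum(abs(a)); db <- sum(abs(b))
  flip <- db < da || (db == da && (b[2L] < a[2L] || (b[2L] == a[2L] && b[1L] < a[1L])))
  if (flip) {
    path$pixels <- pix[nrow(pix):1L, , drop = FALSE]
    js <- path$junction_start
    path$junction_start <- path$junction_end
    path$junction_end <- js
  }
  path
}

#' Describe vessel segments on one frame
#'
#' Builds one vessel segment record per centerline path: provisional id,
#' canonical start/end coordinates, pixel length and diameter profile.
#'
#' @param mask Source binary mask.
#' @param paths Centerline paths (deburred and repaired).
#' @param intersections Optional intersection coordinates for profile
#'   exclusion.
#' @param frame_index Frame number (0-based).
#' @param config Pipeline configuration.
#' @return A list of vessel segments; each has `id`, `frame_index`, `path`,
#'   `start`, `end`, `length`, `profile`, `track_id`.
#' @export
describe_segments <- function(mask, paths, intersections = NULL,
                              frame_index = 0L, config = angio_config()) {
  segs <- list()
  for (i in seq_along(paths)) {
    p <- orient_path(paths[[i]])
    prof <- tryCatch(
      profile_segment(mask, p, intersections, config),
      error = function(e) NULL
    )
    if (is.null(prof)) next
    segs[[length(segs) + 1L]] <- list(
      id = length(segs) + 1L,
      frame_index = as.integer(frame_index),
      path = p,
      start = p$pixels[1L, ],
      end = p$pixels[nrow(p$pixels), ],
      length = path_length(p),
      profile = prof,
      track_id = NA_integer_
    )
  }
  segs
}

#' Export diameter profiles as a data frame
#'
#' @param segments List of vessel segments from [describe_segments()].
#' @return A data frame with columns frame, segment_id, path_index, x, y,
#'   diameter_px.
#' @export
profiles_to_df <- function(segments) {
  rows <- lapply(segments, function(s) {
    pos <- s$profile$positions
    data.frame(
      frame = s$frame_index,
      segment_id = s$id,
      path_index = pos,
      x = s$path$pixels[pos, 1L],
      y = s$path$pixels[pos, 2L],
      diameter_px = s$profile$values
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
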