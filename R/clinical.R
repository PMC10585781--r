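# Stenosis quantification/grading and myocardial-bridge detection.
#
# Stenosis degree: P = (1 - 2*D_min / (D_f + D_b)) * 100, where D_min is
# the candidate minimum of the smoothed diameter profile and D_f, D_b the
# nearest local maxima on either side (the expected healthy diameter is
# their mean). Grades follow the clinical bands: mild 30-50%, moderate
# 50-70%, severe over 70%; below 30% the vessel is reported normal.
#
# A myocardial bridge shows as periodic narrowing of the same vessel along
# the sequence ("milking effect"). Over a vessel track, either rule fires:
#   A: stenosis_max - stenosis_min >= 0.25 with the extreme frames >= 3 apart
#   B: average_min / average_max <= 0.75 with the extreme frames >= 3 apart
# Rule B covers long lesions where the whole vessel thins and no focal
# stenosis can be quantified.

#' Smooth a diameter profile with a trailing moving average
#'
#' y(k) = mean of the N_w samples ending at k; near the left edge the
#' window shrinks to the available samples.
#'
#' @param profile A profile list (`values`, `positions`) or a numeric
#'   vector.
#' @param N_w Odd window length, at most the profile length.
#' @return Same shape as the input with smoothed values.
#' @export
smooth_profile <- function(profile, N_w = 5L) {
  vals <- if (is.list(profile)) profile$values else profile
  if (N_w < 1L || N_w %% 2L == 0L) stop("N_w must be odd and >= 1")
  if (N_w > length(vals)) stop("N_w exceeds profile length")
  n <- length(vals)
  cs <- cumsum(vals)
  out <- numeric(n)
  for (k in seq_len(n)) {
    lo <- max(1L, k - N_w + 1L)
    out[k] <- (cs[k] - if (lo > 1L) cs[lo - 1L] else 0) / (k - lo + 1L)
  }
  if (is.list(profile)) {
    profile$values <- out
    profile
  } else {
    out
  }
}

# Indices of local minima / maxima of a numeric vector, plateau-aware:
# a plateau is an extremum when both flanks bend the same way.
local_extrema <- function(v) {
  n <- length(v)
  if (n < 3L) return(list(minima = integer(0L), maxima = integer(0L)))
  minima <- integer(0L); maxima <- integer(0L)
  i <- 2L
  while (i <= n - 1L) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    if (j <= n - 1L) {
      left <- v[i - 1L]; right <- v[j + 1L]
      mid <- (i + j) %/% 2L
      if (v[i] < left && v[i] < right) minima <- c(minima, mid)
      if (v[i] > left && v[i] > right) maxima <- c(maxima, mid)
    }
    i <- j + 1L
  }
  list(minima = minima, maxima = maxima)
}

#' Percent diameter stenosis
#'
#' @param D_min Minimal diameter (px).
#' @param D_f,D_b Flanking local-maximum diameters (px).
#' @return P in percent.
#' @export
stenosis_percent <- function(D_min, D_f, D_b) {
  (1 - 2 * D_min / (D_f + D_b)) * 100
}

#' Grade a percent stenosis
#'
#' Bands are lower-inclusive: \[30, 50) mild (label 0), \[50, 70) moderate
#' (label 1), >= 70 severe (label 2); below 30 the vessel is normal.
#'
#' @param P Percent stenosis in \[0, 100\].
#' @return Character grade: "normal", "mild", "moderate" or "severe".
#' @export
grade_stenosis <- function(P) {
  vapply(P, function(p) {
    if (p >= 70) "severe"
    else if (p >= 50) "moderate"
    else if (p >= 30) "mild"
    else "normal"
  }, character(1L))
}

#' Integer grade label (Table-style): mild 0, moderate 1, severe 2
#'
#' @param grade Character grade from [grade_stenosis()].
#' @return Integer label, NA for "normal".
#' @export
grade_label <- function(grade) {
  unname(c(normal = NA_integer_, mild = 0L, moderate = 1L, severe = 2L)[grade])
}

#' Quantify stenoses on a smoothed diameter profile
#'
#' Non-peripheral vessels use the global minimum of the whole profile as
#' the single candidate; peripheral (leaf) vessels use all local minima
#' excluding the distal 20% of the path, where the vessel naturally tapers.
#' Flanking diameters are the nearest local maxima on each side; a profile
#' boundary counts as a maximum when the profile is monotone towards it.
#' Candidates below `floor` percent are discarded as normal.
#'
#' @param profile Smoothed profile (`values`, `positions`).
#' @param peripheral Logical; TRUE for leaf segments of the vessel tree.
#' @param floor Reporting floor in percent (default 30; use 0 to keep all
#'   candidates).
#' @return A data frame with columns position (path index), D_min, D_f,
#'   D_b, P, grade, label; zero rows when there is no interior minimum.
#' @export
quantify_stenosis <- function(profile, peripheral = FALSE, floor = 30) {
  v <- profile$values
  pos <- profile$positions
  n <- length(v)
  empty <- data.frame(position = integer(0L), D_min = numeric(0L),
                      D_f = numeric(0L), D_b = numeric(0L), P = numeric(0L),
                      grade = character(0L), label = integer(0L))
  if (n < 5L) return(empty)
  ext <- local_extrema(v)
  if (peripheral) {
    cutoff <- 0.8 * max(pos)
    cand <- ext$minima[pos[ext$minima] <= cutoff]
  } else {
    k <- which.min(v)
    cand <- if (k > 1L && k < n) k else integer(0L)
  }
  if (length(cand) == 0L) return(empty)
  rows <- lapply(cand, function(k) {
    left_max <- ext$maxima[ext$maxima < k]
    right_max <- ext$maxima[ext$maxima > k]
    D_f <- if (length(left_max) > 0L) v[max(left_max)] else v[1L]
    D_b <- if (length(right_max) > 0L) v[min(right_max)] else v[n]
    P <- stenosis_percent(v[k], D_f, D_b)
    data.frame(position = pos[k], D_min = v[k], D_f = D_f, D_b = D_b, P = P)
  })
  out <- do.call(rbind, rows)
  out <- out[out$P >= floor, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)
  out$grade <- grade_stenosis(out$P)
  out$label <- grade_label(out$grade)
  rownames(out) <- NULL
  out
}

#' Detect a myocardial bridge on one vessel track
#'
#' @param track_summary Data frame with one row per track member and
#'   columns `frame`, `degree` (stenosis fraction 0-1) and `mean_diameter`
#'   (px).
#' @param config Pipeline configuration, see [angio_config()].
#' @return A bridge finding (list) or NULL. Rule A (stenosis variation) is
#'   checked before rule B (diameter ratio); tracks shorter than 4 members
#'   never fire.
#' @export
detect_bridge <- function(track_summary, config = angio_config()) {
  ts <- track_summary
  if (nrow(ts) < 4L) return(NULL)
  # rule A: variation of the stenosis degree
  deg <- ts$degree
  if (all(is.finite(deg))) {
    imax <- which.max(deg); imin <- which.min(deg)
    if ((deg[imax] - deg[imin]) >= config$bridge_stenosis_delta &&
        abs(ts$frame[imax] - ts$frame[imin]) >= config$bridge_frame_gap) {
      return(list(
        rule = "stenosis_variation",
        stenosis_max = deg[imax], stenosis_min = deg[imin],
        stenosis_max_frame = ts$frame[imax], stenosis_min_frame = ts$frame[imin]
      ))
    }
  }
  # rule B: ratio of the per-frame mean diameter
  md <- ts$mean_diameter
  if (all(is.finite(md)) && max(md) > 0) {
    imax <- which.max(md); imin <- which.min(md)
    if (md[imin] / md[imax] <= config$bridge_diameter_ratio &&
        abs(ts$frame[imax] - ts$frame[imin]) >= config$bridge_frame_gap) {
      return(list(
        rule = "diameter_ratio",
        average_max = md[imax], average_min = md[imin],
        average_max_frame = ts$frame[imax], average_min_frame = ts$frame[imin]
      ))
    }
  }
  NULL
}

#' Per-frame track summary used for bridge detection
#'
#' For each member segment: the stenosis degree is the most severe
#' candidate on the frame (fraction of P, no reporting floor, clamped at
#' 0), and the mean diameter is the mean of the smoothed profile.
#'
#' @param track A track from [fuse_sequence()].
#' @param frame_segments List (one element per frame, 0-based `frame`
#'   values match `frame + 1` list positions) of described segments.
#' @param tree_peripheral List of per-frame logical vectors (by segment
#'   id) marking leaves.
#' @param config Pipeline configuration.
#' @return Data frame with columns frame, id, degree, mean_diameter.
#' @export
summarize_track <- function(track, frame_segments, tree_peripheral,
                            config = angio_config()) {
  mem <- track$members
  rows <- lapply(seq_len(nrow(mem)), function(i) {
    f <- mem$frame[i]; id <- mem$id[i]
    segs <- frame_segments[[f + 1L]]
    seg <- NULL
    for (s in segs) if (s$id == id) { seg <- s; break }
    sm <- smooth_profile(seg$profile,
                         min(config$smooth_N_w,
                             length(seg$profile$values) -
                               (1 - length(seg$profile$values) %% 2L)))
    periph <- isTRUE(tree_peripheral[[f + 1L]][id])
    q <- quantify_stenosis(sm, peripheral = periph, floor = 0)
    degree <- if (nrow(q) > 0L) max(0, max(q$P) / 100) else 0
    data.frame(frame = f, id = id, degree = degree,
               mean_diameter = mean(sm$values))
  })
  do.call(rbind, rows)
}
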