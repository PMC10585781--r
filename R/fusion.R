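# Inter-frame vessel matching and sequence-wide track construction.
#
# Two segments from different frames are the same vessel when their start
# points and end points are each within 65 px (Manhattan, strict) and the
# ratio of the shorter to the longer length exceeds 0.80. Ambiguities are
# resolved globally by ascending d_s + d_e.

#' Match two vessel segments from different frames
#'
#' @param seg_a,seg_b Vessel segments (canonically oriented).
#' @param config Pipeline configuration, see [angio_config()].
#' @return A match record (list with `d_s`, `d_e`, `rate` and the frame/id
#'   pair) when the acceptance conditions hold, otherwise NULL.
#' @export
match_pair <- function(seg_a, seg_b, config = angio_config()) {
  if (seg_a$length <= 0L || seg_b$length <= 0L) stop("zero-length segment")
  d_s <- spatial_distance(seg_a$start, seg_b$start)
  d_e <- spatial_distance(seg_a$end, seg_b$end)
  rate <- min(seg_a$length, seg_b$length) / max(seg_a$length, seg_b$length)
  if (d_s < config$d_s_max && d_e < config$d_e_max && rate > config$rate_min) {
    list(frame_a = seg_a$frame_index, id_a = seg_a$id,
         frame_b = seg_b$frame_index, id_b = seg_b$id,
         d_s = d_s, d_e = d_e, rate = rate)
  } else {
    NULL
  }
}

#' Match all vessels between two frames
#'
#' Collects every candidate pair passing the acceptance conditions, then
#' resolves ambiguities greedily in ascending d_s + d_e (ties by segment
#' ids); each segment is matched at most once.
#'
#' @param segs_a,segs_b Lists of vessel segments from the two frames.
#' @param config Pipeline configuration.
#' @return A data frame of accepted match records (possibly empty) with
#'   columns frame_a, id_a, frame_b, id_b, d_s, d_e, rate.
#' @export
match_frames <- function(segs_a, segs_b, config = angio_config()) {
  empty <- data.frame(frame_a = integer(0L), id_a = integer(0L),
                      frame_b = integer(0L), id_b = integer(0L),
                      d_s = numeric(0L), d_e = numeric(0L), rate = numeric(0L))
  if (length(segs_a) == 0L || length(segs_b) == 0L) return(empty)
  recs <- list()
  for (a in segs_a) for (b in segs_b) {
    r <- match_pair(a, b, config)
    if (!is.null(r)) recs[[length(recs) + 1L]] <- r
  }
  if (length(recs) == 0L) return(empty)
  df <- do.call(rbind, lapply(recs, as.data.frame))
  df <- df[order(df$d_s + df$d_e, df$id_a, df$id_b), , drop = FALSE]
  used_a <- character(0L); used_b <- character(0L)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    ka <- paste(df$frame_a[i], df$id_a[i]); kb <- paste(df$frame_b[i], df$id_b[i])
    if (!(ka %in% used_a) && !(kb %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, ka); used_b <- c(used_b, kb)
    }
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fuse a described sequence into vessel tracks
#'
#' For each frame t, segments without a forward match are tried against
#' frames t+1, then t+2, then t+3. A segment already absorbed into a track
#' is not rematched. Accepted matches chain into tracks (at most one member
#' per frame, frame-sorted).
#'
#' @param frame_segments List (one element per frame) of segment lists.
#' @param config Pipeline configuration.
#' @return A list with `matches` (data frame of all accepted records) and
#'   `tracks` (list of `track_id`, `members` data frame with columns frame
#'   and id).
#' @export
fuse_sequence <- function(frame_segments, config = angio_config()) {
  TT <- length(frame_segments)
  all_matches <- list()
  # forward link per (frame, id); incoming-matched flag per (frame, id)
  key <- function(f, id) paste0(f, ":", id)
  fwd <- new.env(parent = emptyenv())
  has_incoming <- new.env(parent = emptyenv())
  if (TT >= 2L) {
    for (t in seq_len(TT - 1L)) {
      for (gap in 1:3) {
        tb <- t + gap
        if (tb > TT) break
        a_el <- Filter(function(s) is.null(fwd[[key(t, s$id)]]), frame_segments[[t]])
        b_el <- Filter(function(s) is.null(has_incoming[[key(tb, s$id)]]),
                       frame_segments[[tb]])
        m <- match_frames(a_el, b_el, config)
        if (nrow(m) > 0L) {
          for (i in seq_len(nrow(m))) {
            fwd[[key(t, m$id_a[i])]] <- c(tb, m$id_b[i])
            has_incoming[[key(tb, m$id_b[i])]] <- TRUE
          }
          all_matches[[length(all_matches) + 1L]] <- m
        }
      }
    }
  }
  matches <- if (length(all_matches) > 0L) {
    do.call(rbind, all_matches)
  } else {
    data.frame(frame_a = integer(0L), id_a = integer(0L),
               frame_b = integer(0L), id_b = integer(0L),
               d_s = numeric(0L), d_e = numeric(0L), rate = numeric(0L))
  }
  rownames(matches) <- NULL
  # build tracks by following forward links from chain heads
  tracks <- list()
  for (t in seq_len(TT)) {
    for (s in frame_segments[[t]]) {
      if (!is.null(has_incoming[[key(t, s$id)]])) next
      # chain head; follow links (frames reported 0-based like frame_index)
      members <- data.frame(frame = s$frame_index, id = s$id)
      cur <- c(t, s$id)
      repeat {
        nxt <- fwd[[key(cur[1L], cur[2L])]]
        if (is.null(nxt)) break
        members <- rbind(members,
                         data.frame(frame = frame_segments[[nxt[1L]]][[1L]]$frame_index,
                                    id = nxt[2L]))
        cur <- nxt
      }
      if (nrow(members) > 1L) {
        tracks[[length(tracks) + 1L]] <- list(
          track_id = length(tracks) + 1L,
          members = members
        )
      }
    }
  }
  list(matches = matches, tracks = tracks)
}
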