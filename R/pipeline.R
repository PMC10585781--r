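# End-to-end sequence pipeline: skeletonize each frame, describe segments,
# build the per-frame vessel tree, match vessels across frames, then run
# stenosis quantification per frame and bridge detection per track.

#' Run the full analysis pipeline on a mask sequence
#'
#' @param masks List of binary masks (one per frame, consistent shapes).
#' @param config Pipeline configuration, see [angio_config()].
#' @return A sequence report: `metadata`, `frames` (segments, tree,
#'   keypoints per frame), `matches`, `tracks`, `stenoses`, `bridges`.
#' @export
run_pipeline <- function(masks, config = angio_config()) {
  stopifnot(length(masks) >= 1L)
  TT <- length(masks)
  frame_segments <- vector("list", TT)
  frames_out <- vector("list", TT)
  peripheral <- vector("list", TT)

  for (t in seq_len(TT)) {
    fr_idx <- t - 1L
    res <- tryCatch(
      skeletonize(masks[[t]], config, frame_index = fr_idx),
      error = function(e) {
        warning(sprintf("frame %d skipped during skeletonization: %s",
                        fr_idx, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res) || length(res$paths) == 0L) {
      frame_segments[[t]] <- list()
      peripheral[[t]] <- logical(0L)
      frames_out[[t]] <- list(frame_index = fr_idx, segments = list(),
                              tree = list(), keypoints = list(
                                endpoints = matrix(NA_real_, 0L, 2L),
                                intersections = matrix(NA_real_, 0L, 2L)))
      next
    }
    segs <- describe_segments(masks[[t]], res$paths,
                              intersections = res$keypoints$intersections,
                              frame_index = fr_idx, config = config)
    tre <- build_tree(segs, config$d_n_threshold)
    frame_segments[[t]] <- tre$segments
    peripheral[[t]] <- if (length(tre$segments) > 0L) is_peripheral(tre) else logical(0L)
    frames_out[[t]] <- list(
      frame_index = fr_idx,
      segments = lapply(tre$segments, function(s) list(
        id = s$id, start = as.numeric(s$start), end = as.numeric(s$end),
        length = s$length,
        mean_diameter = mean(s$profile$values)
      )),
      tree = list(
        root_ids = tre$root_ids,
        nodes = lapply(seq_along(tre$nodes), function(i) list(
          id = i, parent = tre$nodes[[i]]$parent,
          children = tre$nodes[[i]]$children
        ))
      ),
      keypoints = res$keypoints
    )
  }

  fused <- fuse_sequence(frame_segments, config)

  # per-frame stenosis findings
  stenoses <- list()
  for (t in seq_len(TT)) {
    for (s in frame_segments[[t]]) {
      nvals <- length(s$profile$values)
      if (nvals < 5L) next
      w <- min(config$smooth_N_w, nvals - (1L - nvals %% 2L))
      sm <- smooth_profile(s$profile, w)
      q <- quantify_stenosis(sm, peripheral = isTRUE(peripheral[[t]][s$id]),
                             floor = config$stenosis_floor)
      if (nrow(q) > 0L) for (i in seq_len(nrow(q))) {
        stenoses[[length(stenoses) + 1L]] <- list(
          frame_index = s$frame_index, segment_id = s$id,
          position = q$position[i], D_min = q$D_min[i],
          D_f = q$D_f[i], D_b = q$D_b[i], P = q$P[i],
          grade = q$grade[i], label = q$label[i]
        )
      }
    }
  }

  # bridge detection per track
  bridges <- list()
  track_summaries <- list()
  for (tr in fused$tracks) {
    ts <- summarize_track(tr, frame_segments, peripheral, config)
    track_summaries[[length(track_summaries) + 1L]] <-
      cbind(track_id = tr$track_id, ts)
    bf <- detect_bridge(ts, config)
    if (!is.null(bf)) {
      bf$track_id <- tr$track_id
      bridges[[length(bridges) + 1L]] <- bf
    }
  }

  list(
    metadata = list(
      package = "angiotrack",
      version = as.character(utils::packageVersion("angiotrack")),
      n_frames = TT,
      config = config
    ),
    frames = frames_out,
    matches = fused$matches,
    tracks = lapply(seq_along(fused$tracks), function(i) {
      tr <- fused$tracks[[i]]
      tr$summary <- track_summaries[[i]]
      tr
    }),
    stenoses = stenoses,
    bridges = bridges
  )
}
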