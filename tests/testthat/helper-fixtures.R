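# Small skeleton fixtures built in code. Coordinates are (x, y), 0-based.

plus_mask <- function() {
  m <- matrix(0L, 11, 11)
  m[6, 2:10] <- 1L
  m[2:10, 6] <- 1L
  m
}

t_mask <- function() {
  m <- matrix(0L, 11, 11)
  m[2, 2:10] <- 1L
  m[2:10, 6] <- 1L
  m
}

# Y junction with arms up, left and down-right: the centre has foreground
# at ring positions p2, p8 and p5, which satisfies all four triple-sum
# intersection conditions (each triple contains exactly one arm).
y_mask <- function() {
  m <- matrix(0L, 11, 11)
  m[6, 6] <- 1L
  for (k in 1:4) {
    m[6 - k, 6] <- 1L       # up
    m[6, 6 - k] <- 1L       # left
    m[6 + k, 6 + k] <- 1L   # down-right diagonal
  }
  m
}

# Filled horizontal bar of a given pixel height.
bar_mask <- function(height = 3L, length = 21L, pad = 4L) {
  m <- matrix(0L, height + 2L * pad, length + 2L * pad)
  m[(pad + 1L):(pad + height), (pad + 1L):(pad + length)] <- 1L
  m
}

# Minimal vessel-segment stub for tree/fusion unit tests.
seg_stub <- function(id, start, end, length, frame = 0L) {
  list(id = as.integer(id), frame_index = as.integer(frame),
       start = start, end = end, length = as.integer(length),
       profile = list(values = rep(5, 10), positions = 1:10),
       track_id = NA_integer_)
}

# Map recovered segments onto phantom truth segments by mean distance of
# the recovered centerline to the truth centerline.
map_to_truth <- function(segments, truth_segs) {
  vapply(segments, function(s) {
    d <- vapply(truth_segs, function(ts) {
      cl <- ts$centerline
      mean(apply(s$path$pixels, 1, function(p) {
        min(sqrt((cl[, 1] - p[1])^2 + (cl[, 2] - p[2])^2))
      }))
    }, numeric(1))
    which.min(d)
  }, integer(1))
}
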