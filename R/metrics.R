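# Segmentation and detection evaluation utilities.

#' Dice overlap between two masks
#'
#' 2|A intersect B| / (|A| + |B|); two empty masks score 1.
#'
#' @param ref,seg Binary masks of the same shape.
#' @return Fraction in \[0, 1\].
#' @export
dice <- function(ref, seg) {
  a <- as_mask(ref); b <- as_mask(seg)
  if (!mask_dims_equal(a, b)) stop("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a * b) / (na + nb)
}

# Boundary pixels: foreground with at least one background 4-neighbour
# (the image border counts as background).
boundary_xy <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- shift_mat(m, -1L, 0L); down <- shift_mat(m, 1L, 0L)
  left <- shift_mat(m, 0L, -1L); right <- shift_mat(m, 0L, 1L)
  inner4 <- up * down * left * right
  b <- m == 1L & (inner4 == 0L |
                    row(m) == 1L | row(m) == H | col(m) == 1L | col(m) == W)
  idx <- which(b)
  rc_to_xy(((idx - 1L) %% H) + 1L, ((idx - 1L) %/% H) + 1L)
}

#' Average symmetric surface distance between two masks
#'
#' Boundaries are foreground pixels with a background 4-neighbour; the ASD
#' averages, over both boundaries, the Euclidean distance of each boundary
#' pixel to the nearest pixel of the other boundary.
#'
#' @param ref,seg Nonempty binary masks of the same shape.
#' @return Distance in pixels.
#' @export
asd <- function(ref, seg) {
  a <- as_mask(ref); b <- as_mask(seg)
  if (!mask_dims_equal(a, b)) stop("mask shapes differ")
  if (sum(a) == 0L || sum(b) == 0L) stop("ASD undefined for an empty mask")
  A <- boundary_xy(a); B <- boundary_xy(b)
  min_d <- function(P, Q) {
    vapply(seq_len(nrow(P)), function(i) {
      sqrt(min((Q[, 1L] - P[i, 1L])^2 + (Q[, 2L] - P[i, 2L])^2))
    }, numeric(1L))
  }
  (sum(min_d(A, B)) + sum(min_d(B, A))) / (nrow(A) + nrow(B))
}

#' Accuracy and recall from confusion counts
#'
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return A list with `accuracy` and `recall`; a rate with a zero
#'   denominator is NA.
#' @export
accuracy_recall <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  total <- TP + TN + FP + FN
  list(
    accuracy = if (total > 0) (TP + TN) / total else NA_real_,
    recall = if (TP + FN > 0) TP / (TP + FN) else NA_real_
  )
}
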