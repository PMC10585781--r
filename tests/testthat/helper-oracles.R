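# Independent oracles, deliberately written as naive pixel-by-pixel loops
# so they share no code path with the package implementation.

# Two-subiteration thinning applied literally, one pixel at a time.
zs_thin_oracle <- function(m) {
  H <- nrow(m); W <- ncol(m)
  val <- function(mm, r, c) if (r < 1 || r > H || c < 1 || c > W) 0L else mm[r, c]
  nbv <- function(mm, r, c) {
    c(val(mm, r - 1, c),     val(mm, r - 1, c + 1), val(mm, r, c + 1),
      val(mm, r + 1, c + 1), val(mm, r + 1, c),     val(mm, r + 1, c - 1),
      val(mm, r, c - 1),     val(mm, r - 1, c - 1))          # p2..p9
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      del <- matrix(FALSE, H, W)
      for (r in 1:H) for (c in 1:W) {
        if (m[r, c] != 1L) next
        v <- nbv(m, r, c)
        N <- sum(v)
        if (N < 2 || N > 6) next
        S <- sum(v == 0 & c(v[-1], v[1]) == 1)
        if (S != 1) next
        if (sub == 1) {
          if (v[1] * v[3] * v[5] != 0 || v[3] * v[5] * v[7] != 0) next
        } else {
          if (v[1] * v[3] * v[7] != 0 || v[1] * v[5] * v[7] != 0) next
        }
        del[r, c] <- TRUE
      }
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# Brute-force double-loop average symmetric surface distance.
asd_oracle <- function(a, b) {
  bxy <- function(m) {
    H <- nrow(m); W <- ncol(m)
    out <- NULL
    for (r in 1:H) for (c in 1:W) {
      if (m[r, c] != 1L) next
      nb4 <- c(if (r > 1) m[r - 1, c] else 0L, if (r < H) m[r + 1, c] else 0L,
               if (c > 1) m[r, c - 1] else 0L, if (c < W) m[r, c + 1] else 0L)
      if (any(nb4 == 0L) || r == 1 || r == H || c == 1 || c == W)
        out <- rbind(out, c(c - 1, r - 1))
    }
    out
  }
  A <- bxy(a); B <- bxy(b)
  dmin <- function(P, Q) {
    sapply(seq_len(nrow(P)), function(i) {
      min(sqrt((Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2))
    })
  }
  (sum(dmin(A, B)) + sum(dmin(B, A))) / (nrow(A) + nrow(B))
}

# Exact Euclidean distance transform value at points (x, y): distance to
# the nearest background pixel centre. 2x this value is the width oracle
# for a vessel centerline sample.
edt_at <- function(mask, xy) {
  bg <- which(mask == 0L)
  H <- nrow(mask)
  bx <- ((bg - 1L) %/% H)        # 0-based x
  by <- ((bg - 1L) %% H)         # 0-based y
  vapply(seq_len(nrow(xy)), function(i) {
    sqrt(min((bx - xy[i, 1L])^2 + (by - xy[i, 2L])^2))
  }, numeric(1L))
}

# Random blobby binary mask (unioned axis-aligned boxes and discs).
random_mask <- function(H, W, n_blobs = 3L) {
  m <- matrix(0L, H, W)
  for (b in seq_len(n_blobs)) {
    if (runif(1) < 0.5) {
      r <- sample(1:H, 1); c <- sample(1:W, 1); rad <- sample(2:6, 1)
      m[pmax(1, r - rad):pmin(H, r + rad), pmax(1, c - rad):pmin(W, c + rad)] <- 1L
    } else {
      r <- sample(1:H, 1); c <- sample(1:W, 1); rad <- sample(2:7, 1)
      for (rr in pmax(1, r - rad):pmin(H, r + rad))
        for (cc in pmax(1, c - rad):pmin(W, c + rad))
          if ((rr - r)^2 + (cc - c)^2 <= rad^2) m[rr, cc] <- 1L
    }
  }
  m
}
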