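# Readers/writers for mask sequences and the JSON sequence report.

#' Read a mask sequence
#'
#' Accepts a directory of numbered PNG or TIFF files (ordered by filename)
#' or a single (possibly multipage) TIFF file. Any non-zero pixel is
#' foreground.
#'
#' @param path Directory or TIFF file path.
#' @return A list of 0/1 integer masks with consistent shapes.
#' @export
read_mask_sequence <- function(path) {
  read_one <- function(img) {
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    matrix(as.integer(img != 0), nrow(img), ncol(img))
  }
  masks <- list()
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) stop("no PNG/TIFF files in ", path)
    for (f in files) {
      img <- if (grepl("\\.png$", f, ignore.case = TRUE)) {
        png::readPNG(f)
      } else {
        tiff::readTIFF(f)
      }
      masks[[length(masks) + 1L]] <- read_one(img)
    }
  } else if (file.exists(path)) {
    if (!grepl("\\.(tif|tiff)$", path, ignore.case = TRUE))
      stop("single-file input must be a TIFF: ", path)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    masks <- lapply(pages, read_one)
  } else {
    stop("no such file or directory: ", path)
  }
  dims <- vapply(masks, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("frames have inconsistent shapes")
  masks
}

#' Validate a sequence report
#'
#' Checks the report structure and that every segment id referenced by
#' matches, tracks, stenoses and bridges exists among the frame segments.
#'
#' @param report A report list from [run_pipeline()].
#' @return TRUE invisibly; stops with the offending path otherwise.
#' @export
validate_report <- function(report) {
  need <- c("metadata", "frames", "matches", "tracks", "stenoses", "bridges")
  miss <- setdiff(need, names(report))
  if (length(miss) > 0L) stop("report missing fields: ", paste(miss, collapse = ", "))
  ids <- lapply(report$frames, function(fr) {
    vapply(fr$segments, function(s) s$id, integer(1L))
  })
  have <- function(frame, id) {
    frame >= 0L && frame < length(ids) && id %in% ids[[frame + 1L]]
  }
  m <- report$matches
  if (nrow(m) > 0L) for (i in seq_len(nrow(m))) {
    if (!have(m$frame_a[i], m$id_a[i]) || !have(m$frame_b[i], m$id_b[i]))
      stop("report$matches[", i, "] references a missing segment")
  }
  for (tr in report$tracks) {
    mem <- tr$members
    for (i in seq_len(nrow(mem))) {
      if (!have(mem$frame[i], mem$id[i]))
        stop("report$tracks track ", tr$track_id, " references a missing segment")
    }
  }
  for (i in seq_along(report$stenoses)) {
    st <- report$stenoses[[i]]
    if (!have(st$frame_index, st$segment_id))
      stop("report$stenoses[", i, "] references a missing segment")
  }
  invisible(TRUE)
}

#' Write a sequence report to JSON
#'
#' @param report Report list (validated first).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  validate_report(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

#' Quality-control overlay for one frame
#'
#' Writes an RGB PNG with the mask in grey, the skeleton in red, endpoints
#' in green and intersections in blue.
#'
#' @param mask Binary mask.
#' @param skel_result Result of [skeletonize()] for the mask.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
qc_overlay <- function(mask, skel_result, path) {
  m <- as_mask(mask)
  H <- nrow(m); W <- ncol(m)
  img <- array(0, c(H, W, 3L))
  for (k in 1:3) img[, , k] <- m * 0.35
  sk <- skel_result$skeleton == 1L
  img[, , 1L][sk] <- 1; img[, , 2L][sk] <- 0; img[, , 3L][sk] <- 0
  paint <- function(xy, ch) {
    if (nrow(xy) == 0L) return()
    rc <- xy_to_rc(xy)
    for (k in 1:3) {
      plane <- img[, , k]
      plane[cbind(rc[, 1L], rc[, 2L])] <- as.numeric(k == ch)
      img[, , k] <<- plane
    }
  }
  paint(skel_result$keypoints$endpoints, 2L)
  paint(skel_result$keypoints$intersections, 3L)
  png::writePNG(img, path)
  invisible(path)
}
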