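# File interchange: multi-page TIFF for movies/stacks (page order
# frame-major, z within frame), CSV tables for ground truth and results,
# and a JSON metadata sidecar carrying calibration, parameters and seed.

#' Write a mask or intensity movie as multi-page TIFF
#'
#' 2D+t arrays (y, x, frame) are written one page per frame; 3D+t arrays
#' (z, y, x, frame) are written frame-major with z varying fastest.
#' Intensities are rescaled to \[0, 1\] for storage; the scale is recorded
#' in the sidecar written by [write_movie_sidecar()].
#'
#' @param movie logical/numeric array, 3D (y, x, frame) or 4D
#'   (z, y, x, frame).
#' @param path output file path (`.tif`).
#' @return invisibly, the intensity range that was mapped to \[0, 1\].
#' @export
write_movie_tiff <- function(movie, path) {
  d <- dim(movie)
  rng <- range(movie)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- list()
  if (length(d) == 3) {
    for (f in seq_len(d[3])) {
      pages[[f]] <- (movie[, , f] - rng[1]) / scale
    }
  } else if (length(d) == 4) {
    i <- 0L
    for (f in seq_len(d[4])) {
      for (z in seq_len(d[1])) {
        i <- i + 1L
        pages[[i]] <- (movie[z, , , f] - rng[1]) / scale
      }
    }
  } else {
    stop("movie must be a 3D (y,x,frame) or 4D (z,y,x,frame) array")
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(rng)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path.
#' @param nz number of z slices per frame (1 for 2D+t).
#' @return array (y, x, frame) when `nz = 1`, else (z, y, x, frame), with
#'   intensities in \[0, 1\].
#' @export
read_movie_tiff <- function(path, nz = 1L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  np <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  if (nz == 1L) {
    out <- array(0, dim = c(ny, nx, np))
    for (f in seq_len(np)) out[, , f] <- pages[[f]]
  } else {
    stopifnot(np %% nz == 0)
    frames <- np %/% nz
    out <- array(0, dim = c(nz, ny, nx, frames))
    i <- 0L
    for (f in seq_len(frames)) {
      for (z in seq_len(nz)) {
        i <- i + 1L
        out[z, , , f] <- pages[[i]]
      }
    }
  }
  out
}

#' Write a generator's ground truth and metadata sidecar
#'
#' Positions/curves go to CSV; parameters, calibration and seed go to a
#' JSON sidecar next to them.
#'
#' @param truth ground-truth list or data frame from a generator.
#' @param meta metadata list from a generator.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return invisibly, the paths written.
#' @export
write_ground_truth <- function(truth, meta, dir, stem = "truth") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  tables <- if (is.data.frame(truth)) list(curve = truth) else
    Filter(is.data.frame, truth)
  for (nm in names(tables)) {
    p <- file.path(dir, sprintf("%s_%s.csv", stem, nm))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  scalars <- if (is.data.frame(truth)) list() else
    Filter(function(x) !is.data.frame(x), truth)
  meta_path <- file.path(dir, sprintf("%s_meta.json", stem))
  jsonlite::write_json(
    list(meta = serialize_meta(meta), truth_scalars = scalars),
    meta_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(paths, meta_path))
}

# Flatten S3 objects (kinetics, motion models) into plain lists for JSON.
serialize_meta <- function(x) {
  if (is.list(x)) lapply(x, serialize_meta) else x
}
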