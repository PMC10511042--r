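# Spheroid-doublet fusion metrics: long-axis doublet length (max Feret of
# the silhouette after protrusion removal) and contact length (silhouette
# width at the waist between the two lobes).

#' Long-axis length of a spheroid doublet
#'
#' Maximum Feret diameter of the silhouette, measured between pixel
#' centers, after a morphological opening that removes thin surface
#' protrusions. The silhouette must be a single connected component (two
#' spheroids in contact).
#'
#' @param mask logical or 0/1 matrix.
#' @param open_radius protrusion-removal opening radius in px; 0
#'   disables.
#' @return length in px.
#' @export
doublet_axis_length <- function(mask, open_radius = 5) {
  mask <- prepare_doublet_mask(mask, open_radius)
  coords <- which(mask, arr.ind = TRUE)
  hull <- coords[grDevices::chull(coords[, 2], coords[, 1]), , drop = FALSE]
  max(stats::dist(hull))
}

prepare_doublet_mask <- function(mask, open_radius) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop("empty doublet mask")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  if (max(lab) > 1L) {
    stop("silhouette has multiple components: spheroids are not in contact")
  }
  if (open_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(open_radius) + 1L,
                                shape = "disc")
    mask <- EBImage::imageData(EBImage::opening(EBImage::Image(mask * 1),
                                                brush)) > 0
    if (!any(mask)) stop("opening removed the whole silhouette")
  }
  fill_holes(mask)
}

#' Contact (neck) length of a spheroid doublet
#'
#' Width of the silhouette at its waist: positions along the long axis
#' are scanned between the centroids of the two lobes and the minimum
#' perpendicular width is returned. A silhouette with no interior waist
#' (fully coalesced, convex) is flagged `fully_fused` and the width at
#' the axis midpoint is reported.
#'
#' @inheritParams doublet_axis_length
#' @param waist_tol relative tolerance: a waist is recognised when the
#'   minimum interior width falls below `1 - waist_tol` times the width
#'   at the lobe centroids.
#' @return list `contact_px`, `fully_fused`, `waist_position`.
#' @export
contact_length <- function(mask, open_radius = 0, waist_tol = 0.05) {
  mask <- prepare_doublet_mask(mask, open_radius)
  coords <- which(mask, arr.ind = TRUE)
  # principal axis from second moments
  cy <- mean(coords[, 1]); cx <- mean(coords[, 2])
  yy <- coords[, 1] - cy; xx <- coords[, 2] - cx
  cov <- cbind(c(mean(xx * xx), mean(xx * yy)),
               c(mean(xx * yy), mean(yy * yy)))
  ev <- eigen(cov, symmetric = TRUE)$vectors[, 1]
  u <- c(ev[1], ev[2]) # (x, y) direction of the long axis
  s <- xx * u[1] + yy * u[2]        # coordinate along the axis
  t <- -xx * u[2] + yy * u[1]       # perpendicular coordinate

  bins <- round(s)
  width_of <- tapply(t, bins, function(v) max(v) - min(v) + 1)
  at <- as.numeric(names(width_of))

  # lobe centroids: mean axial coordinate of each half
  c1 <- mean(s[s < 0]); c2 <- mean(s[s >= 0])
  interior <- at > c1 & at < c2
  if (!any(interior)) {
    return(list(contact_px = unname(width_of[which.min(abs(at))]),
                fully_fused = TRUE, waist_position = 0))
  }
  w_int <- width_of[interior]
  i_min <- which.min(w_int)
  waist <- unname(w_int[i_min])
  ref <- min(width_of[which.min(abs(at - c1))],
             width_of[which.min(abs(at - c2))])
  if (waist >= (1 - waist_tol) * ref) {
    mid <- width_of[which.min(abs(at))]
    return(list(contact_px = unname(mid), fully_fused = TRUE,
                waist_position = 0))
  }
  list(contact_px = waist, fully_fused = FALSE,
       waist_position = unname(at[interior][i_min]))
}

#' Fusion time series of a doublet mask movie
#'
#' Per-frame doublet long-axis length (normalized to the first frame) and
#' contact length.
#'
#' @param movie logical array y * x * frame.
#' @param interval_h frame interval in hours.
#' @param open_radius protrusion-removal radius passed to
#'   [doublet_axis_length()].
#' @return data frame `frame, time_h, doublet_length_px,
#'   doublet_length_norm, contact_length_px, fully_fused`.
#' @export
fusion_timeseries <- function(movie, interval_h = 0.5, open_radius = 0) {
  stopifnot(length(dim(movie)) == 3)
  frames <- dim(movie)[3]
  len <- rep(NA_real_, frames)
  cl <- rep(NA_real_, frames)
  ff <- rep(NA, frames)
  for (f in seq_len(frames)) {
    m <- movie[, , f]
    if (!any(m > 0)) {
      warning(sprintf("frame %d is empty; values set to NA", f))
      next
    }
    len[f] <- doublet_axis_length(m, open_radius = open_radius)
    cc <- contact_length(m, open_radius = open_radius)
    cl[f] <- cc$contact_px
    ff[f] <- cc$fully_fused
  }
  norm <- len / len[which(!is.na(len))[1]]
  data.frame(frame = seq_len(frames), time_h = (seq_len(frames) - 1) * interval_h,
             doublet_length_px = len, doublet_length_norm = norm,
             contact_length_px = cl, fully_fused = ff)
}
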