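# Junction morphometrics: maximum projection, punctum adherens (PA)
# detection with max-Feret measurement, PA density, and tight-junction
# network length by skeletonization.

#' Maximum intensity projection of a z-stack
#'
#' @param stack numeric 3D array (z, y, x) or a 2D matrix (returned
#'   unchanged).
#' @return matrix, per-pixel maximum over z.
#' @export
project_max <- function(stack) {
  if (is.matrix(stack)) return(stack)
  stopifnot(length(dim(stack)) == 3)
  apply(stack, c(2, 3), max)
}

#' Maximum Feret diameter of a pixel object
#'
#' Greatest caliper distance across the object, measured between pixel
#' *corner* points (each pixel contributes its four corners), so a single
#' pixel has Feret `sqrt(2)` rather than 0. Computed on the convex hull,
#' which is exact.
#'
#' @param object logical matrix, or an n x 2 matrix of pixel (y, x)
#'   coordinates.
#' @return Feret diameter in px.
#' @export
max_feret <- function(object) {
  if (is.logical(object) || (is.matrix(object) && ncol(object) != 2)) {
    coords <- which(object > 0, arr.ind = TRUE)
  } else {
    coords <- object
  }
  if (nrow(coords) == 0) stop("empty object")
  corners <- rbind(
    cbind(coords[, 1] - 0.5, coords[, 2] - 0.5),
    cbind(coords[, 1] - 0.5, coords[, 2] + 0.5),
    cbind(coords[, 1] + 0.5, coords[, 2] - 0.5),
    cbind(coords[, 1] + 0.5, coords[, 2] + 0.5)
  )
  hull <- corners[grDevices::chull(corners[, 2], corners[, 1]), , drop = FALSE]
  max(stats::dist(hull))
}

#' Detect punctum adherens spots attached to actin bundles
#'
#' Threshold-segments the spot channel, keeps connected objects within a
#' size range, and retains only objects whose footprint dilated by
#' `attach_radius` overlaps the segmented actin mask (the operational
#' version of "attached to an F-actin bundle"). Each object's max Feret
#' diameter is measured.
#'
#' @param spot_channel,actin_channel registered 2D matrices of equal
#'   shape.
#' @param threshold `"otsu"` or numeric, applied to each channel.
#' @param size_range object area limits in px, `c(min, max)`.
#' @param attach_radius dilation radius in px for the attachment test.
#' @return data frame `id, area_px, feret_px, attached` restricted to
#'   attached objects; attribute `rejected` counts spots that failed the
#'   attachment test.
#' @export
detect_pa <- function(spot_channel, actin_channel, threshold = "otsu",
                      size_range = c(4, 500), attach_radius = 2) {
  if (!all(dim(spot_channel) == dim(actin_channel))) {
    stop("spot and actin channels have different shapes; register them first")
  }
  th_s <- if (identical(threshold, "otsu")) {
    if (any(spot_channel > 0)) otsu_threshold(spot_channel) else Inf
  } else threshold
  th_a <- if (identical(threshold, "otsu")) {
    if (any(actin_channel > 0)) otsu_threshold(actin_channel) else Inf
  } else threshold
  spot_mask <- spot_channel > th_s
  actin_mask <- actin_channel > th_a
  if (!any(spot_mask)) {
    return(structure(data.frame(id = integer(0), area_px = numeric(0),
                                feret_px = numeric(0), attached = logical(0)),
                     rejected = 0L))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(spot_mask * 1)))
  n_obj <- max(lab)
  brush_size <- 2L * as.integer(attach_radius) + 1L
  brush <- EBImage::makeBrush(brush_size, shape = "disc")
  rows <- vector("list", n_obj)
  rejected <- 0L
  for (i in seq_len(n_obj)) {
    obj <- lab == i
    area <- sum(obj)
    if (area < size_range[1] || area > size_range[2]) next
    dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(obj * 1), brush)) > 0
    attached <- any(dil & actin_mask)
    if (!attached) {
      rejected <- rejected + 1L
      next
    }
    rows[[i]] <- data.frame(id = i, area_px = area,
                            feret_px = max_feret(obj), attached = TRUE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), area_px = numeric(0), feret_px = numeric(0),
               attached = logical(0))
  rownames(out) <- NULL
  structure(out, rejected = rejected)
}

#' PA count density
#'
#' @param objects data frame from [detect_pa()].
#' @param field_area_px2 field area in px^2.
#' @return count per px^2.
#' @export
pa_density <- function(objects, field_area_px2) {
  stopifnot(field_area_px2 > 0)
  nrow(objects) / field_area_px2
}

# Zhang-Suen thinning of a binary matrix to a 1-px-wide skeleton.
# Vectorised over the image: neighbor planes via padded shifts.
skeletonize <- function(mask) {
  img <- as.matrix(mask) > 0
  nr <- nrow(img); nc <- ncol(img)
  shift <- function(m, dy, dx) {
    out <- matrix(FALSE, nr, nc)
    ys <- max(1, 1 - dy):min(nr, nr - dy)
    xs <- max(1, 1 - dx):min(nc, nc - dx)
    out[ys, xs] <- m[ys + dy, xs + dx]
    out
  }
  # neighbors clockwise from north: P2..P9
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      P <- lapply(offs, function(o) shift(img, o[1], o[2]))
      B <- Reduce(`+`, P)
      A <- matrix(0L, nr, nc)
      for (k in 1:8) {
        k2 <- if (k == 8) 1L else k + 1L
        A <- A + (!P[[k]] & P[[k2]])
      }
      if (step == 0) {
        cond <- (!P[[1]] | !P[[3]] | !P[[5]]) & (!P[[3]] | !P[[5]] | !P[[7]])
      } else {
        cond <- (!P[[1]] | !P[[3]] | !P[[7]]) & (!P[[1]] | !P[[5]] | !P[[7]])
      }
      del <- img & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        img[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

# Length of a 1-px skeleton. pixel_count mirrors the plain "count the
# skeleton pixels" length proxy; euclidean_px decomposes the skeleton
# into branches and applies the chain-code length estimator
# sqrt(Nd^2 + (Nd + Na)^2) per branch (exact for straight digital lines),
# plus the individual weights of branch-to-junction links.
skeleton_length <- function(skel) {
  coords <- which(skel, arr.ind = TRUE)
  n <- nrow(coords)
  if (n == 0) return(list(pixel_count = 0L, euclidean_px = 0))
  idmat <- matrix(0L, nrow(skel), ncol(skel))
  idmat[coords] <- seq_len(n)
  nr <- nrow(skel); nc <- ncol(skel)
  neighbor_id <- function(dy, dx) {
    yy <- coords[, 1] + dy; xx <- coords[, 2] + dx
    ok <- yy >= 1 & yy <= nr & xx >= 1 & xx <= nc
    out <- integer(n)
    out[ok] <- idmat[cbind(yy[ok], xx[ok])]
    out
  }
  # axial edges (i < j by construction of positive shifts)
  e_s <- neighbor_id(1, 0)   # south
  e_e <- neighbor_id(0, 1)   # east
  # diagonal edges kept only when not short-cutting an axial corner
  e_se <- neighbor_id(1, 1)
  e_sw <- neighbor_id(1, -1)
  se_ok <- e_se > 0 & !(e_s > 0 | e_e > 0)
  w_s <- neighbor_id(0, -1) # west neighbor present?
  sw_ok <- e_sw > 0 & !(e_s > 0 | w_s > 0)

  from <- c(which(e_s > 0), which(e_e > 0), which(se_ok), which(sw_ok))
  to <- c(e_s[e_s > 0], e_e[e_e > 0], e_se[se_ok], e_sw[sw_ok])
  w <- c(rep(1, sum(e_s > 0) + sum(e_e > 0)),
         rep(sqrt(2), sum(se_ok) + sum(sw_ok)))
  diag_edge <- c(rep(FALSE, sum(e_s > 0) + sum(e_e > 0)),
                 rep(TRUE, sum(se_ok) + sum(sw_ok)))

  deg <- tabulate(c(from, to), nbins = n)
  junction <- deg >= 3L

  # union-find over chain (non-junction) pixels
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  chain_edge <- !junction[from] & !junction[to]
  for (k in which(chain_edge)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[a] <- b
  }
  total <- 0
  if (any(chain_edge)) {
    comp <- vapply(from[chain_edge], find, 0L)
    na_per <- tapply(!diag_edge[chain_edge], comp, sum)
    nd_per <- tapply(diag_edge[chain_edge], comp, sum)
    total <- sum(sqrt(nd_per^2 + (nd_per + na_per)^2))
  }
  # links touching junction pixels contribute their own weight
  jl <- junction[from] | junction[to]
  total <- total + sum(w[jl])
  list(pixel_count = n, euclidean_px = total)
}

#' Tight-junction network length
#'
#' Enhances linear structures in the ZO-1 channel with a white top-hat
#' (disc structuring element at the line scale), segments the TJ region by
#' thresholding, skeletonizes it to single-pixel width, and reports the
#' skeleton pixel count as the total TJ length, normalized by cell number
#' (from nuclei blob segmentation) and by field area. A chain-code
#' corrected length (`length_euclidean_px`, counting diagonal steps as
#' sqrt(2)) is also reported since the raw pixel count underestimates
#' diagonal runs.
#'
#' @param zo1_projection 2D matrix (TJ marker, max-projected).
#' @param nuclei_projection 2D matrix of the same shape, or `NULL` to
#'   skip cell counting.
#' @param tophat_radius structuring-element radius in px (somewhat larger
#'   than the TJ line half-width).
#' @param threshold `"otsu"` or numeric, on the enhanced image.
#' @param nucleus_min_area minimum blob area for a counted nucleus.
#' @return list `total_length_px` (pixel count), `length_euclidean_px`,
#'   `cell_count`, `field_area_px2`, `per_cell`, `per_area`, `skeleton`.
#' @export
tj_length <- function(zo1_projection, nuclei_projection = NULL,
                      tophat_radius = 5, threshold = "otsu",
                      nucleus_min_area = 9) {
  img <- as.matrix(zo1_projection)
  if (!is.null(nuclei_projection) &&
      !all(dim(img) == dim(as.matrix(nuclei_projection)))) {
    stop("channels have different shapes; register them first")
  }
  brush <- EBImage::makeBrush(2L * as.integer(tophat_radius) + 1L,
                              shape = "disc")
  enhanced <- EBImage::imageData(EBImage::whiteTopHat(EBImage::Image(img),
                                                      brush))
  th <- if (identical(threshold, "otsu")) {
    if (any(enhanced > 0)) otsu_threshold(enhanced[enhanced > 0]) / 2
    else Inf
  } else threshold
  tj_mask <- enhanced > th
  skel <- skeletonize(tj_mask)
  len <- skeleton_length(skel)

  cell_count <- NA_integer_
  if (!is.null(nuclei_projection)) {
    nuc <- gaussian_blur2d(as.matrix(nuclei_projection), 1)
    nmask <- nuc > otsu_threshold(nuc)
    nlab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(nmask * 1)))
    if (max(nlab) > 0) {
      areas <- tabulate(nlab[nlab > 0])
      cell_count <- sum(areas >= nucleus_min_area)
    } else {
      cell_count <- 0L
    }
  }
  field_area <- prod(dim(img))
  per_cell <- if (!is.na(cell_count) && cell_count > 0) {
    len$pixel_count / cell_count
  } else {
    if (!is.na(cell_count)) warning("zero nuclei counted; per_cell undefined")
    NA_real_
  }
  list(total_length_px = len$pixel_count,
       length_euclidean_px = len$euclidean_px,
       cell_count = cell_count,
       field_area_px2 = field_area,
       per_cell = per_cell,
       per_area = len$pixel_count / field_area,
       skeleton = skel)
}
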