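# Synthetic junction images: a polygonal (hexagonal) tight-junction
# tessellation with per-cell nuclei, actin bundles along the cell borders,
# and elongated punctum-adherens spots attached to them — with exact
# ground-truth edge lengths, PA lengths and cell count.

# Pixels within distance w/2 of segment (y1,x1)-(y2,x2), painted into img.
paint_segment <- function(img, y1, x1, y2, x2, width, value = 1) {
  half <- width / 2
  ylo <- max(1L, floor(min(y1, y2) - half - 1))
  yhi <- min(nrow(img), ceiling(max(y1, y2) + half + 1))
  xlo <- max(1L, floor(min(x1, x2) - half - 1))
  xhi <- min(ncol(img), ceiling(max(x1, x2) + half + 1))
  if (ylo > yhi || xlo > xhi) return(img)
  ys <- ylo:yhi; xs <- xlo:xhi
  Y <- outer(ys, rep(1, length(xs)))
  X <- outer(rep(1, length(ys)), xs)
  vy <- y2 - y1; vx <- x2 - x1
  len2 <- vy^2 + vx^2
  t <- if (len2 == 0) 0 else pmin(pmax(((Y - y1) * vy + (X - x1) * vx) / len2, 0), 1)
  d2 <- (Y - (y1 + t * vy))^2 + (X - (x1 + t * vx))^2
  sub <- img[ys, xs]
  sub[d2 <= half^2] <- value
  img[ys, xs] <- sub
  img
}

# Hexagonal tessellation (pointy-top, side s) clipped to a square field:
# returns unique edges and the centers of fully interior cells.
hex_tessellation <- function(side, n_cells_target, margin = 6) {
  s <- side
  dx <- sqrt(3) * s
  dy <- 1.5 * s
  ncols <- ceiling(sqrt(n_cells_target)) + 1L
  nrows <- ceiling(n_cells_target / ncols) + 1L
  size <- ceiling(max(ncols * dx, nrows * dy) + 2 * margin + 2 * s)
  centers <- list()
  for (i in seq_len(nrows + 2L)) {
    for (j in seq_len(ncols + 2L)) {
      cy <- margin + s + (i - 1) * dy
      cx <- margin + s + (j - 1) * dx + (i %% 2) * dx / 2
      centers[[length(centers) + 1L]] <- c(cy, cx)
    }
  }
  centers <- do.call(rbind, centers)
  ang <- pi / 2 + (0:5) * pi / 3
  vy <- s * sin(ang); vx <- s * cos(ang)
  keep <- apply(centers, 1, function(cc) {
    all(cc[1] + vy >= margin & cc[1] + vy <= size - margin &
          cc[2] + vx >= margin & cc[2] + vx <= size - margin)
  })
  centers <- centers[keep, , drop = FALSE]
  if (nrow(centers) < n_cells_target) {
    stop("internal: hex grid too small for requested cell count")
  }
  centers <- centers[seq_len(n_cells_target), , drop = FALSE]
  edges <- list()
  seen <- character(0)
  for (i in seq_len(nrow(centers))) {
    py <- centers[i, 1] + vy; px <- centers[i, 2] + vx
    for (k in 1:6) {
      k2 <- if (k == 6) 1L else k + 1L
      a <- c(py[k], px[k]); b <- c(py[k2], px[k2])
      key <- paste(round(c(pmin(a, b), pmax(a, b)), 3), collapse = "_")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        edges[[length(edges) + 1L]] <- c(a, b)
      }
    }
  }
  edges <- do.call(rbind, edges)
  colnames(edges) <- c("y1", "x1", "y2", "x2")
  list(centers = centers, edges = edges, size = size, side = s)
}

#' Generate a synthetic junction image with ground truth
#'
#' Renders a multichannel 2D image of an epithelial sheet: a tight-junction
#' network (thin lines of a hexagonal tessellation), actin bundles
#' coincident with (and wider than) the borders, elongated
#' punctum-adherens spots centered on border segments, and one nuclear
#' blob per cell. Ground truth stores the exact tessellation edge length,
#' the programmed PA max-Feret lengths and the cell count.
#'
#' @param n_cells number of cells (>= 2). With `layout = "two_cell"` the
#'   image holds a single straight shared border.
#' @param pa_spec list with `n` (spot count) and `length_px` (a single
#'   fixed length or a function(n) returning lengths).
#' @param side hexagon side length in px.
#' @param line_width TJ line width in px (~2 px, as in confocal ZO-1).
#' @param actin_width actin bundle width in px.
#' @param pa_width PA spot minor width in px.
#' @param seed integer seed.
#' @param layout `"hex"` (default) or `"two_cell"`.
#' @param border_length_px shared border length for `layout = "two_cell"`.
#' @return list with `channels` (list of matrices `tj`, `actin`, `spots`,
#'   `nuclei`), `truth` (list `tj_length_px`, `edges`, `pa_lengths_px`,
#'   `n_cells`, `field_area_px2`), and `meta`.
#' @export
generate_junction_image <- function(n_cells, pa_spec = list(n = 10, length_px = 10),
                                    side = 20, line_width = 2,
                                    actin_width = 4, pa_width = 2,
                                    seed = 1L, layout = c("hex", "two_cell"),
                                    border_length_px = 40) {
  layout <- match.arg(layout)
  if (n_cells < 2) stop("n_cells must be >= 2")
  set.seed(as.integer(seed))

  if (layout == "two_cell") {
    size <- ceiling(border_length_px + 40)
    mid <- size / 2
    edges <- matrix(c(mid - border_length_px / 2, mid,
                      mid + border_length_px / 2, mid),
                    1, 4, dimnames = list(NULL, c("y1", "x1", "y2", "x2")))
    centers <- rbind(c(mid, mid - 15), c(mid, mid + 15))
  } else {
    tess <- hex_tessellation(side, n_cells)
    edges <- tess$edges
    centers <- tess$centers
    size <- tess$size
  }

  edge_len <- sqrt((edges[, "y2"] - edges[, "y1"])^2 +
                     (edges[, "x2"] - edges[, "x1"])^2)
  tj <- matrix(0, size, size)
  actin <- matrix(0, size, size)
  for (e in seq_len(nrow(edges))) {
    tj <- paint_segment(tj, edges[e, 1], edges[e, 2], edges[e, 3], edges[e, 4],
                        line_width)
    actin <- paint_segment(actin, edges[e, 1], edges[e, 2], edges[e, 3],
                           edges[e, 4], actin_width)
  }

  n_pa <- pa_spec$n
  pa_len <- if (is.function(pa_spec$length_px)) pa_spec$length_px(n_pa)
            else rep(pa_spec$length_px, n_pa)
  spots <- matrix(0, size, size)
  pa_placed <- numeric(0)
  if (n_pa > 0) {
    e_idx <- sample(nrow(edges), n_pa, replace = nrow(edges) < n_pa)
    tpos <- stats::runif(n_pa, 0.3, 0.7)
    for (i in seq_len(n_pa)) {
      e <- edges[e_idx[i], ]
      uy <- (e["y2"] - e["y1"]) / edge_len[e_idx[i]]
      ux <- (e["x2"] - e["x1"]) / edge_len[e_idx[i]]
      cy <- e["y1"] + tpos[i] * (e["y2"] - e["y1"])
      cx <- e["x1"] + tpos[i] * (e["x2"] - e["x1"])
      # stadium shape: segment of length L - w with round caps -> max
      # caliper exactly L
      half <- (pa_len[i] - pa_width) / 2
      spots <- paint_segment(spots, cy - half * uy, cx - half * ux,
                             cy + half * uy, cx + half * ux, pa_width)
      pa_placed <- c(pa_placed, pa_len[i])
    }
  }

  nuclei <- matrix(0, size, size)
  for (i in seq_len(nrow(centers))) {
    nuclei <- nuclei + exp(-((outer(seq_len(size), rep(1, size)) - centers[i, 1])^2 +
                               (outer(rep(1, size), seq_len(size)) - centers[i, 2])^2) /
                             (2 * 3^2))
  }

  list(
    channels = list(tj = tj, actin = actin, spots = spots, nuclei = nuclei),
    truth = list(tj_length_px = sum(edge_len), edges = edges,
                 pa_lengths_px = pa_placed,
                 n_cells = if (layout == "two_cell") 2L else n_cells,
                 field_area_px2 = size^2),
    meta = list(generator = "junctions", layout = layout, side = side,
                line_width = line_width, actin_width = actin_width,
                pa_width = pa_width, seed = as.integer(seed),
                img_size = size)
  )
}
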