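# Synthetic rounding movies: an elongated cell mass (rounded rectangle)
# that relaxes toward a disc following a programmed circularity curve with
# latent / rising / static phases and optional discrete fusion jumps.

#' Programmed rounding kinetics
#'
#' Describes the circularity-versus-time curve a synthetic rounding movie
#' follows: flat at `c0` until the end of the latent phase, a smooth
#' monotone rise to `c_inf` during the rising phase, flat thereafter
#' (static phase). Discrete fusion events add instantaneous upward jumps.
#'
#' @param c_inf plateau circularity in (0, 1].
#' @param t_latent end of the latent phase in hours.
#' @param t_static start of the static phase in hours; must exceed
#'   `t_latent`.
#' @param c0 initial circularity. Usually left `NULL`: the movie generator
#'   fills it in with the analytic circularity of the initial silhouette.
#' @param jumps optional data frame with columns `time_h` and `delta`
#'   (positive circularity increments applied instantaneously).
#' @return an object of class `rounding_kinetics`.
#' @seealso [programmed_circularity()], [generate_rounding_movie()]
#' @export
rounding_kinetics <- function(c_inf, t_latent, t_static, c0 = NULL,
                              jumps = NULL) {
  stopifnot(c_inf > 0, c_inf <= 1, t_latent < t_static)
  if (!is.null(c0)) stopifnot(c0 > 0, c0 <= c_inf)
  if (is.null(jumps)) {
    jumps <- data.frame(time_h = numeric(0), delta = numeric(0))
  }
  stopifnot(all(c("time_h", "delta") %in% names(jumps)),
            all(jumps$delta > 0))
  structure(
    list(c0 = c0, c_inf = c_inf, t_latent = t_latent, t_static = t_static,
         jumps = jumps[order(jumps$time_h), , drop = FALSE]),
    class = "rounding_kinetics"
  )
}

# Smoothstep: C1 monotone ramp from 0 at u=0 to 1 at u=1.
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Evaluate a programmed circularity curve
#'
#' @param kinetics a [rounding_kinetics()] object with `c0` resolved.
#' @param t vector of times in hours.
#' @param cap upper clamp applied after jumps (a silhouette cannot exceed
#'   circularity 1; the renderer needs strictly < 1).
#' @return circularity values, monotone non-decreasing in `t`.
#' @export
programmed_circularity <- function(kinetics, t, cap = 0.995) {
  stopifnot(inherits(kinetics, "rounding_kinetics"))
  c0 <- kinetics$c0
  if (is.null(c0)) stop("kinetics$c0 is unresolved; set it or use the movie generator")
  u <- (t - kinetics$t_latent) / (kinetics$t_static - kinetics$t_latent)
  v <- c0 + (kinetics$c_inf - c0) * smoothstep(u)
  if (nrow(kinetics$jumps) > 0) {
    for (i in seq_len(nrow(kinetics$jumps))) {
      v <- v + ifelse(t >= kinetics$jumps$time_h[i], kinetics$jumps$delta[i], 0)
    }
  }
  pmin(v, cap)
}

#' Analytic geometry of a rounded rectangle
#'
#' Area, perimeter and circularity of a rectangle of aspect ratio
#' `aspect` (width/height, >= 1) whose corners are circular arcs of radius
#' `corner_frac` times the half-height. `corner_frac = 1` with
#' `aspect = 1` degenerates to a disc.
#'
#' @param aspect width-to-height ratio, >= 1.
#' @param corner_frac corner radius as a fraction of the half-height,
#'   in (0, 1].
#' @param half_height half-height in pixels (scale; circularity is
#'   scale-free).
#' @return list with `area`, `perimeter`, `circularity`.
#' @export
rounded_rect_metrics <- function(aspect, corner_frac, half_height = 1) {
  stopifnot(aspect >= 1, corner_frac > 0, corner_frac <= 1, half_height > 0)
  h <- half_height
  w <- aspect * h
  rho <- corner_frac * h
  area <- 4 * w * h - (4 - pi) * rho^2
  perim <- 4 * (w + h) - (8 - 2 * pi) * rho
  list(area = area, perimeter = perim,
       circularity = 4 * pi * area / perim^2)
}

# Shape-path parameterisation: s in [0,1] moves the silhouette from the
# initial rounded rectangle (aspect0, corner_frac0) to a disc (1, 1).
# Circularity is strictly increasing along the path, so a target
# circularity is inverted with uniroot.
shape_path <- function(s, aspect0, corner_frac0) {
  list(aspect = aspect0 + s * (1 - aspect0),
       corner_frac = corner_frac0 + s * (1 - corner_frac0))
}

solve_shape_for_circularity <- function(c_target, aspect0, corner_frac0) {
  f <- function(s) {
    p <- shape_path(s, aspect0, corner_frac0)
    rounded_rect_metrics(p$aspect, p$corner_frac)$circularity - c_target
  }
  if (f(0) >= 0) return(0)   # already at or above the target
  if (f(1) <= 0) return(1)
  stats::uniroot(f, c(0, 1), tol = 1e-10)$root
}

# Rasterise a rounded rectangle centred in an img_size x img_size frame.
# Membership: distance from the pixel centre to the inner rectangle <= rho.
render_rounded_rect <- function(img_size, half_width, half_height, rho) {
  ctr <- (img_size + 1) / 2
  x <- abs(seq_len(img_size) - ctr)
  y <- abs(seq_len(img_size) - ctr)
  dx <- pmax(outer(rep(1, img_size), x) - (half_width - rho), 0)
  dy <- pmax(outer(y, rep(1, img_size)) - (half_height - rho), 0)
  dx^2 + dy^2 <= rho^2
}

#' Generate a synthetic rounding movie with ground truth
#'
#' Renders a 2D+t binary mask movie of an elongated cell mass whose
#' silhouette is a constant-area rounded rectangle morphing into a disc so
#' that its analytic circularity follows the programmed kinetics curve.
#' Fusion jumps appear as instantaneous increases of the target
#' circularity, mimicking two sub-masses merging into a rounder single
#' component.
#'
#' @param aspect_ratio initial silhouette aspect ratio, >= 1.
#' @param kinetics a [rounding_kinetics()] object. If its `c0` is `NULL`
#'   it is set to the analytic circularity of the initial silhouette.
#' @param frames number of frames, >= 2.
#' @param interval_h frame interval in hours.
#' @param seed integer seed recorded in the metadata (rendering is
#'   deterministic; the seed keeps the calling convention uniform across
#'   generators).
#' @param half_height_px initial silhouette half-height in pixels.
#' @param corner_frac initial corner radius as a fraction of the
#'   half-height.
#' @return list with `movie` (logical array y * x * frame), `truth` (data
#'   frame `frame`, `time_h`, `circularity`), and `meta` (parameters,
#'   calibration).
#' @export
generate_rounding_movie <- function(aspect_ratio, kinetics, frames,
                                    interval_h = 1, seed = 1L,
                                    half_height_px = 30,
                                    corner_frac = 0.4) {
  if (aspect_ratio < 1) stop("aspect_ratio must be >= 1")
  if (frames < 2) stop("frames must be >= 2")
  stopifnot(inherits(kinetics, "rounding_kinetics"))

  m0 <- rounded_rect_metrics(aspect_ratio, corner_frac, half_height_px)
  if (is.null(kinetics$c0)) kinetics$c0 <- m0$circularity
  if (kinetics$c0 > kinetics$c_inf + 1e-9) {
    stop("initial circularity exceeds c_inf; increase c_inf or aspect_ratio")
  }
  area0 <- m0$area
  r_final <- sqrt(area0 / pi)
  img_size <- 2L * ceiling(max(aspect_ratio * half_height_px, r_final)) + 24L

  times <- (seq_len(frames) - 1) * interval_h
  c_prog <- programmed_circularity(kinetics, times)

  movie <- array(FALSE, dim = c(img_size, img_size, frames))
  for (f in seq_len(frames)) {
    s <- solve_shape_for_circularity(c_prog[f], aspect_ratio, corner_frac)
    p <- shape_path(s, aspect_ratio, corner_frac)
    unit <- rounded_rect_metrics(p$aspect, p$corner_frac)
    scale <- sqrt(area0 / unit$area)
    movie[, , f] <- render_rounded_rect(img_size,
                                        half_width = p$aspect * scale,
                                        half_height = scale,
                                        rho = p$corner_frac * scale)
  }

  list(
    movie = movie,
    truth = data.frame(frame = seq_len(frames), time_h = times,
                       circularity = c_prog),
    meta = list(generator = "rounding", aspect_ratio = aspect_ratio,
                kinetics = kinetics, interval_h = interval_h,
                half_height_px = half_height_px, corner_frac = corner_frac,
                img_size = img_size, seed = as.integer(seed))
  )
}
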