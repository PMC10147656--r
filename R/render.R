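# Transmission-contrast bead renderer: a dark disk on a bright background
# whose edge softens with axial defocus. Not a physical PSF model -- just
# enough optics (radial edge profile + defocus blur) for tracker fixtures.

render_frame <- function(nx, ny, x_px, y_px, radius_px, sigma_px,
                         background, depth) {
  cx <- matrix(rep(0:(nx - 1L), each = ny), ny, nx)
  cy <- matrix(rep(0:(ny - 1L), nx), ny, nx)
  r <- sqrt((cx - x_px)^2 + (cy - y_px)^2)
  background - depth * stats::pnorm((radius_px - r) / sigma_px)
}

#' Render a transmission video of a diffusing bead
#'
#' Draws the probe as a dark disk of its physical diameter on a bright
#' background (brightfield transmission contrast), with an edge that blurs
#' as the bead moves away from the focal plane. Intended as the ground
#' truth fixture generator for the tracking stage: every frame's true
#' sub-pixel position is stored in the attributes.
#'
#' @param traj A [trajectory()] with at least an x axis; a missing y or z
#'   axis is rendered as 0.
#' @param pixel_size Pixel pitch in metres per pixel.
#' @param image_shape `c(ny, nx)` frame shape in pixels.
#' @param focus_z Axial position of the focal plane (m).
#' @param background,depth Background level and bead contrast depth in
#'   camera counts (16-bit range).
#' @param blur_sigma0 Edge softness at focus (pixels).
#' @param blur_per_metre Additional edge softness per metre of defocus
#'   (pixels/m); `1.5e6` is 1.5 px per micrometre.
#' @param noise_sigma Gaussian read-noise standard deviation (counts);
#'   the contrast-to-noise ratio is `depth / noise_sigma`.
#' @param poisson If `TRUE`, add Poisson shot noise on top.
#' @param seed Optional seed for the noise.
#' @return A numeric array `[ny, nx, n_frames]` of class `bead_video`,
#'   with attributes `pixel_size`, `frame_rate`, `true_x_px`, `true_y_px`,
#'   `true_z_m`.
#' @export
render_bead_video <- function(traj, pixel_size, image_shape = c(48L, 48L),
                              focus_z = 0, background = 1000, depth = 600,
                              blur_sigma0 = 1.2, blur_per_metre = 1.5e6,
                              noise_sigma = 0, poisson = FALSE, seed = NULL) {
  stopifnot(inherits(traj, "trajectory"), pixel_size > 0)
  ny <- image_shape[1L]; nx <- image_shape[2L]
  n <- length(traj$t)
  p <- traj$positions
  gx <- if ("x" %in% colnames(p)) p[, "x"] else numeric(n)
  gy <- if ("y" %in% colnames(p)) p[, "y"] else numeric(n)
  gz <- if ("z" %in% colnames(p)) p[, "z"] else numeric(n)
  x_px <- (nx - 1) / 2 + gx / pixel_size
  y_px <- (ny - 1) / 2 + gy / pixel_size
  r_px <- traj$context$radius_a / pixel_size
  bad <- which(x_px - r_px < 0 | x_px + r_px > nx - 1 |
               y_px - r_px < 0 | y_px + r_px > ny - 1)
  if (length(bad))
    stop(sprintf("bead leaves the field of view at frame %d", bad[1L]))
  stack <- array(0, dim = c(ny, nx, n))
  for (i in seq_len(n)) {
    sigma <- blur_sigma0 + blur_per_metre * abs(gz[i] - focus_z)
    stack[, , i] <- render_frame(nx, ny, x_px[i], y_px[i], r_px, sigma,
                                 background, depth)
  }
  if (noise_sigma > 0 || poisson) {
    stack <- with_seed(seed, {
      if (poisson) stack[] <- stats::rpois(length(stack), lambda = pmax(stack, 0))
      if (noise_sigma > 0)
        stack <- stack + stats::rnorm(length(stack), 0, noise_sigma)
      stack
    })
  }
  stack <- round(pmin(pmax(stack, 0), 65535))
  structure(stack, class = "bead_video",
            pixel_size = pixel_size, frame_rate = traj$frame_rate,
            true_x_px = x_px, true_y_px = y_px, true_z_m = gz,
            layout = "fullframe")
}

#' Render a nine-plane multiplane video
#'
#' Emulates the image formed by a pair of quadratically distorted
#' diffraction gratings: each camera frame is a 3x3 tile of sub-images,
#' each conjugate to an object plane offset by an integer multiple of
#' `plane_spacing`. Tile order is row-major with plane label
#' `p = 3*(row-1) + (col-1) - 4`, so labels run -4..+4 and plane 0 is the
#' central tile. The sub-image of plane `p` shows the bead defocused by
#' `z_bead - p * plane_spacing`.
#'
#' @inheritParams render_bead_video
#' @param sub_shape `c(ny, nx)` shape of each of the nine sub-images.
#' @param plane_spacing Axial spacing between adjacent planes (m), e.g.
#'   `0.79e-6`; nine planes span `9 * plane_spacing`.
#' @param n_planes Must be 9 (3x3 tiling); other values are unsupported.
#' @return A numeric array `[3*ny, 3*nx, n_frames]` of class
#'   `bead_video` with attribute `layout = "multiplane3x3"` and
#'   `plane_spacing`.
#' @export
render_multiplane_video <- function(traj, pixel_size, sub_shape = c(48L, 48L),
                                    plane_spacing = 0.79e-6, n_planes = 9L,
                                    focus_z = 0, background = 1000,
                                    depth = 600, blur_sigma0 = 1.2,
                                    blur_per_metre = 1.5e6, noise_sigma = 0,
                                    poisson = FALSE, seed = NULL) {
  if (n_planes != 9L)
    stop("only the 3x3 nine-plane layout is supported")
  if (plane_spacing <= 0) stop("'plane_spacing' must be > 0")
  stopifnot(inherits(traj, "trajectory"), pixel_size > 0)
  ny <- sub_shape[1L]; nx <- sub_shape[2L]
  n <- length(traj$t)
  p <- traj$positions
  gx <- if ("x" %in% colnames(p)) p[, "x"] else numeric(n)
  gy <- if ("y" %in% colnames(p)) p[, "y"] else numeric(n)
  gz <- if ("z" %in% colnames(p)) p[, "z"] else numeric(n)
  x_px <- (nx - 1) / 2 + gx / pixel_size
  y_px <- (ny - 1) / 2 + gy / pixel_size
  r_px <- traj$context$radius_a / pixel_size
  bad <- which(x_px - r_px < 0 | x_px + r_px > nx - 1 |
               y_px - r_px < 0 | y_px + r_px > ny - 1)
  if (length(bad))
    stop(sprintf("bead leaves the sub-image field of view at frame %d",
                 bad[1L]))
  stack <- array(0, dim = c(3L * ny, 3L * nx, n))
  for (i in seq_len(n)) {
    for (row in 1:3) for (col in 1:3) {
      plane <- 3L * (row - 1L) + (col - 1L) - 4L
      defocus <- (gz[i] - focus_z) - plane * plane_spacing
      sigma <- blur_sigma0 + blur_per_metre * abs(defocus)
      stack[(row - 1L) * ny + seq_len(ny),
            (col - 1L) * nx + seq_len(nx), i] <-
        render_frame(nx, ny, x_px[i], y_px[i], r_px, sigma,
                     background, depth)
    }
  }
  if (noise_sigma > 0 || poisson) {
    stack <- with_seed(seed, {
      if (poisson) stack[] <- stats::rpois(length(stack), lambda = pmax(stack, 0))
      if (noise_sigma > 0)
        stack <- stack + stats::rnorm(length(stack), 0, noise_sigma)
      stack
    })
  }
  stack <- round(pmin(pmax(stack, 0), 65535))
  structure(stack, class = "bead_video",
            pixel_size = pixel_size, frame_rate = traj$frame_rate,
            true_x_px = x_px, true_y_px = y_px, true_z_m = gz,
            layout = "multiplane3x3", plane_spacing = plane_spacing)
}
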