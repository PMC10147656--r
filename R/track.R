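# Tracking stage: bead localization in transmission frames (multilevel
# Otsu centre of mass), sharpness-based axial localization against a
# per-bead calibration, and whole-video tracking.

#' Split a 3x3-tiled multiplane frame into its nine sub-images
#'
#' @param raw_frame Numeric matrix whose dimensions are divisible by 3.
#' @param plane_spacing Axial spacing between adjacent planes (m).
#' @param layout Tile order; only `"row_major"` is supported, with plane
#'   label `p = 3*(row-1) + (col-1) - 4` (labels -4..+4, plane 0 central).
#' @return A `multiplane_frame`: list of 9 sub-images, `plane_labels`
#'   (-4..4) and `plane_spacing_dz`.
#' @export
split_multiplane <- function(raw_frame, plane_spacing = NA_real_,
                             layout = "row_major") {
  if (layout != "row_major") stop("unsupported tile layout: ", layout)
  d <- dim(raw_frame)
  if (is.null(d) || length(d) != 2L)
    stop("'raw_frame' must be a 2D matrix")
  if (d[1L] %% 3L != 0L || d[2L] %% 3L != 0L)
    stop(sprintf("frame shape %dx%d is not divisible by 3 in both axes",
                 d[1L], d[2L]))
  ny <- d[1L] %/% 3L; nx <- d[2L] %/% 3L
  subs <- vector("list", 9L)
  labels <- integer(9L)
  k <- 0L
  for (row in 1:3) for (col in 1:3) {
    k <- k + 1L
    labels[k] <- 3L * (row - 1L) + (col - 1L) - 4L
    subs[[k]] <- raw_frame[(row - 1L) * ny + seq_len(ny),
                           (col - 1L) * nx + seq_len(nx), drop = FALSE]
  }
  structure(list(sub_images = subs, plane_labels = labels,
                 plane_spacing_dz = plane_spacing),
            class = "multiplane_frame")
}

#' Reassemble a multiplane frame into the original tiled image
#' @param frame A `multiplane_frame` from [split_multiplane()].
#' @export
reassemble_multiplane <- function(frame) {
  stopifnot(inherits(frame, "multiplane_frame"))
  d <- dim(frame$sub_images[[1L]])
  out <- matrix(0, 3L * d[1L], 3L * d[2L])
  k <- 0L
  for (row in 1:3) for (col in 1:3) {
    k <- k + 1L
    out[(row - 1L) * d[1L] + seq_len(d[1L]),
        (col - 1L) * d[2L] + seq_len(d[2L])] <- frame$sub_images[[k]]
  }
  out
}

#' Two-level (three-class) Otsu thresholds
#'
#' Exhaustive search over a 256-bin histogram for the threshold pair
#' maximizing the between-class variance, the multilevel extension of
#' Otsu's method.
#'
#' @param image Numeric matrix or vector of intensities.
#' @return Numeric length-2 vector of thresholds on the intensity scale.
#' @export
otsu_thresholds <- function(image) {
  v <- as.numeric(image)
  rng <- range(v)
  if (diff(rng) <= 0) stop("image has no intensity contrast")
  nb <- 256L
  b <- pmin(floor((v - rng[1L]) / diff(rng) * nb), nb - 1L)
  h <- tabulate(b + 1L, nbins = nb) / length(v)
  mids <- rng[1L] + (seq_len(nb) - 0.5) / nb * diff(rng)
  W <- cumsum(h); M <- cumsum(h * mids)
  Wt <- W[nb]; Mt <- M[nb]
  best <- -Inf; bt <- c(1L, 2L)
  for (t1 in 1:(nb - 2L)) {
    w1 <- W[t1]; m1 <- M[t1]
    t2 <- (t1 + 1L):(nb - 1L)
    w2 <- W[t2] - w1; m2 <- M[t2] - m1
    w3 <- Wt - W[t2]; m3 <- Mt - M[t2]
    s <- ifelse(w1 > 0, m1^2 / w1, 0) + ifelse(w2 > 0, m2^2 / w2, 0) +
      ifelse(w3 > 0, m3^2 / w3, 0)
    i <- which.max(s)
    if (s[i] > best) { best <- s[i]; bt <- c(t1, t2[i]) }
  }
  rng[1L] + bt / nb * diff(rng)
}

# 3x3 box filter with edge replication (symmetric kernel: no centroid
# bias, exact whole-pixel shift equivariance away from the border).
box3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- m[c(1L, seq_len(nr), nr), c(1L, seq_len(nc), nc)]
  (p[1:nr, 1:nc] + p[1:nr, 2:(nc + 1L)] + p[1:nr, 3:(nc + 2L)] +
     p[2:(nr + 1L), 1:nc] + p[2:(nr + 1L), 2:(nc + 1L)] +
     p[2:(nr + 1L), 3:(nc + 2L)] +
     p[3:(nr + 2L), 1:nc] + p[3:(nr + 2L), 2:(nc + 1L)] +
     p[3:(nr + 2L), 3:(nc + 2L)]) / 9
}

#' Locate a single bead in a transmission frame
#'
#' Partitions intensities into three classes with two-level Otsu
#' thresholding; the bead mask is the darkest class (transmission contrast:
#' dark bead on bright background; set `invert = TRUE` for fluorescent
#' beads). The position is the intensity-weighted centre of mass of the
#' mask in continuous 0-based pixel coordinates (pixel centres at
#' integers).
#'
#' @param image Numeric matrix.
#' @param invert If `TRUE` the bead is the brightest class.
#' @param smooth If `TRUE` (default) a 3x3 box filter is applied before
#'   thresholding; the kernel is symmetric so it adds no bias and
#'   preserves whole-pixel shift equivariance while damping read noise.
#' @return List with `x_px`, `y_px`, `ok` (localization success flag) and
#'   `quality` in `[0, 1]`.
#' @export
locate_xy <- function(image, invert = FALSE, smooth = TRUE) {
  fail <- list(x_px = NA_real_, y_px = NA_real_, ok = FALSE, quality = 0)
  if (smooth) image <- box3(image)
  rng <- range(image)
  if (diff(rng) <= 0) return(fail)
  thr <- otsu_thresholds(image)
  mask <- if (invert) image >= thr[2L] else image <= thr[1L]
  if (!any(mask)) return(fail)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.integer(EBImage::imageData(lab))
  sizes <- tabulate(lab[lab > 0L])
  main <- which.max(sizes)
  if (sum(sizes > 0.25 * sizes[main]) > 1L) return(fail)  # >1 large component
  sel <- lab == main
  dim(sel) <- dim(image)
  w <- if (invert) image - thr[2L] else thr[1L] - image
  w <- pmax(w, 0) * sel
  sw <- sum(w)
  if (sw <= 0) return(fail)
  ny <- nrow(image); nx <- ncol(image)
  cx <- matrix(rep(0:(nx - 1L), each = ny), ny, nx)
  cy <- matrix(rep(0:(ny - 1L), nx), ny, nx)
  x0 <- sum(w * cx) / sw
  y0 <- sum(w * cy) / sw
  # refinement: absorbance-weighted centroid over a circular window
  # centred on the mask centroid; weights are independent of the Otsu
  # thresholds, which decouples the estimate from threshold noise
  bg <- stats::median(if (invert) image[image <= thr[1L]]
                      else image[image >= thr[2L]])
  rwin <- sqrt(sizes[main] / pi) + 3
  for (iter in 1:2) {
    win <- (cx - x0)^2 + (cy - y0)^2 <= rwin^2
    w2 <- pmax(if (invert) image - bg else bg - image, 0) * win
    s2 <- sum(w2)
    if (s2 <= 0) break
    x0 <- sum(w2 * cx) / s2
    y0 <- sum(w2 * cy) / s2
  }
  list(x_px = x0, y_px = y0, ok = TRUE,
       quality = sizes[main] / sum(sizes))
}

#' Image sharpness (normalized squared-gradient energy)
#'
#' Tenengrad-style focus metric: the sum of squared central-difference
#' gradients normalized by the squared mean intensity and the number of
#' interior pixels. Translation-insensitive, invariant to a global
#' intensity scale, zero for a constant image, and strictly decreasing
#' with defocus blur over the calibration range of the renderer.
#'
#' @param image Numeric matrix.
#' @return A non-negative scalar.
#' @export
sharpness <- function(image) {
  if (length(image) == 0L) stop("empty image")
  ny <- nrow(image); nx <- ncol(image)
  if (ny < 3L || nx < 3L) stop("image too small for gradients")
  gx <- (image[, 3:nx] - image[, 1:(nx - 2L)]) / 2
  gy <- (image[3:ny, ] - image[1:(ny - 2L), ]) / 2
  m <- mean(image)
  if (m == 0) return(0)
  (sum(gx^2) + sum(gy^2)) / (m^2 * (ny - 2L) * (nx - 2L))
}

# Normalized 9-plane sharpness signature of one multiplane frame.
plane_signature <- function(frame) {
  s <- vapply(frame$sub_images, sharpness, numeric(1L))
  s / sum(s)
}

#' Calibrate the sharpness-to-z map for one bead
#'
#' For a stack of multiplane frames recorded at known stage offsets the
#' per-plane sharpness profiles are tabulated; axial localization then
#' matches an unknown frame's nine-plane sharpness signature against these
#' profiles. The valid range is the largest contiguous z interval over
#' which the sharpness-weighted plane centroid is strictly monotone (the
#' signature is invertible there).
#'
#' @param stack A multiplane `bead_video` (array `[3ny, 3nx, n]`) or plain
#'   3D array of tiled frames.
#' @param z_offsets Known axial offsets (m), strictly increasing, at least
#'   5 values spanning more than `2 * plane_spacing`.
#' @param plane_spacing Axial plane spacing (m); taken from the stack
#'   attribute when present.
#' @return A `sharpness_calibration` with `z_grid`, `profiles`
#'   (`n_z x 9`, rows sum to 1), `plane_labels`, `plane_spacing` and
#'   `valid_range`.
#' @export
calibrate_z <- function(stack, z_offsets,
                        plane_spacing = attr(stack, "plane_spacing")) {
  if (is.null(plane_spacing) || !is.finite(plane_spacing))
    stop("'plane_spacing' must be given")
  z <- as.numeric(z_offsets)
  if (any(diff(z) <= 0))
    stop("z offsets must be strictly increasing (non-monotone grid)")
  if (length(z) < 5L) stop("need at least 5 distinct z offsets")
  if (diff(range(z)) <= 2 * plane_spacing)
    stop("z sweep must span more than 2 * plane_spacing")
  if (dim(stack)[3L] != length(z))
    stop("number of frames and z offsets differ")
  prof <- t(vapply(seq_along(z), function(i) {
    plane_signature(split_multiplane(stack[, , i], plane_spacing))
  }, numeric(9L)))
  cent <- as.numeric(prof %*% (-4:4))
  dc <- sign(diff(cent))
  # longest run of strict monotonicity in the sharpness-weighted centroid
  best <- c(1L, 1L); i <- 1L
  while (i <= length(dc)) {
    if (dc[i] == 0) { i <- i + 1L; next }
    j <- i
    while (j < length(dc) && dc[j + 1L] == dc[i]) j <- j + 1L
    if (j + 1L - i > best[2L] - best[1L]) best <- c(i, j + 1L)
    i <- j + 1L
  }
  structure(list(z_grid = z, profiles = prof, plane_labels = -4:4,
                 plane_spacing = plane_spacing,
                 valid_range = c(z[best[1L]], z[best[2L]])),
            class = "sharpness_calibration")
}

#' Save / load a sharpness calibration (plain JSON, full precision)
#'
#' Numbers are written with 17 significant digits so the stored
#' calibration reloads bit-exactly.
#'
#' @param cal A `sharpness_calibration`.
#' @param path File path.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "sharpness_calibration"))
  num <- function(x) paste0("[", paste(fmt_g(x), collapse = ","), "]")
  txt <- sprintf(
    '{"z_grid":%s,"profiles":[%s],"plane_labels":[%s],"plane_spacing":%s,"valid_range":%s}',
    num(cal$z_grid),
    paste(apply(cal$profiles, 1L, num), collapse = ","),
    paste(cal$plane_labels, collapse = ","),
    fmt_g(cal$plane_spacing), num(cal$valid_range))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.matrix(x$profiles))
    x$profiles <- matrix(unlist(x$profiles), ncol = 9L, byrow = TRUE)
  structure(list(z_grid = as.numeric(x$z_grid), profiles = x$profiles,
                 plane_labels = as.integer(x$plane_labels),
                 plane_spacing = as.numeric(x$plane_spacing),
                 valid_range = as.numeric(x$valid_range)),
            class = "sharpness_calibration")
}

#' Axial localization from a nine-plane sharpness signature
#'
#' Least-squares match of the frame's normalized sharpness vector against
#' the calibration profiles, interpolated on a fine z grid with a final
#' parabolic sub-grid refinement.
#'
#' @param frame A `multiplane_frame` from [split_multiplane()].
#' @param cal A `sharpness_calibration` from [calibrate_z()].
#' @param n_grid Number of interpolation points across the valid range.
#' @return List with `z` (m), `ok` flag (`FALSE` when the match falls at
#'   the edge of the calibrated range) and the residual `sse`.
#' @export
locate_z <- function(frame, cal, n_grid = 2001L) {
  stopifnot(inherits(frame, "multiplane_frame"),
            inherits(cal, "sharpness_calibration"))
  s <- plane_signature(frame)
  zf <- seq(cal$valid_range[1L], cal$valid_range[2L], length.out = n_grid)
  pf <- vapply(1:9, function(p)
    stats::approx(cal$z_grid, cal$profiles[, p], xout = zf)$y,
    numeric(n_grid))
  sse <- rowSums((pf - matrix(s, n_grid, 9L, byrow = TRUE))^2)
  i <- which.min(sse)
  if (i == 1L || i == n_grid)
    return(list(z = zf[i], ok = FALSE, sse = sse[i]))
  # parabolic refinement through the three bracketing grid points
  num <- sse[i - 1L] - sse[i + 1L]
  den <- sse[i - 1L] - 2 * sse[i] + sse[i + 1L]
  dz <- if (den > 0) 0.5 * num / den else 0
  list(z = zf[i] + dz * (zf[2L] - zf[1L]), ok = TRUE, sse = sse[i])
}

#' Track a bead through a rendered or recorded video
#'
#' Runs per-frame localization ([locate_xy()], plus [locate_z()] for
#' multiplane stacks, where the lateral position is read from the central
#' plane-0 sub-image). Frames that fail localization are dropped and
#' recorded -- never interpolated, since interpolation biases the MSD.
#' When drops occur, the returned trajectory is the longest contiguous run
#' of successful frames (uniform sampling is preserved) and all dropped
#' frame indices are kept in the `dropped_frames` field.
#'
#' @param stack A `bead_video` or plain array `[ny, nx, n]`.
#' @param mode `"2d"` or `"multiplane"`.
#' @param pixel_size Metres per pixel (default from stack attributes).
#' @param frame_rate Hz (default from stack attributes).
#' @param ctx A [probe_context()].
#' @param cal `sharpness_calibration`, required for multiplane mode.
#' @param invert Passed to [locate_xy()].
#' @return A [trajectory()] (axes x, y and, for multiplane, z).
#' @export
track_video <- function(stack, mode = c("2d", "multiplane"),
                        pixel_size = attr(stack, "pixel_size"),
                        frame_rate = attr(stack, "frame_rate"),
                        ctx, cal = NULL, invert = FALSE) {
  mode <- match.arg(mode)
  if (is.null(pixel_size) || is.null(frame_rate))
    stop("pixel_size and frame_rate must be supplied or present as attributes")
  n <- dim(stack)[3L]
  xs <- ys <- zs <- rep(NA_real_, n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    fr <- stack[, , i]
    if (mode == "multiplane") {
      if (is.null(cal)) stop("multiplane tracking requires a calibration")
      mp <- split_multiplane(fr, cal$plane_spacing)
      central <- mp$sub_images[[which(mp$plane_labels == 0L)]]
      loc <- locate_xy(central, invert = invert)
      if (loc$ok) {
        lz <- locate_z(mp, cal)
        if (lz$ok) { zs[i] <- lz$z } else loc$ok <- FALSE
      }
    } else {
      loc <- locate_xy(fr, invert = invert)
    }
    if (loc$ok) { xs[i] <- loc$x_px; ys[i] <- loc$y_px; ok[i] <- TRUE }
  }
  if (!any(ok)) stop("no frame could be localized")
  dropped <- which(!ok)
  if (length(dropped) > 0.1 * n)
    warning(sprintf("%d of %d frames (%.0f%%) dropped during localization",
                    length(dropped), n, 100 * length(dropped) / n))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  runs <- which(r$values)
  seg <- runs[which.max(r$lengths[runs])]
  idx <- (ends[seg] - r$lengths[seg] + 1L):ends[seg]
  dt <- 1 / frame_rate
  pos <- cbind(x = xs[idx] * pixel_size, y = ys[idx] * pixel_size)
  if (mode == "multiplane") pos <- cbind(pos, z = zs[idx])
  trajectory(t = (idx - 1L) * dt, positions = pos, frame_rate = frame_rate,
             context = ctx,
             provenance = sprintf(
               "track_video(mode=%s, frames %d-%d of %d, %d dropped)",
               mode, idx[1L], idx[length(idx)], n, length(dropped)),
             dropped_frames = dropped)
}
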