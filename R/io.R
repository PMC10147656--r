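# File formats: trajectory tables (plain text, SI units, bit-exact
# round-trip), multi-page TIFF image stacks with a JSON metadata sidecar,
# and analysis configuration files.

fmt_g <- function(x) formatC(x, format = "g", digits = 17)

#' Write a trajectory as plain-text CSV with a metadata header
#'
#' Columns are `t_s, x_m[, y_m, z_m]` in SI units; acquisition metadata
#' (frame rate, probe context, provenance, dropped frames) is stored in
#' `# key: value` comment lines. Numbers are written with 17 significant
#' digits so a read back is bit-exact.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  ctx <- traj$context
  writeLines(c("# microrheo trajectory v1",
               sprintf("# frame_rate_hz: %s", fmt_g(traj$frame_rate)),
               sprintf("# radius_a_m: %s", fmt_g(ctx$radius_a)),
               sprintf("# temperature_K: %s", fmt_g(ctx$temperature_T)),
               sprintf("# solvent_viscosity_Pa_s: %s",
                       fmt_g(ctx$solvent_viscosity_eta_s)),
               sprintf("# provenance: %s", traj$provenance)), con)
  if (length(traj$dropped_frames))
    writeLines(sprintf("# dropped_frames: %s",
                       paste(traj$dropped_frames, collapse = ",")), con)
  cols <- colnames(traj$positions)
  writeLines(paste(c("t_s", paste0(cols, "_m")), collapse = ","), con)
  body <- cbind(fmt_g(traj$t),
                matrix(fmt_g(traj$positions), ncol = length(cols)))
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read a trajectory table
#'
#' Accepts the format written by [write_trajectory()]: SI-unit columns
#' (`t_s`, `x_m`, `y_m`, `z_m`) and metadata comments. Time must be
#' strictly monotone and uniformly sampled. Legacy pixel-unit columns
#' (`x_px`, ...) are converted only when the header declares
#' `# pixel_size_m: <v>`; otherwise reading fails -- units are never
#' guessed.
#'
#' @param path Input path.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  meta <- list()
  m <- regmatches(hdr, regexec("^#\\s*([A-Za-z_0-9]+):\\s*(.*)$", hdr))
  for (g in m) if (length(g) == 3L) meta[[g[2L]]] <- g[3L]
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  dat <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!"t_s" %in% names(dat))
    stop("missing required column 't_s' (time in seconds)")
  px_cols <- grep("_px$", names(dat), value = TRUE)
  if (length(px_cols)) {
    if (is.null(meta$pixel_size_m))
      stop("pixel-unit columns found but no '# pixel_size_m:' metadata; ",
           "declare the pixel size to convert to metres")
    ps <- as.numeric(meta$pixel_size_m)
    for (pc in px_cols) {
      dat[[sub("_px$", "_m", pc)]] <- dat[[pc]] * ps
      dat[[pc]] <- NULL
    }
  }
  axes <- intersect(c("x_m", "y_m", "z_m"), names(dat))
  if (!length(axes))
    stop("no position columns (x_m, y_m, z_m) found")
  tt <- dat$t_s
  if (any(diff(tt) <= 0))
    stop("time stamps are not strictly increasing (non-monotone time)")
  fr <- if (!is.null(meta$frame_rate_hz)) as.numeric(meta$frame_rate_hz)
        else 1 / mean(diff(tt))
  ctx <- probe_context(
    radius_a = as.numeric(meta$radius_a_m %||% 3e-6),
    temperature_T = as.numeric(meta$temperature_K %||% 298.15),
    solvent_viscosity_eta_s =
      as.numeric(meta$solvent_viscosity_Pa_s %||% 0.89e-3))
  dropped <- if (!is.null(meta$dropped_frames))
    as.integer(strsplit(meta$dropped_frames, ",")[[1L]]) else integer()
  pos <- as.matrix(dat[axes])
  colnames(pos) <- sub("_m$", "", axes)
  trajectory(tt, pos, fr, ctx,
             provenance = meta$provenance %||% sprintf("read from %s", path),
             dropped_frames = dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an image stack as 16-bit multi-page TIFF with a JSON sidecar
#'
#' @param stack Array `[ny, nx, n]` of counts in 0..65535.
#' @param path Output `.tif` path; metadata (`pixel_size`, `frame_rate`,
#'   layout, plane spacing) goes to `<path>.json`.
#' @export
write_image_stack <- function(stack, path) {
  n <- dim(stack)[3L]
  pages <- lapply(seq_len(n), function(i) stack[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(pixel_size = attr(stack, "pixel_size"),
               frame_rate = attr(stack, "frame_rate"),
               layout = attr(stack, "layout") %||% "fullframe",
               plane_spacing = attr(stack, "plane_spacing"))
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF image stack
#'
#' Single-channel 8/16-bit stacks only. Acquisition metadata is taken
#' from the `<path>.json` sidecar; a missing frame rate is an error, it
#' is never guessed.
#'
#' @param path `.tif` path.
#' @param frame_rate,pixel_size Overrides for sidecar metadata.
#' @return A numeric array `[ny, nx, n]` of counts with metadata
#'   attributes, class `bead_video`.
#' @export
read_image_stack <- function(path, frame_rate = NULL, pixel_size = NULL) {
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, info = FALSE),
    error = function(e)
      stop("failed to read TIFF (file truncated or corrupt?): ",
           conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, TRUE)))
    stop("multi-channel (RGB) input: a single-channel stack is expected")
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  frame_rate <- frame_rate %||% meta$frame_rate
  pixel_size <- pixel_size %||% meta$pixel_size
  if (is.null(frame_rate))
    stop("no frame rate in sidecar metadata and none supplied; ",
         "a frame rate is required and never guessed")
  d <- dim(pages[[1L]])
  stack <- array(0, dim = c(d[1L], d[2L], length(pages)))
  for (i in seq_along(pages)) stack[, , i] <- pages[[i]] * 65535
  structure(stack, class = "bead_video", pixel_size = pixel_size,
            frame_rate = frame_rate,
            layout = meta$layout %||% "fullframe",
            plane_spacing = meta$plane_spacing)
}

#' Read / write an analysis configuration (lossless JSON)
#'
#' A configuration is a plain named list (probe metadata, conventions,
#' filter thresholds, grids, seeds, paths). Every pipeline output embeds
#' the configuration used, so results are reproducible from the file
#' alone.
#'
#' @param config Named list.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Export a modulus or viscosity table as tabular text
#'
#' Column headers carry units; numbers keep full precision.
#'
#' @param x A `modulus_curve`, `msd_curve`, `compliance_curve` or data
#'   frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  df <- if (inherits(x, "modulus_curve"))
    data.frame(omega_rad_per_s = x$omega, G_prime_Pa = x$G_prime,
               G_doubleprime_Pa = x$G_doubleprime)
  else if (inherits(x, "msd_curve"))
    data.frame(tau_s = x$tau, msd_m2 = x$values, n_pairs = x$n_pairs)
  else if (inherits(x, "compliance_curve"))
    data.frame(t_s = x$t, J_per_Pa = x$J)
  else as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], fmt_g)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
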