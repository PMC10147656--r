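# Geometry stage: triangular surface meshes of cell clusters, exact
# point-to-mesh distances, and distance-stratified summaries of per-probe
# rheology.

#' Triangular surface mesh
#'
#' @param vertices Numeric matrix `n x 3` of vertex coordinates.
#' @param faces Integer matrix `m x 3` of 1-based vertex indices.
#' @param units Length unit the coordinates are expressed in (free
#'   string, e.g. `"m"` or `"um"`); declared, never guessed.
#' @return A `surface_mesh`; zero-area faces are dropped during cleaning.
#' @export
surface_mesh <- function(vertices, faces, units = "m") {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L)
  if (nrow(faces) == 0L) stop("mesh has no faces")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  v0 <- vertices[faces[, 1L], , drop = FALSE]
  e1 <- vertices[faces[, 2L], , drop = FALSE] - v0
  e2 <- vertices[faces[, 3L], , drop = FALSE] - v0
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  area2 <- sqrt(rowSums(cr^2))
  scale <- max(sqrt(rowSums(e1^2)), sqrt(rowSums(e2^2)))
  keep <- area2 > 1e-14 * scale^2
  if (!any(keep)) stop("all faces are degenerate")
  structure(list(vertices = vertices, faces = faces[keep, , drop = FALSE],
                 units = units),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("Surface mesh: %d vertices, %d faces (units: %s)\n",
              nrow(x$vertices), nrow(x$faces), x$units))
  invisible(x)
}

#' Read a triangular mesh from ASCII OBJ, PLY or STL
#'
#' Length units must be declared, either by a `# units: <u>` comment
#' (OBJ), a `comment units <u>` line (PLY), or the `units` argument;
#' reading fails otherwise -- units are never guessed.
#'
#' @param path File path (`.obj`, `.ply` or `.stl`, ASCII).
#' @param units Unit declaration overriding/absent from the file.
#' @return A `surface_mesh`.
#' @export
read_surface_mesh <- function(path, units = NULL) {
  lines <- readLines(path, warn = FALSE)
  ext <- tolower(tools::file_ext(path))
  file_units <- NULL
  if (ext == "obj") {
    m <- regmatches(lines, regexec("^#\\s*units:\\s*(\\S+)", lines))
    hit <- which(lengths(m) == 2L)
    if (length(hit)) file_units <- m[[hit[1L]]][2L]
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)),
                                            "\\s+"),
                                   function(s) as.numeric(s[1:3])))
    faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)),
                                            "\\s+"), function(s)
      as.integer(vapply(strsplit(s[1:3], "/"), `[[`, "", 1L))))
  } else if (ext == "ply") {
    m <- regmatches(lines, regexec("^comment\\s+units\\s+(\\S+)", lines))
    hit <- which(lengths(m) == 2L)
    if (length(hit)) file_units <- m[[hit[1L]]][2L]
    nv <- as.integer(sub(".*vertex\\s+", "",
                         grep("^element vertex", lines, value = TRUE)[1L]))
    nf <- as.integer(sub(".*face\\s+", "",
                         grep("^element face", lines, value = TRUE)[1L]))
    body <- which(lines == "end_header") + 1L
    verts <- do.call(rbind, lapply(strsplit(lines[body:(body + nv - 1L)],
                                            "\\s+"),
                                   function(s) as.numeric(s[1:3])))
    faces <- do.call(rbind, lapply(
      strsplit(lines[(body + nv):(body + nv + nf - 1L)], "\\s+"),
      function(s) as.integer(s[2:4]) + 1L))
  } else if (ext == "stl") {
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    verts <- do.call(rbind, lapply(strsplit(trimws(sub("vertex", "", vl)),
                                            "\\s+"),
                                   function(s) as.numeric(s[1:3])))
    faces <- matrix(seq_len(nrow(verts)), ncol = 3L, byrow = TRUE)
  } else stop("unsupported mesh format: .", ext)
  u <- if (!is.null(units)) units else file_units
  if (is.null(u))
    stop("mesh file declares no length units; pass `units = ` explicitly")
  surface_mesh(verts, faces, units = u)
}

#' Write a mesh as ASCII OBJ with a units comment
#' @param mesh A `surface_mesh`.
#' @param path Output path.
#' @export
write_surface_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", mesh$units), con)
  writeLines(sprintf("v %.17g %.17g %.17g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1L], mesh$faces[, 2L],
                     mesh$faces[, 3L]), con)
  invisible(path)
}

#' Shortest distance from a point to a triangular mesh
#'
#' Exact minimum over all faces, considering closest points in face
#' interiors, on edges and at vertices: the point is projected into each
#' triangle's plane via barycentric coordinates; where the projection
#' falls outside, the closest point on each of the three edge segments is
#' used instead.
#'
#' @param point Numeric length-3 coordinate.
#' @param mesh A `surface_mesh`.
#' @return List with `distance`, `closest_point` and the `face` index.
#' @export
point_to_mesh_distance <- function(point, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"), length(point) == 3L)
  V <- mesh$vertices; Fc <- mesh$faces
  v0 <- V[Fc[, 1L], , drop = FALSE]
  v1 <- V[Fc[, 2L], , drop = FALSE]
  v2 <- V[Fc[, 3L], , drop = FALSE]
  e1 <- v1 - v0; e2 <- v2 - v0
  p <- matrix(point, nrow(Fc), 3L, byrow = TRUE) - v0
  d11 <- rowSums(e1 * e1); d12 <- rowSums(e1 * e2); d22 <- rowSums(e2 * e2)
  dp1 <- rowSums(p * e1); dp2 <- rowSums(p * e2)
  det <- d11 * d22 - d12^2
  u <- (d22 * dp1 - d12 * dp2) / det
  v <- (d11 * dp2 - d12 * dp1) / det
  inside <- u >= 0 & v >= 0 & (u + v) <= 1
  cand <- v0 + u * e1 + v * e2              # in-plane projection
  seg_closest <- function(A, B) {
    AB <- B - A
    tt <- rowSums((matrix(point, nrow(A), 3L, byrow = TRUE) - A) * AB) /
      rowSums(AB * AB)
    tt <- pmin(pmax(tt, 0), 1)
    A + tt * AB
  }
  c1 <- seg_closest(v0, v1); c2 <- seg_closest(v1, v2); c3 <- seg_closest(v2, v0)
  dist_to <- function(C) sqrt(rowSums((matrix(point, nrow(C), 3L,
                                              byrow = TRUE) - C)^2))
  d_edge <- pmin(dist_to(c1), dist_to(c2), dist_to(c3))
  edge_pick <- max.col(-cbind(dist_to(c1), dist_to(c2), dist_to(c3)),
                       ties.method = "first")
  best_edge <- rbind(c1, c2, c3)[(edge_pick - 1L) * nrow(Fc) +
                                   seq_len(nrow(Fc)), , drop = FALSE]
  d_face <- ifelse(inside, dist_to(cand), d_edge)
  closest <- ifelse(matrix(inside, nrow(Fc), 3L), cand, best_edge)
  i <- which.min(d_face)
  list(distance = d_face[i], closest_point = as.numeric(closest[i, ]),
       face = i)
}

# Ray-parity interior test (unsigned distances carry an interior flag).
# Fixed irrational-ish ray direction avoids edge/vertex grazing for
# generic meshes.
point_in_mesh <- function(point, mesh) {
  dir <- c(0.2357022, 0.5773503, 0.7818315)
  V <- mesh$vertices; Fc <- mesh$faces
  v0 <- V[Fc[, 1L], , drop = FALSE]
  e1 <- V[Fc[, 2L], , drop = FALSE] - v0
  e2 <- V[Fc[, 3L], , drop = FALSE] - v0
  # Moller-Trumbore, vectorized over faces
  h <- cbind(dir[2L] * e2[, 3L] - dir[3L] * e2[, 2L],
             dir[3L] * e2[, 1L] - dir[1L] * e2[, 3L],
             dir[1L] * e2[, 2L] - dir[2L] * e2[, 1L])
  a <- rowSums(e1 * h)
  ok <- abs(a) > 1e-300
  s <- matrix(point, nrow(Fc), 3L, byrow = TRUE) - v0
  u <- rowSums(s * h) / a
  q <- cbind(s[, 2L] * e1[, 3L] - s[, 3L] * e1[, 2L],
             s[, 3L] * e1[, 1L] - s[, 1L] * e1[, 3L],
             s[, 1L] * e1[, 2L] - s[, 2L] * e1[, 1L])
  v <- (dir[1L] * q[, 1L] + dir[2L] * q[, 2L] + dir[3L] * q[, 3L]) / a
  tt <- rowSums(e2 * q) / a
  hits <- ok & u >= 0 & v >= 0 & (u + v) <= 1 & tt > 1e-12
  sum(hits) %% 2L == 1L
}

#' Distances from probe positions to the nearest cell-cluster mesh
#'
#' For each probe (optionally per timepoint) the unsigned shortest
#' distance to the nearest of the supplied cluster meshes is computed;
#' the nearest cluster and an interior flag (ray-casting parity) are
#' recorded. All measured columns of `probes` are carried through.
#'
#' @param probes Data frame with columns `x`, `y`, `z` (and optionally
#'   `probe_id`, `timepoint`, measured quantities).
#' @param meshes A `surface_mesh`, a list of them (one per cluster), or
#'   -- when `probes$timepoint` is present -- a named list (timepoint ->
#'   list of cluster meshes).
#' @param units Unit the probe coordinates are in; must match every
#'   mesh's declared unit or an error is raised.
#' @return `probes` with added columns `distance_to_nearest_cluster`,
#'   `nearest_cluster` and `interior`.
#' @export
probe_cluster_distances <- function(probes, meshes, units = "m") {
  probes <- as.data.frame(probes)
  need <- c("x", "y", "z")
  if (nrow(probes) > 0L && !all(need %in% names(probes)))
    stop("probes need columns x, y, z")
  as_cluster_list <- function(m) {
    if (inherits(m, "surface_mesh")) list(cluster_1 = m)
    else { if (is.null(names(m))) names(m) <- paste0("cluster_", seq_along(m)); m }
  }
  per_time <- "timepoint" %in% names(probes) &&
    is.list(meshes) && !inherits(meshes, "surface_mesh") &&
    all(vapply(meshes, function(m) !inherits(m, "surface_mesh"), TRUE))
  check_units <- function(ml) for (m in ml)
    if (!identical(m$units, units))
      stop(sprintf("unit mismatch: probes in '%s' but mesh declares '%s'",
                   units, m$units))
  if (per_time) lapply(meshes, function(ml) check_units(as_cluster_list(ml)))
  else check_units(as_cluster_list(meshes))
  out <- probes
  out$distance_to_nearest_cluster <- numeric(nrow(probes))
  out$nearest_cluster <- character(nrow(probes))
  out$interior <- logical(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    ml <- if (per_time) as_cluster_list(meshes[[as.character(probes$timepoint[i])]])
          else as_cluster_list(meshes)
    pt <- as.numeric(probes[i, need])
    ds <- vapply(ml, function(m) point_to_mesh_distance(pt, m)$distance,
                 numeric(1L))
    j <- which.min(ds)
    out$distance_to_nearest_cluster[i] <- ds[j]
    out$nearest_cluster[i] <- names(ml)[j]
    out$interior[i] <- point_in_mesh(pt, ml[[j]])
  }
  out
}

#' Stratify probe records by distance to the nearest cluster
#'
#' Summarizes a measured quantity per distance bin (and per grouping
#' column when given): count, median, min, max and the spread in decades
#' (`log10(max/min)`), the scale on which microrheological heterogeneity
#' is usually quoted.
#'
#' @param records Data frame with a `distance_to_nearest_cluster` column
#'   and the measured quantity.
#' @param breaks Distance bin edges (same unit as the distances), e.g.
#'   `c(0, 50e-6, Inf)`.
#' @param value Name of the measured column (e.g. `"G0_prime"`).
#' @param by Optional name of a grouping column (e.g. `"day"`).
#' @return Data frame with one row per bin (x group): `bin`, `n`,
#'   `median`, `min`, `max`, `decades`. Empty bins report `n = 0` and NA
#'   statistics.
#' @export
stratify_by_distance <- function(records, breaks = c(0, 50e-6, Inf),
                                 value, by = NULL) {
  records <- as.data.frame(records)
  stopifnot("distance_to_nearest_cluster" %in% names(records),
            value %in% names(records))
  labs <- paste0("[", utils::head(breaks, -1L), ", ",
                 utils::tail(breaks, -1L), ")")
  bin <- cut(records$distance_to_nearest_cluster, breaks = breaks,
             labels = labs, right = FALSE, include.lowest = TRUE)
  groups <- if (is.null(by)) list(rep("all", nrow(records)))
            else list(records[[by]])
  combos <- expand.grid(bin = labs,
                        group = unique(unlist(groups)),
                        stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- bin == combos$bin[i] & groups[[1L]] == combos$group[i]
    v <- records[[value]][which(sel)]
    if (!length(v))
      data.frame(bin = combos$bin[i], group = combos$group[i], n = 0L,
                 median = NA_real_, min = NA_real_, max = NA_real_,
                 decades = NA_real_)
    else
      data.frame(bin = combos$bin[i], group = combos$group[i],
                 n = length(v), median = stats::median(v), min = min(v),
                 max = max(v),
                 decades = if (length(v) == 1L) 0 else log10(max(v) / min(v)))
  }))
  if (is.null(by)) res$group <- NULL else names(res)[2L] <- by
  res
}
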