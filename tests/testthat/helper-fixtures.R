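# Shared fixtures: probe contexts, a latitude/longitude sphere mesh and
# small builders used across the test files.

kB <- 1.380649e-23

# 6 um diameter polystyrene probe in water at 25 C
water_ctx <- function() probe_context(3e-6, 298.15, 0.89e-3)

# same probe in a 100x-viscous medium: slow diffusion that stays inside a
# small rendered field of view
thick_ctx <- function() probe_context(3e-6, 298.15, 0.89e-1)

kBT <- function(ctx) ctx$boltzmann_kB * ctx$temperature_T

# latitude/longitude triangulation of a sphere, radius r
sphere_mesh <- function(r, nth = 24L, nph = 48L, units = "m") {
  th <- seq(0, pi, length.out = nth)
  ph <- seq(0, 2 * pi, length.out = nph + 1L)[-(nph + 1L)]
  verts <- rbind(c(0, 0, r), c(0, 0, -r))
  for (i in 2:(nth - 1L)) for (j in seq_len(nph))
    verts <- rbind(verts, r * c(sin(th[i]) * cos(ph[j]),
                                sin(th[i]) * sin(ph[j]), cos(th[i])))
  idx <- function(i, j) 2L + (i - 2L) * nph + j
  faces <- NULL
  for (j in seq_len(nph)) {
    jn <- j %% nph + 1L
    faces <- rbind(faces,
                   c(1L, idx(2L, j), idx(2L, jn)),
                   c(2L, idx(nth - 1L, jn), idx(nth - 1L, j)))
  }
  for (i in 2:(nth - 2L)) for (j in seq_len(nph)) {
    jn <- j %% nph + 1L
    faces <- rbind(faces, c(idx(i, j), idx(i + 1L, j), idx(i + 1L, jn)),
                   c(idx(i, j), idx(i + 1L, jn), idx(i, jn)))
  }
  surface_mesh(verts, faces, units = units)
}

# uniform surface sampling of a mesh (triangles by area, then uniform
# barycentric): the brute-force oracle for point-to-mesh distances
sample_mesh_surface <- function(mesh, n) {
  V <- mesh$vertices; Fc <- mesh$faces
  v0 <- V[Fc[, 1L], , drop = FALSE]
  e1 <- V[Fc[, 2L], , drop = FALSE] - v0
  e2 <- V[Fc[, 3L], , drop = FALSE] - v0
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  area <- sqrt(rowSums(cr^2)) / 2
  fi <- sample.int(nrow(Fc), n, replace = TRUE, prob = area)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  u <- 1 - r1; v <- r1 * (1 - r2)
  v0[fi, ] + u * e1[fi, ] + v * e2[fi, ]
}

# stationary trajectory from given position columns
make_traj <- function(pos, dt = 0.01, ctx = water_ctx()) {
  n <- nrow(as.matrix(pos))
  trajectory(t = (seq_len(n) - 1L) * dt, positions = pos,
             frame_rate = 1 / dt, context = ctx, provenance = "fixture")
}

# analytic Kelvin-Voigt creep compliance curve (closed-form oracle input)
kv_compliance <- function(G0, eta, t = 10^seq(-5, 1, by = 1 / 64),
                          ctx = water_ctx()) {
  structure(list(t = t, J = (1 / G0) * (1 - exp(-t * G0 / eta)),
                 terminal_slope = 0, dimension = 2, convention = "paper",
                 context = ctx),
            class = "compliance_curve")
}

newtonian_compliance <- function(eta, t = 10^seq(-5, 1, by = 1 / 64),
                                 ctx = water_ctx()) {
  structure(list(t = t, J = t / eta, terminal_slope = 1 / eta,
                 dimension = 2, convention = "paper", context = ctx),
            class = "compliance_curve")
}

# static-bead trajectory at a fixed (x, y, z) offset, for rendering
static_traj <- function(x = 0, y = 0, z = NULL, n = 2L, dt = 0.01,
                        ctx = thick_ctx()) {
  pos <- cbind(x = rep(x, n), y = rep(y, n))
  if (!is.null(z)) pos <- cbind(pos, z = rep(z, n))
  make_traj(pos, dt, ctx)
}

# multiplane stack of static frames at the given z positions
multiplane_sweep <- function(zs, ctx = thick_ctx(), pixel_size = 0.25e-6,
                             sub_shape = c(48L, 48L), dz = 0.79e-6,
                             noise_sigma = 0, seed = NULL) {
  if (length(zs) == 1L) zs <- rep(zs, 2L)
  tz <- make_traj(cbind(x = numeric(length(zs)), y = numeric(length(zs)),
                        z = zs), 0.01, ctx)
  render_multiplane_video(tz, pixel_size, sub_shape, plane_spacing = dz,
                          noise_sigma = noise_sigma, seed = seed)
}
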