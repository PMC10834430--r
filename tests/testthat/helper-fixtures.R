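# Shared fixtures and independent oracles, all built in code at test time.

# rotation about an axis by angle (Rodrigues)
rot_axis <- function(ax, th) {
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

geodesic_angle <- function(Ra, Rb) {
  c_ <- (sum(diag(t(Ra) %*% Rb)) - 1) / 2
  acos(pmin(1, pmax(-1, c_)))
}

fixture_tetra <- function() {
  TriMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

# closed unit cube surface, outward-oriented
fixture_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = 0
             c(5, 6, 7), c(6, 8, 7),   # z = 1
             c(1, 2, 5), c(2, 6, 5),   # y = 0
             c(3, 7, 4), c(4, 7, 8),   # y = 1
             c(1, 5, 3), c(3, 5, 7),   # x = 0
             c(2, 4, 6), c(4, 8, 6))   # x = 1
  TriMesh(v, f)
}

# digitized ball mask, radius r mm on an h-mm grid centred at the origin
fixture_sphere_mask <- function(r = 5, h = 0.5) {
  n <- 2L * ceiling(r / h) + 5L
  xs <- (seq_len(n) - (n + 1) / 2) * h
  g <- expand.grid(x = xs, y = xs, z = xs)
  VoxelMask(array(as.integer(g$x^2 + g$y^2 + g$z^2 <= r^2), c(n, n, n)),
            rep(h, 3), rep(xs[1], 3))
}

sphere_mesh_cache <- new.env(parent = emptyenv())
fixture_sphere_mesh <- function(r = 5, h = 0.5) {
  key <- paste(r, h)
  if (is.null(sphere_mesh_cache[[key]]))
    sphere_mesh_cache[[key]] <- mask_to_surface(fixture_sphere_mask(r, h))
  sphere_mesh_cache[[key]]
}

# independent point-to-triangle distance: candidate projections onto the
# plane, the three edges and the three vertices (different construction
# from the package's region-based kernel)
oracle_point_tri <- function(p, a, b, c) {
  cand <- list(a, b, c)
  seg <- function(u, v) {
    t <- sum((p - u) * (v - u)) / sum((v - u)^2)
    u + min(1, max(0, t)) * (v - u)
  }
  cand <- c(cand, list(seg(a, b), seg(b, c), seg(c, a)))
  n <- pracma_cross(b - a, c - a)
  if (sum(n^2) > 0) {
    q <- p - sum((p - a) * n) / sum(n^2) * n
    # barycentric inside test
    M <- cbind(b - a, c - a)
    uv <- qr.solve(crossprod(M), crossprod(M, q - a))
    if (uv[1] >= 0 && uv[2] >= 0 && sum(uv) <= 1) cand <- c(cand, list(q))
  }
  sqrt(min(vapply(cand, function(x) sum((p - x)^2), numeric(1))))
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# exhaustive directed distances: every vertex of `from` against every
# triangle of `to`
oracle_directed_distances <- function(from, to) {
  vapply(seq_len(nrow(from$vertices)), function(i) {
    p <- from$vertices[i, ]
    min(vapply(seq_len(nrow(to$faces)), function(t) {
      f <- to$faces[t, ]
      oracle_point_tri(p, to$vertices[f[1], ], to$vertices[f[2], ],
                       to$vertices[f[3], ])
    }, numeric(1)))
  }, numeric(1))
}

# bumpy open triangulated sheet for distance-oracle tests
fixture_random_sheet <- function(n = 7, seed = 1, z_amp = 0.5, shift = c(0, 0, 0)) {
  set.seed(seed)
  g <- expand.grid(x = seq(0, 3, length.out = n), y = seq(0, 3, length.out = n))
  v <- cbind(g$x, g$y, z_amp * sin(g$x * 2) * cos(g$y * 3)) +
    matrix(rep(shift, each = n * n), ncol = 3)
  idx <- function(i, j) (j - 1L) * n + i
  f <- NULL
  for (j in seq_len(n - 1)) for (i in seq_len(n - 1)) {
    f <- rbind(f, c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  }
  TriMesh(v, f)
}

# small shared shape population + SSM, built once per test run
ssm_cache <- new.env(parent = emptyenv())
fixture_small_ssm <- function() {
  if (is.null(ssm_cache$model)) {
    pop <- synth_population(PopulationSpec(n_shapes = 9, seed = 31))
    template <- taubin_smooth(remesh_template(pop$meshes[[1]], 1500))
    corr <- suppressWarnings(
      correspond(template, pop$meshes[seq_len(8)], n_points = 350, seed = 7))
    sets <- refine_correspondence(corr$sets, pop$meshes[seq_len(8)], d = 2,
                                  max_iter = 30)
    sets <- extend_correspondence(sets, attr(corr, "template_points"),
                                  template, pop$meshes[seq_len(8)])
    sets <- refine_correspondence(sets, pop$meshes[seq_len(8)], d = 2,
                                  max_iter = 10)
    al <- gpa(sets)
    attr(al, "template_points") <- template$vertices
    model <- build_ssm(al, variance_fraction = 1.0, template_mesh = template)
    ssm_cache$pop <- pop
    ssm_cache$template <- template
    ssm_cache$corr <- corr
    ssm_cache$aligned <- al
    ssm_cache$model <- model
  }
  ssm_cache
}
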