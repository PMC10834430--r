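#' Voxel grid specification
#'
#' @param spacing length-3 positive numeric (mm per axis).
#' @param origin length-3 numeric, world mm of voxel (0,0,0) centre.
#' @param dims length-3 integer grid dimensions.
#' @return A list with class `grid_spec`.
#' @export
grid_spec <- function(spacing, origin, dims) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(spacing) == 3L, all(spacing > 0), length(origin) == 3L,
            length(dims) == 3L, all(dims >= 1))
  structure(list(spacing = spacing, origin = as.numeric(origin),
                 dims = as.integer(dims)), class = "grid_spec")
}

#' @rdname grid_spec
#' @param mask a [VoxelMask()] whose grid is reused.
#' @export
grid_from_mask <- function(mask) {
  grid_spec(mask$spacing, mask$origin, dim(mask$values))
}

#' @rdname grid_spec
#' @param mesh a mesh whose bounding box (plus `margin` mm) defines the grid.
#' @param margin margin in mm added around the mesh bounding box.
#' @export
grid_for_mesh <- function(mesh, spacing, margin = 2) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  lo <- apply(mesh$vertices, 2L, min) - margin
  hi <- apply(mesh$vertices, 2L, max) + margin
  dims <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  grid_spec(spacing, lo, dims)
}

# separable Gaussian smoothing of a 3-D array (zero padding), sigma in voxels
gaussian_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-r):r)^2 / (2 * sigma^2))
  w <- w / sum(w)
  for (ax in 1:3) {
    out <- array(0, dim(a))
    n <- dim(a)[ax]
    for (k in (-r):r) {
      i0 <- max(1L, 1L - k)
      i1 <- min(n, n - k)
      if (i0 > i1) next
      di <- lapply(dim(a), seq_len)
      si <- di
      di[[ax]] <- i0:i1
      si[[ax]] <- (i0:i1) + k
      slab <- do.call(`[`, c(list(a), si, list(drop = FALSE)))
      cur <- do.call(`[`, c(list(out), di, list(drop = FALSE)))
      out <- do.call(`[<-`, c(list(out), di,
                              list(value = cur + w[k + r + 1L] * slab)))
    }
    a <- out
  }
  a
}

#' Extract a triangle surface from a binary mask
#'
#' Runs isosurface extraction (marching tetrahedra, crack-free parity
#' decomposition) at `iso` on the binary field, after an optional Gaussian
#' pre-smoothing of the field that removes voxel staircase artifacts (the
#' smoothing falls back to the raw binary field when it would erase the
#' surface, e.g. for single-voxel blobs).  The largest connected surface
#' component is kept and the mesh is oriented outward.
#'
#' @param mask a [VoxelMask()].
#' @param iso iso-level on the (smoothed) binary field.
#' @param smooth_sigma Gaussian sigma in voxels applied to the binary field
#'   before extraction; `0` disables smoothing.
#' @param keep_largest keep only the largest connected component.
#' @return A [TriMesh()] in world mm coordinates.
#' @export
mask_to_surface <- function(mask, iso = 0.5, smooth_sigma = 1, keep_largest = TRUE) {
  stopifnot(inherits(mask, "VoxelMask"))
  if (sum(mask$values) == 0L) stop("mask has no foreground voxels")
  pad <- max(1L, as.integer(ceiling(3 * smooth_sigma)))
  d <- dim(mask$values) + 2L * pad
  field <- array(0, d)
  field[pad + seq_len(dim(mask$values)[1]),
        pad + seq_len(dim(mask$values)[2]),
        pad + seq_len(dim(mask$values)[3])] <- mask$values
  origin <- mask$origin - pad * mask$spacing
  if (smooth_sigma > 0) {
    sm <- gaussian_smooth3(field, smooth_sigma)
    if (max(sm) > iso) field <- sm  # else: smoothing erased the blob
  }
  res <- cpp_marching_tets(as.numeric(field), dim(field), mask$spacing,
                           origin, iso)
  if (nrow(res$faces) == 0L) stop("no isosurface found in mask")
  mesh <- TriMesh(res$vertices, res$faces + 1L)
  if (keep_largest) mesh <- mesh_largest_component(mesh)
  if (mesh_signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh
}

#' Voxelize a closed surface onto a regular grid
#'
#' A voxel is foreground iff its centre lies inside the closed surface
#' (ray-parity test).
#'
#' @param mesh a closed (watertight) [TriMesh()].
#' @param grid a [grid_spec()].
#' @return A [VoxelMask()] on `grid`.
#' @export
voxelize_surface <- function(mesh, grid) {
  stopifnot(inherits(mesh, "TriMesh"), inherits(grid, "grid_spec"))
  nb <- mesh_boundary_edge_count(mesh)
  if (nb > 0L)
    stop("mesh is not watertight: ", nb, " boundary edges")
  inside <- cpp_voxelize(mesh$vertices, mesh$faces - 1L, grid$dims,
                         grid$spacing, grid$origin)
  VoxelMask(array(as.integer(inside), dim = grid$dims), grid$spacing,
            grid$origin)
}

#' Taubin mesh smoothing
#'
#' Alternating lambda/mu uniform-Laplacian passes; the negative `mu` step
#' compensates the shrinkage of plain Laplacian smoothing.
#'
#' @param mesh a [TriMesh()].
#' @param lam positive smoothing factor of the forward pass.
#' @param mu negative factor of the inflating pass.
#' @param iterations number of lambda/mu pairs.
#' @return The smoothed mesh (same connectivity).
#' @export
taubin_smooth <- function(mesh, lam = 0.5, mu = -0.53, iterations = 10) {
  stopifnot(inherits(mesh, "TriMesh"))
  if (lam <= 0) stop("lam must be > 0")
  if (mu >= 0) stop("mu must be < 0")
  if (iterations == 0) return(mesh)
  smooth_pass_factors(mesh, rep(c(lam, mu), iterations))
}

# apply a sequence of uniform-Laplacian passes with the given factors
smooth_pass_factors <- function(mesh, factors) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- unique(rbind(e, e[, c(2, 1)]))
  ord <- order(e[, 1])
  e <- e[ord, , drop = FALSE]
  deg <- tabulate(e[, 1], nbins = nrow(v))
  for (fac in factors) {
    s <- rowsum(v[e[, 2], , drop = FALSE], e[, 1], reorder = TRUE)
    nb <- v
    present <- sort(unique(e[, 1]))
    nb[present, ] <- s / deg[present]
    v <- v + fac * (nb - v)
  }
  TriMesh(v, f)
}

# plain Laplacian smoothing (shrinking); used for comparisons
laplacian_smooth <- function(mesh, lam = 0.5, iterations = 10) {
  smooth_pass_factors(mesh, rep(lam, iterations))
}

#' Remesh a template surface to a target resolution
#'
#' Isotropic remeshing by re-extraction: the closed input surface is
#' voxelized at a grid size iterated to hit the requested vertex budget,
#' re-extracted, projected back onto the input surface, and relaxed
#' tangentially.  When the target is within 10% of the current vertex count
#' the input is returned unchanged.
#'
#' @param mesh closed manifold [TriMesh()].
#' @param target_vertex_count requested vertex count (within 10%).
#' @param relax_iterations tangential relaxation passes after projection.
#' @return A [TriMesh()].
#' @export
remesh_template <- function(mesh, target_vertex_count, relax_iterations = 5) {
  stopifnot(inherits(mesh, "TriMesh"))
  if (target_vertex_count < 4) stop("target_vertex_count must be >= 4")
  tab <- mesh_edge_table(mesh$faces)
  if (any(tab > 2L)) stop("non-manifold input mesh (edge shared by >2 faces)")
  nv <- nrow(mesh$vertices)
  if (abs(nv - target_vertex_count) <= 0.1 * target_vertex_count)
    return(mesh)
  if (any(tab == 1L))
    stop("remeshing requires a closed surface (", sum(tab == 1L),
         " boundary edges)")
  A <- mesh_area(mesh)
  h <- sqrt(2.2 * A / target_vertex_count)
  out <- NULL
  for (it in 1:8) {
    g <- grid_for_mesh(mesh, h, margin = 3 * h)
    vm <- voxelize_surface(mesh, g)
    if (sum(vm$values) == 0L) {
      h <- h / 2
      next
    }
    cand <- mask_to_surface(vm, smooth_sigma = 1)
    n <- nrow(cand$vertices)
    out <- cand
    if (abs(n - target_vertex_count) <= 0.1 * target_vertex_count) break
    h <- h * sqrt(n / target_vertex_count)
  }
  # project onto the input surface, then tangential relaxation with projection
  out$vertices <- mesh_closest(out$vertices, mesh)$closest
  nbrs <- mesh_vertex_neighbors(out)
  for (r in seq_len(relax_iterations)) {
    v <- out$vertices
    cent <- t(vapply(seq_len(nrow(v)), function(i) {
      nb <- nbrs[[i]]
      if (is.null(nb) || length(nb) == 0L) v[i, ] else colMeans(v[nb, , drop = FALSE])
    }, numeric(3)))
    out$vertices <- mesh_closest(cent, mesh)$closest
  }
  out
}

# uniform-by-area random points on a mesh surface (expects seeded RNG state)
sample_points_on_mesh <- function(mesh, n) {
  areas <- mesh_face_areas(mesh)
  fi <- sample.int(nrow(mesh$faces), n, replace = TRUE, prob = areas)
  r1 <- sqrt(stats::runif(n))
  r2 <- stats::runif(n)
  a <- mesh$vertices[mesh$faces[fi, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[fi, 2], , drop = FALSE]
  c3 <- mesh$vertices[mesh$faces[fi, 3], , drop = FALSE]
  (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c3
}

#' Poisson-disk sampling of a surface
#'
#' Oversamples the surface uniformly by area, then greedily accepts points
#' respecting a minimum-distance radius that shrinks geometrically until
#' exactly `n_points` are accepted.  The accepted radius never drops below
#' 0.55 of the ideal hexagonal-packing radius `sqrt(area / (2*sqrt(3)*n))`.
#'
#' @param mesh a [TriMesh()].
#' @param n_points number of points to draw (>= 4).
#' @param seed RNG seed; identical seeds give identical point sets.
#' @param oversample pool size multiplier.
#' @return A [SurfacePointSet()].
#' @export
poisson_disk_sample <- function(mesh, n_points, seed = 1, oversample = 30) {
  stopifnot(inherits(mesh, "TriMesh"))
  if (n_points < 4) stop("n_points must be >= 4")
  pool_n <- ceiling(oversample * n_points)
  if (pool_n < n_points)
    stop("n_points exceeds the oversampling pool budget; increase `oversample`")
  pool <- with_seed(seed, sample_points_on_mesh(mesh, pool_n))
  r_ideal <- sqrt(mesh_area(mesh) / (2 * sqrt(3) * n_points))
  idx <- cpp_poisson_greedy(pool, as.integer(n_points), 1.7 * r_ideal,
                            0.55 * r_ideal, 0.88)
  if (length(idx) < n_points)
    stop("n_points exceeds the oversampling pool budget; increase `oversample`")
  SurfacePointSet(pool[idx + 1L, , drop = FALSE], "poisson_disk")
}

#' Uniformize the spacing of surface points
#'
#' Relaxation that pushes each point away from its nearest neighbour when
#' their distance is below the median nearest-neighbour distance, then
#' reprojects onto the surface.  Iterations that would increase the spread
#' of nearest-neighbour distances are rejected (step halving), so the
#' standard deviation of nearest-neighbour distances is non-increasing.
#'
#' @param points a [SurfacePointSet()] on `mesh`.
#' @param mesh the source [TriMesh()].
#' @param iterations maximum relaxation iterations.
#' @return A [SurfacePointSet()].
#' @export
uniformize_points <- function(points, mesh, iterations = 20) {
  stopifnot(inherits(points, "SurfacePointSet"), inherits(mesh, "TriMesh"))
  p <- points$points
  if (nrow(p) < 4L) stop("need at least 4 points")
  if (iterations == 0) return(points)
  alpha <- 0.5
  nn <- cpp_all_nn(p)
  sd_cur <- stats::sd(nn$dist)
  for (it in seq_len(iterations)) {
    d <- nn$dist
    q <- p[nn$idx + 1L, , drop = FALSE]
    m <- stats::median(d)
    move <- d < m & d > 1e-12
    step <- p
    if (any(move)) {
      dir <- (p[move, , drop = FALSE] - q[move, , drop = FALSE]) / d[move]
      step[move, ] <- p[move, , drop = FALSE] + alpha * (m - d[move]) * dir
    }
    cand <- mesh_closest(step, mesh)$closest
    nn2 <- cpp_all_nn(cand)
    sd_new <- stats::sd(nn2$dist)
    if (sd_new <= sd_cur + 1e-15) {
      p <- cand
      nn <- nn2
      sd_cur <- sd_new
    } else {
      alpha <- alpha / 2
      if (alpha < 0.05) break
    }
  }
  SurfacePointSet(p, points$source_mesh_id)
}

# run expr with a temporarily seeded RNG, restoring the caller's RNG state.
# `seed` must be forced *before* the state snapshot: a lazy seed argument
# like sample.int(n, 1) would otherwise advance the RNG after the snapshot
# and be rolled back, freezing the caller's stream.
with_seed <- function(seed, expr) {
  force(seed)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
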