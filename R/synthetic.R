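#' Specification of a synthetic bone-shape population
#'
#' Each shape is a smooth closed distal-femur-like implicit surface (two
#' superellipsoid condyles blended with a cylindrical shaft) whose named
#' geometric parameters are drawn independently from Gaussians.  Parameters
#' with zero SD are fixed; those with positive SD are the population's
#' latent anatomical modes.
#'
#' @param n_shapes number of shapes (>= 2).
#' @param modes named list of `c(mean, sd)` pairs; recognised names:
#'   `condyle_width`, `condyle_depth`, `condyle_height`,
#'   `condyle_separation`, `shaft_radius`, `shaft_length` (mm).  Defaults
#'   give two active modes (condyle width and separation) with SDs around
#'   6-8% of the mean, a typical anatomical coefficient of variation.
#' @param base_resolution marching grid spacing in mm.
#' @param seed RNG seed.
#' @return An object of class `PopulationSpec`.
#' @export
PopulationSpec <- function(n_shapes = 30,
                           modes = list(condyle_width = c(12, 1.0),
                                        condyle_depth = c(15, 0),
                                        condyle_height = c(14, 0),
                                        condyle_separation = c(26, 1.8),
                                        shaft_radius = c(10, 0),
                                        shaft_length = c(35, 0)),
                           base_resolution = 1.5, seed = 1) {
  defaults <- list(condyle_width = c(12, 0), condyle_depth = c(15, 0),
                   condyle_height = c(14, 0), condyle_separation = c(26, 0),
                   shaft_radius = c(10, 0), shaft_length = c(35, 0))
  for (nm in names(modes)) {
    if (!nm %in% names(defaults)) stop("unknown latent mode: ", nm)
    defaults[[nm]] <- as.numeric(modes[[nm]])
  }
  if (n_shapes < 2) stop("n_shapes must be >= 2")
  for (nm in names(defaults)) {
    m <- defaults[[nm]]
    if (length(m) != 2L || m[1] <= 0 || m[2] < 0)
      stop("mode ", nm, " must be c(positive mean, non-negative sd)")
  }
  structure(list(n_shapes = as.integer(n_shapes), modes = defaults,
                 base_resolution = base_resolution, seed = seed),
            class = "PopulationSpec")
}

# implicit distal-femur-like field: positive inside (smooth-min union of
# two superellipsoid condyles and a capped shaft cylinder).  Like a real
# distal femur the shape is asymmetric: the medial condyle is larger than
# the lateral one and the shaft axis sits anterior to the condylar centre,
# which also makes the principal-axes orientation of every sample
# unambiguous.
femur_field <- function(x, y, z, p) {
  pe <- 2.5
  k <- 6
  cond <- function(cx, f) {
    (((abs(x - cx) / (f * p["condyle_width"]))^pe +
      (abs(y) / (f * p["condyle_depth"]))^pe +
      (abs(z) / (f * p["condyle_height"]))^pe)^(1 / pe)) - 1
  }
  f1 <- cond(-p["condyle_separation"] / 2, 1.15)  # medial, larger
  f2 <- cond(p["condyle_separation"] / 2, 0.95)   # lateral
  y_shaft <- y - 0.3 * p["condyle_depth"]         # shaft anterior offset
  f3 <- pmax(sqrt(x^2 + y_shaft^2) / p["shaft_radius"] - 1,
             (z - p["shaft_length"]) / p["shaft_radius"],
             (-z - 2) / p["shaft_radius"])
  -(-log(exp(-k * f1) + exp(-k * f2) + exp(-k * f3)) / k)
}

#' Generate a synthetic population of bone-like surfaces
#'
#' Draws the latent parameters from `spec`, evaluates the implicit field on
#' a regular grid and extracts each surface by marching tetrahedra.  Seed
#' determinism: identical spec gives bit-identical draws and meshes.
#'
#' @param spec a [PopulationSpec()].
#' @return List with `meshes` (list of [TriMesh()]), `params` (data frame of
#'   drawn latent values, one row per shape) and `spec`.
#' @export
synth_population <- function(spec) {
  stopifnot(inherits(spec, "PopulationSpec"))
  means <- vapply(spec$modes, `[`, numeric(1), 1L)
  sds <- vapply(spec$modes, `[`, numeric(1), 2L)
  draws <- with_seed(spec$seed, {
    m <- matrix(stats::rnorm(spec$n_shapes * length(means)),
                nrow = spec$n_shapes)
    sweep(sweep(m, 2L, sds, `*`), 2L, means, `+`)
  })
  colnames(draws) <- names(means)
  if (any(draws <= 0)) stop("degenerate (non-positive) parameter draw")
  h <- spec$base_resolution
  meshes <- lapply(seq_len(spec$n_shapes), function(i) {
    p <- draws[i, ]
    ext_x <- p["condyle_separation"] / 2 + p["condyle_width"] + 4
    ext_y <- p["condyle_depth"] + 4
    lo <- c(-ext_x, -ext_y, -p["condyle_height"] - 4)
    hi <- c(ext_x, ext_y, p["shaft_length"] + 4)
    dims <- as.integer(ceiling((hi - lo) / h)) + 1L
    xs <- lo[1] + (seq_len(dims[1]) - 1L) * h
    ys <- lo[2] + (seq_len(dims[2]) - 1L) * h
    zs <- lo[3] + (seq_len(dims[3]) - 1L) * h
    gx <- array(rep(xs, times = dims[2] * dims[3]), dims)
    gy <- array(rep(rep(ys, each = dims[1]), times = dims[3]), dims)
    gz <- array(rep(zs, each = dims[1] * dims[2]), dims)
    fld <- femur_field(as.vector(gx), as.vector(gy), as.vector(gz), p)
    res <- cpp_marching_tets(fld, dims, rep(h, 3), lo, 0)
    m <- TriMesh(res$vertices, res$faces + 1L)
    m <- mesh_largest_component(m)
    if (mesh_signed_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
    m
  })
  list(meshes = meshes, params = as.data.frame(draws), spec = spec)
}

#' Specification of segmentation-mask degradation
#'
#' Emulates the coarse surface topology, noise, artifacts and holes of an
#' automatic segmentation: voxelization on a coarse grid, vertex jitter,
#' carved spherical holes at surface-adjacent centres and random flips of
#' boundary voxels.
#'
#' @param spacing voxel spacing in mm (scalar or length 3).  The default is
#'   0.5 mm isotropic; `spacing = c(0.36, 0.36, 0.7)` matches typical knee
#'   MRI resolution.
#' @param jitter_sd vertex jitter SD in mm.
#' @param n_holes number of carved spherical holes.
#' @param hole_radius hole radius in mm.
#' @param flip_prob probability of flipping each boundary voxel.
#' @param seed RNG seed.
#' @return An object of class `DegradationSpec`.
#' @export
DegradationSpec <- function(spacing = 0.5, jitter_sd = 0.3, n_holes = 3,
                            hole_radius = 2, flip_prob = 0.02, seed = 1) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(all(spacing > 0), jitter_sd >= 0, n_holes >= 0, hole_radius >= 0,
            flip_prob >= 0, flip_prob <= 1)
  structure(list(spacing = spacing, jitter_sd = jitter_sd,
                 n_holes = as.integer(n_holes), hole_radius = hole_radius,
                 flip_prob = flip_prob, seed = seed),
            class = "DegradationSpec")
}

#' Degrade a ground-truth surface into a coarse noisy segmentation mask
#'
#' @param gt closed ground-truth [TriMesh()].
#' @param spec a [DegradationSpec()].
#' @return A [VoxelMask()]; deterministic per seed.
#' @export
synth_degrade <- function(gt, spec) {
  stopifnot(inherits(gt, "TriMesh"), inherits(spec, "DegradationSpec"))
  ext <- apply(gt$vertices, 2L, function(c3) diff(range(c3)))
  if (spec$hole_radius > min(ext) / 2)
    stop("hole_radius larger than the shape")
  with_seed(spec$seed, {
    grid <- grid_for_mesh(gt, spec$spacing,
                          margin = max(2, spec$hole_radius + 1))
    src <- gt
    if (spec$jitter_sd > 0) {
      src <- TriMesh(gt$vertices +
                       matrix(stats::rnorm(length(gt$vertices), 0,
                                           spec$jitter_sd),
                              ncol = 3L), gt$faces)
    }
    mask <- voxelize_surface(src, grid)
    vals <- mask$values
    dims <- dim(vals)
    if (spec$n_holes > 0L && spec$hole_radius > 0) {
      centers <- gt$vertices[sample.int(nrow(gt$vertices), spec$n_holes), ,
                             drop = FALSE]
      for (i in seq_len(spec$n_holes)) {
        ix <- which(abs((grid$origin[1] + (seq_len(dims[1]) - 1) *
                           grid$spacing[1]) - centers[i, 1]) <= spec$hole_radius)
        iy <- which(abs((grid$origin[2] + (seq_len(dims[2]) - 1) *
                           grid$spacing[2]) - centers[i, 2]) <= spec$hole_radius)
        iz <- which(abs((grid$origin[3] + (seq_len(dims[3]) - 1) *
                           grid$spacing[3]) - centers[i, 3]) <= spec$hole_radius)
        if (!length(ix) || !length(iy) || !length(iz)) next
        px <- grid$origin[1] + (ix - 1) * grid$spacing[1]
        py <- grid$origin[2] + (iy - 1) * grid$spacing[2]
        pz <- grid$origin[3] + (iz - 1) * grid$spacing[3]
        dd <- outer(outer((px - centers[i, 1])^2, (py - centers[i, 2])^2, `+`),
                    (pz - centers[i, 3])^2, `+`)
        cut <- array(dd <= spec$hole_radius^2, dim(dd))
        vals[ix, iy, iz][cut] <- 0L
      }
    }
    if (spec$flip_prob > 0) {
      boundary <- which(is_boundary_voxel(vals))
      flip <- boundary[stats::runif(length(boundary)) < spec$flip_prob]
      vals[flip] <- 1L - vals[flip]
    }
    VoxelMask(vals, grid$spacing, grid$origin)
  })
}

# 6-neighbourhood boundary voxels (foreground next to background or
# background next to foreground)
is_boundary_voxel <- function(vals) {
  d <- dim(vals)
  shift <- function(a, ax, k) {
    out <- array(a[1] * 0L, d)  # zero-filled
    n <- d[ax]
    i0 <- max(1L, 1L - k)
    i1 <- min(n, n - k)
    di <- lapply(d, seq_len)
    si <- di
    di[[ax]] <- i0:i1
    si[[ax]] <- (i0:i1) + k
    slab <- do.call(`[`, c(list(a), si, list(drop = FALSE)))
    do.call(`[<-`, c(list(out), di, list(value = slab)))
  }
  differs <- array(FALSE, d)
  for (ax in 1:3) for (k in c(-1L, 1L)) {
    differs <- differs | (shift(vals, ax, k) != vals &
                            shift(array(1L, d), ax, k) == 1L)
  }
  differs
}

#' Offset a bone patch into a synthetic articular cartilage surface
#'
#' Offsets the patch sub-mesh along its vertex normals by a positive
#' thickness profile and keeps the patch triangulation.
#'
#' @param bone closed [TriMesh()].
#' @param patch face index set (see [select_contact_patch()]).
#' @param thickness_profile positive scalar (mm) or function mapping an
#'   N x 3 matrix of positions to per-vertex thicknesses.
#' @return A [TriMesh()] articular surface.
#' @export
synth_cartilage_surface <- function(bone, patch, thickness_profile = 2) {
  stopifnot(inherits(bone, "TriMesh"))
  sub <- mesh_subset_faces(bone, patch)
  nrm <- mesh_vertex_normals(sub)
  # offset along a smoothed normal field: raw per-vertex normals of jagged
  # patches flip skinny boundary triangles under finite offsets
  nbrs <- mesh_vertex_neighbors(sub)
  for (pass in 1:2) {
    nrm <- t(vapply(seq_len(nrow(nrm)), function(i) {
      nb <- nbrs[[i]]
      v <- if (is.null(nb) || !length(nb)) nrm[i, ]
           else nrm[i, ] + colSums(nrm[nb, , drop = FALSE])
      v / sqrt(sum(v^2))
    }, numeric(3)))
  }
  th <- if (is.function(thickness_profile)) thickness_profile(sub$vertices)
        else rep(thickness_profile, nrow(sub$vertices))
  if (any(th <= 0)) stop("thickness profile must be positive everywhere")
  out <- TriMesh(sub$vertices + th * nrm, sub$faces)
  # inverted non-degenerate triangles signal a self-intersecting offset
  # (micro-slivers can flip under any differential offset and are ignored)
  unit <- function(n) n / pmax(sqrt(rowSums(n^2)), 1e-300)
  a_in <- mesh_face_areas(sub)
  flip <- rowSums(unit(mesh_face_normals(out)) * unit(mesh_face_normals(sub)))
  bad <- flip < -1e-6 & a_in > 1e-3 * stats::median(a_in)
  if (any(bad))
    stop("self-intersection detected in the offset cartilage surface")
  out
}

#' Generate null/effect ensembles of smooth stance-phase trajectories
#'
#' Gaussian white noise per node, smoothed with a Gaussian kernel of the
#' requested FWHM and rescaled to unit variance per node; group B is
#' mean-shifted by `effect_size` (in noise SD units).
#'
#' @param n_per_group trajectories per group.
#' @param effect_size constant mean shift added to group B.
#' @param fwhm_nodes smoothness (kernel FWHM) in node units (> 0).
#' @param Q number of nodes over 0-100% stance (>= 8).
#' @param seed RNG seed.
#' @return List with `A` and `B`, each a list of [Trajectory()] objects.
#' @export
synth_trajectories <- function(n_per_group, effect_size = 0, fwhm_nodes = 20,
                               Q = 101, seed = 1) {
  if (Q < 8) stop("Q must be >= 8")
  if (fwhm_nodes <= 0) stop("fwhm_nodes must be > 0")
  sigma <- fwhm_nodes / sqrt(8 * log(2))
  r <- ceiling(4 * sigma)
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  with_seed(seed, {
    gen <- function(shift) {
      lapply(seq_len(n_per_group), function(i) {
        noise <- stats::rnorm(Q + 2L * r)
        sm <- stats::convolve(noise, rev(w), type = "filter")
        Trajectory(sm / sqrt(sum(w^2)) + shift)
      })
    }
    list(A = gen(0), B = gen(effect_size))
  })
}
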