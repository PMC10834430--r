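#' Triangle surface mesh
#'
#' Constructs a triangle mesh in world millimetre coordinates. Faces are
#' 1-based vertex indices (converted to 0-based only at the C++ boundary).
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm).
#' @param faces integer M x 3 matrix of 1-based vertex indices.
#' @return An object of class `TriMesh` with elements `vertices` and `faces`.
#' @export
TriMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be N x 3")
  if (ncol(faces) != 3L) stop("faces must be M x 3")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
            faces[, 2] == faces[, 3]))
      stop("degenerate face with repeated vertex index")
  }
  structure(list(vertices = vertices, faces = faces), class = "TriMesh")
}

#' Quadrilateral surface mesh
#'
#' @param vertices numeric N x 3 matrix (mm).
#' @param faces integer M x 4 matrix of 1-based vertex indices.
#' @return An object of class `QuadMesh`.
#' @export
QuadMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be N x 3")
  if (ncol(faces) != 4L) stop("faces must be M x 4")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices out of range")
    if (any(apply(faces, 1L, function(q) length(unique(q)) != 4L)))
      stop("degenerate quad with repeated vertex index")
  }
  structure(list(vertices = vertices, faces = faces), class = "QuadMesh")
}

#' Binary segmentation mask on a regular voxel grid
#'
#' World position of voxel `(i,j,k)` (0-based) is `origin + c(i,j,k) * spacing`
#' (voxel centres).
#'
#' @param values 3-D array; any nonzero entry is foreground.
#' @param spacing positive length-3 numeric, mm per axis.
#' @param origin length-3 numeric, world mm of the centre of voxel (0,0,0).
#' @return An object of class `VoxelMask`.
#' @export
VoxelMask <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive reals")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite reals")
  v <- array(as.integer(values != 0), dim = dim(values))
  structure(list(values = v, spacing = spacing, origin = origin),
            class = "VoxelMask")
}

#' Points sampled on a surface
#'
#' @param points numeric K x 3 matrix (mm).
#' @param source_mesh_id provenance label for the source surface.
#' @return An object of class `SurfacePointSet`.
#' @export
SurfacePointSet <- function(points, source_mesh_id = "") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must be K x 3")
  if (!all(is.finite(points))) stop("non-finite point coordinates")
  structure(list(points = points, source_mesh_id = as.character(source_mesh_id)),
            class = "SurfacePointSet")
}

#' @export
print.TriMesh <- function(x, ...) {
  cat(sprintf("TriMesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' @export
print.QuadMesh <- function(x, ...) {
  cat(sprintf("QuadMesh: %d vertices, %d quads\n", nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' @export
print.VoxelMask <- function(x, ...) {
  cat(sprintf("VoxelMask: %s grid, spacing (%s) mm, %d foreground voxels\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = ", "), sum(x$values)))
  invisible(x)
}

#' @export
print.SurfacePointSet <- function(x, ...) {
  cat(sprintf("SurfacePointSet: %d points (source: %s)\n", nrow(x$points),
              x$source_mesh_id))
  invisible(x)
}

# ---- internal mesh helpers -------------------------------------------------

mesh_face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

mesh_face_areas <- function(mesh) {
  n <- mesh_face_normals(mesh)
  0.5 * sqrt(rowSums(n^2))
}

mesh_area <- function(mesh) sum(mesh_face_areas(mesh))

mesh_vertex_normals <- function(mesh) {
  fn <- mesh_face_normals(mesh)  # area-weighted (cross product magnitude)
  vn <- matrix(0, nrow(mesh$vertices), 3L)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    vn[, 1] <- vn[, 1] + tabulate0(idx, fn[, 1], nrow(vn))
    vn[, 2] <- vn[, 2] + tabulate0(idx, fn[, 2], nrow(vn))
    vn[, 3] <- vn[, 3] + tabulate0(idx, fn[, 3], nrow(vn))
  }
  nrm <- sqrt(rowSums(vn^2))
  nrm[nrm == 0] <- 1
  vn / nrm
}

# sum weights w by integer bins (fast accumulation)
tabulate0 <- function(bin, w, nbins) {
  out <- numeric(nbins)
  s <- rowsum(w, bin, reorder = FALSE)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# undirected edge list (each row sorted) with face multiplicity
mesh_edge_table <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

mesh_boundary_edge_count <- function(mesh) {
  sum(mesh_edge_table(mesh$faces) == 1L)
}

mesh_is_closed <- function(mesh) {
  tab <- mesh_edge_table(mesh$faces)
  all(tab == 2L)
}

mesh_euler_characteristic <- function(mesh) {
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(3, 1)])
  ne <- length(unique(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))))
  nrow(mesh$vertices) - ne + nrow(mesh$faces)
}

mesh_median_edge_length <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  stats::median(sqrt(rowSums((v[e[, 1], , drop = FALSE] -
                              v[e[, 2], , drop = FALSE])^2)))
}

# signed volume via divergence theorem (positive for outward orientation)
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) +
      a[, 2] * (b[, 3] * c3[, 1] - b[, 1] * c3[, 3]) +
      a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])) / 6
}

# connected components of faces via shared edges; returns face component ids
mesh_face_components <- function(faces) {
  cpp_face_components(faces - 1L, max(faces)) + 1L
}

# keep the connected component with the largest area; drop unused vertices
mesh_largest_component <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(mesh)
  comp <- mesh_face_components(mesh$faces)
  areas <- mesh_face_areas(mesh)
  keep_comp <- names(which.max(tapply(areas, comp, sum)))
  keep <- comp == as.integer(keep_comp)
  mesh_subset_faces(mesh, which(keep))
}

# sub-mesh from a face index set, dropping unreferenced vertices
mesh_subset_faces <- function(mesh, face_idx) {
  f <- mesh$faces[face_idx, , drop = FALSE]
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  TriMesh(mesh$vertices[used, , drop = FALSE],
          matrix(remap[f], ncol = 3L))
}

# vertex 1-ring adjacency as a list of integer vectors
mesh_vertex_neighbors <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- rbind(e, e[, c(2, 1)])
  sp <- split(e[, 2], e[, 1])
  out <- vector("list", nrow(mesh$vertices))
  out[as.integer(names(sp))] <- lapply(sp, function(x) unique(x))
  out
}

mesh_min_angle <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  ang <- function(p, q, r) {
    u <- q - p
    w <- r - p
    acos(pmin(1, pmax(-1, rowSums(u * w) /
                        (sqrt(rowSums(u^2)) * sqrt(rowSums(w^2))))))
  }
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  min(c(ang(a, b, c3), ang(b, c3, a), ang(c3, a, b)))
}

# closest points on a TriMesh for a matrix of query points; grid-accelerated
# above a face-count threshold where binning pays off
mesh_closest <- function(points, mesh) {
  points <- as.matrix(points)
  res <- if (nrow(mesh$faces) > 512L)
    cpp_closest_on_mesh_grid(points, mesh$vertices, mesh$faces - 1L)
  else cpp_closest_on_mesh(points, mesh$vertices, mesh$faces - 1L)
  list(dist = as.numeric(res$dist), closest = res$closest,
       tri = as.integer(res$tri) + 1L)
}
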