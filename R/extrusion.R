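#' Hexahedral mesh container
#'
#' Nodes in mm; elements as M x 8 1-based node indices in Abaqus C3D8
#' corner ordering (bottom quad counter-clockwise, then top quad).
#'
#' @param nodes N x 3 matrix.
#' @param elements M x 8 integer matrix.
#' @param layer_id integer per-element layer label.
#' @param node_sets named list of 1-based node index vectors.
#' @param element_sets named list of 1-based element index vectors.
#' @return An object of class `HexMesh`.
#' @export
HexMesh <- function(nodes, elements, layer_id = rep(1L, nrow(elements)),
                    node_sets = list(), element_sets = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  stopifnot(ncol(nodes) == 3L, ncol(elements) == 8L,
            length(layer_id) == nrow(elements))
  if (nrow(elements) > 0L &&
      (min(elements) < 1L || max(elements) > nrow(nodes)))
    stop("element node indices out of range")
  structure(list(nodes = nodes, elements = elements,
                 layer_id = as.integer(layer_id),
                 node_sets = node_sets, element_sets = element_sets),
            class = "HexMesh")
}

#' @export
print.HexMesh <- function(x, ...) {
  cat(sprintf("HexMesh: %d nodes, %d hex elements, %d layers\n",
              nrow(x$nodes), nrow(x$elements), length(unique(x$layer_id))))
  invisible(x)
}

#' Element-size presets for cartilage meshing (mm)
#'
#' Coarse/fine/very-fine target element sizes commonly used for contact
#' convergence checks.
#' @export
element_size_presets <- c(coarse = 2, fine = 1, very_fine = 0.5)

#' Select the bone faces adjacent to the cartilage surface
#'
#' Bone faces whose centroids lie within `max_distance` of the articular
#' cartilage surface; the largest connected face component is kept.
#'
#' @param bone a [TriMesh()].
#' @param cartilage_surface a [TriMesh()].
#' @param max_distance selection distance in mm.
#' @return Integer vector of face indices into `bone$faces`.
#' @export
select_contact_patch <- function(bone, cartilage_surface, max_distance = 2.0) {
  stopifnot(inherits(bone, "TriMesh"), inherits(cartilage_surface, "TriMesh"))
  v <- bone$vertices
  f <- bone$faces
  cent <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
           v[f[, 3], , drop = FALSE]) / 3
  d <- mesh_closest(cent, cartilage_surface)$dist
  sel <- which(d <= max_distance)
  if (length(sel) == 0L)
    stop("no bone faces within max_distance = ", max_distance,
         " mm of the cartilage surface; increase max_distance")
  sub <- f[sel, , drop = FALSE]
  comp <- mesh_face_components(sub)
  areas <- mesh_face_areas(list(vertices = v, faces = sub))
  keep <- comp == as.integer(names(which.max(tapply(areas, comp, sum))))
  sort(sel[keep])
}

#' Fit a regular quadrilateral grid over a surface patch
#'
#' A `nu x nv` node grid is laid over the patch's least-squares plane
#' (spanning the patch footprint) and every node is projected onto the bone
#' surface (closest point on the patch sub-mesh), giving
#' `(nu-1) x (nv-1)` quadrilaterals whose nodes lie on the surface.
#'
#' @param bone a [TriMesh()].
#' @param patch face index set from [select_contact_patch()].
#' @param grid integer `c(nu, nv)` node counts; when `NULL`, derived from
#'   the patch extent and `element_size`.
#' @param element_size target quad edge length in mm (see
#'   [element_size_presets]); used when `grid` is `NULL`.
#' @return A [QuadMesh()].
#' @export
quad_patch <- function(bone, patch, grid = NULL, element_size = 1) {
  stopifnot(inherits(bone, "TriMesh"))
  sub <- mesh_subset_faces(bone, patch)
  pv <- sub$vertices
  ctr <- colMeans(pv)
  ev <- eigen(crossprod(sweep(pv, 2L, ctr)) / nrow(pv), symmetric = TRUE)
  e1 <- ev$vectors[, 1]
  e2 <- ev$vectors[, 2]
  uv <- sweep(pv, 2L, ctr) %*% cbind(e1, e2)
  ru <- range(uv[, 1])
  rv <- range(uv[, 2])
  if (is.null(grid)) {
    grid <- c(max(2L, 1L + ceiling(diff(ru) / element_size)),
              max(2L, 1L + ceiling(diff(rv) / element_size)))
  }
  nu <- as.integer(grid[1])
  nv <- as.integer(grid[2])
  stopifnot(nu >= 2L, nv >= 2L)
  us <- seq(ru[1], ru[2], length.out = nu)
  vs <- seq(rv[1], rv[2], length.out = nv)
  gu <- rep(us, times = nv)
  gv <- rep(vs, each = nu)
  plane_pts <- sweep(outer(gu, e1) + outer(gv, e2), 2L, -ctr)
  cp <- mesh_closest(plane_pts, sub)
  diam <- sqrt(diff(ru)^2 + diff(rv)^2)
  if (mean(cp$dist > diam) > 0.05)
    stop("projection failed for more than 5% of grid nodes")
  nodes <- cp$closest
  # quads: node (i,j) has index i + (j-1)*nu
  qi <- as.vector(outer(seq_len(nu - 1L), (seq_len(nv - 1L) - 1L) * nu, `+`))
  quads <- cbind(qi, qi + 1L, qi + 1L + nu, qi + nu)
  QuadMesh(nodes, quads)
}

quad_normals <- function(qm) {
  v <- qm$vertices
  f <- qm$faces
  d1 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  d2 <- v[f[, 4], , drop = FALSE] - v[f[, 2], , drop = FALSE]
  n <- cbind(d1[, 2] * d2[, 3] - d1[, 3] * d2[, 2],
             d1[, 3] * d2[, 1] - d1[, 1] * d2[, 3],
             d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1])
  0.5 * n  # area-weighted quad normals (cross of diagonals)
}

#' Extrude layered hexahedral cartilage elements from a quad patch
#'
#' Each patch node is carried to the articular surface along its outward
#' area-weighted normal (ray casting; nearest-point fallback when the ray
#' misses), the per-node thickness is floored at `min_thickness`, and the
#' column is divided into `n_layers` equal segments, producing
#' `quads x n_layers` hexahedra.  Interface nodes are the patch nodes
#' verbatim; top-layer nodes lie on the articular surface.
#'
#' @param patch a [QuadMesh()] on the bone surface.
#' @param articular articular cartilage surface [TriMesh()].
#' @param n_layers number of element layers through the thickness.
#' @param min_thickness thickness floor in mm.
#' @return A [HexMesh()] with node sets `bone_interface` and
#'   `articular_surface` and per-layer element sets `layer_1..layer_n`.
#' @export
extrude_cartilage <- function(patch, articular, n_layers = 5,
                              min_thickness = 0.1) {
  stopifnot(inherits(patch, "QuadMesh"), inherits(articular, "TriMesh"))
  np <- nrow(patch$vertices)
  nq <- nrow(patch$faces)
  if (nq == 0L) stop("empty quad patch")
  qn <- quad_normals(patch)
  vn <- matrix(0, np, 3L)
  for (k in 1:4)
    for (d in 1:3)
      vn[, d] <- vn[, d] + tabulate0(patch$faces[, k], qn[, d], np)
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn <- vn / len
  # orient normals toward the articular surface
  cp0 <- mesh_closest(patch$vertices, articular)
  to_art <- cp0$closest - patch$vertices
  if (sum(vn * to_art) < 0) vn <- -vn
  ray <- cpp_ray_mesh(patch$vertices, vn, articular$vertices,
                      articular$faces - 1L)
  thick <- as.numeric(ray$t)
  dirs <- vn
  miss <- thick <= 0
  if (any(miss)) {  # nearest-point fallback
    d <- cp0$dist[miss]
    fallback_dir <- to_art[miss, , drop = FALSE]
    ok <- d > 1e-12
    fallback_dir[ok, ] <- fallback_dir[ok, , drop = FALSE] / d[ok]
    fallback_dir[!ok, ] <- vn[miss, , drop = FALSE][!ok, , drop = FALSE]
    dirs[miss, ] <- fallback_dir
    thick[miss] <- d
  }
  floored <- thick < min_thickness
  if (any(floored)) {
    warning(sum(floored), " node(s) floored to min_thickness = ",
            min_thickness, " mm")
    thick[floored] <- min_thickness
  }
  # orient quads so their right-hand normal points along the extrusion
  quads <- patch$faces
  qn2 <- quad_normals(patch)
  qdir <- (dirs[quads[, 1], ] + dirs[quads[, 2], ] +
           dirs[quads[, 3], ] + dirs[quads[, 4], ]) / 4
  flip <- rowSums(qn2 * qdir) < 0
  quads[flip, ] <- quads[flip, c(1L, 4L, 3L, 2L), drop = FALSE]
  # nodes: layer 0 is the patch verbatim (bit-identical), then layers 1..n
  layers <- lapply(0:n_layers, function(j)
    if (j == 0L) patch$vertices
    else patch$vertices + (j / n_layers) * thick * dirs)
  nodes <- do.call(rbind, layers)
  elements <- do.call(rbind, lapply(seq_len(n_layers), function(j) {
    off_b <- (j - 1L) * np
    off_t <- j * np
    cbind(quads + off_b, quads + off_t)
  }))
  layer_id <- rep(seq_len(n_layers), each = nq)
  HexMesh(nodes, elements, layer_id,
          node_sets = list(bone_interface = seq_len(np),
                           articular_surface = n_layers * np + seq_len(np)),
          element_sets = stats::setNames(
            lapply(seq_len(n_layers), function(j) which(layer_id == j)),
            paste0("layer_", seq_len(n_layers))))
}

# corner-edge triples (1-based local node ids) forming right-handed frames
hex_corner_triples <- list(
  c(2, 4, 5), c(3, 1, 6), c(4, 2, 7), c(1, 3, 8),
  c(8, 6, 1), c(5, 7, 2), c(6, 8, 3), c(7, 5, 4))

#' Hexahedral element quality report
#'
#' Scaled Jacobians at the 8 corners of every element via the trilinear
#' shape-function corner frames, inverted-element count, per-element
#' thickness (mean vertical edge length) and edge aspect ratios.
#'
#' @param mesh a [HexMesh()].
#' @return A `QualityReport` list: `min_scaled_jacobian`, `n_inverted`,
#'   `min_thickness`, `max_thickness`, `max_aspect_ratio`.
#' @export
hex_quality <- function(mesh) {
  stopifnot(inherits(mesh, "HexMesh"))
  ne <- nrow(mesh$elements)
  msj <- numeric(ne)
  inverted <- logical(ne)
  thick <- numeric(ne)
  aspect <- numeric(ne)
  for (e in seq_len(ne)) {
    xyz <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    sj <- vapply(seq_len(8L), function(k) {
      tr <- hex_corner_triples[[k]]
      E <- rbind(xyz[tr[1], ] - xyz[k, ],
                 xyz[tr[2], ] - xyz[k, ],
                 xyz[tr[3], ] - xyz[k, ])
      lens <- sqrt(rowSums(E^2))
      if (any(lens == 0)) return(0)
      det(E) / prod(lens)
    }, numeric(1))
    msj[e] <- min(sj)
    inverted[e] <- any(sj <= 0)
    vert <- sqrt(rowSums((xyz[5:8, ] - xyz[1:4, ])^2))
    thick[e] <- mean(vert)
    edges <- rbind(xyz[c(2, 3, 4, 1), ] - xyz[1:4, ],
                   xyz[c(6, 7, 8, 5), ] - xyz[5:8, ],
                   xyz[5:8, ] - xyz[1:4, ])
    el <- sqrt(rowSums(edges^2))
    aspect[e] <- max(el) / max(min(el), 1e-300)
  }
  structure(list(min_scaled_jacobian = if (ne) min(msj) else NA_real_,
                 n_inverted = sum(inverted),
                 min_thickness = if (ne) min(thick) else NA_real_,
                 max_thickness = if (ne) max(thick) else NA_real_,
                 max_aspect_ratio = if (ne) max(aspect) else NA_real_),
            class = "QualityReport")
}

#' Write a hexahedral mesh as an Abaqus INP deck
#'
#' Emits `*NODE` (1-based ids, mm), `*ELEMENT, TYPE=` blocks plus `*NSET`
#' and `*ELSET` blocks for the stored node/element sets.  The file is
#' re-parseable with [read_inp()].
#'
#' @param mesh a [HexMesh()].
#' @param path output path.
#' @param element_type Abaqus element code (default pore-pressure hex
#'   `C3D8P`).
#' @param part_name part name written to the heading.
#' @export
write_inp <- function(mesh, path, element_type = "C3D8P",
                      part_name = "cartilage") {
  stopifnot(inherits(mesh, "HexMesh"))
  if (nrow(mesh$elements) == 0L) stop("empty hex mesh")
  fmt_ids <- function(ids) {
    rows <- split(ids, ceiling(seq_along(ids) / 16))
    vapply(rows, function(r) paste(r, collapse = ", "), character(1))
  }
  out <- c(paste0("*HEADING"), paste0("** part: ", part_name),
           "*NODE",
           sprintf("%d, %.9g, %.9g, %.9g", seq_len(nrow(mesh$nodes)),
                   mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]),
           sprintf("*ELEMENT, TYPE=%s, ELSET=%s", element_type, part_name),
           sprintf("%d, %s", seq_len(nrow(mesh$elements)),
                   apply(mesh$elements, 1L, paste, collapse = ", ")))
  for (nm in names(mesh$node_sets))
    out <- c(out, sprintf("*NSET, NSET=%s", toupper(nm)),
             fmt_ids(mesh$node_sets[[nm]]))
  for (nm in names(mesh$element_sets))
    out <- c(out, sprintf("*ELSET, ELSET=%s", toupper(nm)),
             fmt_ids(mesh$element_sets[[nm]]))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}

#' Read back an Abaqus INP deck written by [write_inp()]
#'
#' @param path INP file path.
#' @return A [HexMesh()]; layer element sets named `LAYER_k` restore
#'   `layer_id`.
#' @export
read_inp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kw <- grep("^\\*", lines)
  sections <- list()
  for (i in seq_along(kw)) {
    from <- kw[i] + 1L
    to <- if (i < length(kw)) kw[i + 1L] - 1L else length(lines)
    sections[[i]] <- list(header = toupper(lines[kw[i]]),
                          body = if (from <= to) lines[from:to] else character(0))
  }
  nodes <- NULL
  elements <- NULL
  node_sets <- list()
  element_sets <- list()
  for (s in sections) {
    h <- s$header
    body <- s$body[nzchar(trimws(s$body)) & !grepl("^\\*\\*", s$body)]
    if (startsWith(h, "*NODE")) {
      m <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
      nodes <- m[order(m[, 1]), 2:4, drop = FALSE]
    } else if (startsWith(h, "*ELEMENT")) {
      m <- do.call(rbind, lapply(strsplit(body, ","), as.numeric))
      elements <- m[order(m[, 1]), 2:9, drop = FALSE]
    } else if (startsWith(h, "*NSET")) {
      nm <- tolower(sub(".*NSET=([^,]+).*", "\\1", h))
      node_sets[[nm]] <- as.integer(unlist(strsplit(paste(body, collapse = ","),
                                                    ",")))
    } else if (startsWith(h, "*ELSET")) {
      nm <- tolower(sub(".*ELSET=([^,]+).*", "\\1", h))
      element_sets[[nm]] <- as.integer(unlist(strsplit(paste(body,
                                                             collapse = ","),
                                                       ",")))
    }
  }
  if (is.null(nodes) || is.null(elements)) stop("INP missing NODE/ELEMENT")
  layer_sets <- element_sets[grepl("^layer_", names(element_sets))]
  layer_id <- rep(1L, nrow(elements))
  for (nm in names(layer_sets))
    layer_id[layer_sets[[nm]]] <- as.integer(sub("layer_", "", nm))
  HexMesh(nodes, elements, layer_id, node_sets, element_sets)
}

#' Write a hexahedral mesh as legacy VTK unstructured grid (for viewing)
#'
#' @param mesh a [HexMesh()].
#' @param path output `.vtk` path.
#' @export
write_vtk_hex <- function(mesh, path) {
  stopifnot(inherits(mesh, "HexMesh"))
  ne <- nrow(mesh$elements)
  # VTK_HEXAHEDRON ordering equals the C3D8 corner ordering
  out <- c("# vtk DataFile Version 3.0", "bonessm hex mesh", "ASCII",
           "DATASET UNSTRUCTURED_GRID",
           paste("POINTS", nrow(mesh$nodes), "double"),
           fmt_coord(mesh$nodes),
           paste("CELLS", ne, ne * 9L),
           apply(mesh$elements - 1L, 1L, function(r)
             paste(c(8L, r), collapse = " ")),
           paste("CELL_TYPES", ne),
           rep("12", ne))
  writeLines(out, path)
  invisible(path)
}
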