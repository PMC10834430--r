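#' Read a surface mesh from PLY, STL, OFF or VTK
#'
#' ASCII variants of the four formats are supported; coordinates are taken
#' as millimetres.  STL face soup is indexed by merging vertices that agree
#' to 1e-9 mm.  Files whose polygons are all quadrilaterals load as a
#' [QuadMesh()]; all-triangle files load as a [TriMesh()].
#'
#' @param path file path.
#' @param format one of `"PLY"`, `"STL"`, `"OFF"`, `"VTK"`; inferred from the
#'   file extension when `NULL`.
#' @return A `TriMesh` or `QuadMesh`.
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  format <- toupper(format %||% tools::file_ext(path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("empty mesh file: ", path)
  switch(format,
    PLY = read_ply(lines, path),
    STL = read_stl(lines, path),
    OFF = read_off(lines, path),
    VTK = read_vtk(lines, path),
    stop("unsupported mesh format: ", format)
  )
}

#' Write a surface mesh to PLY, STL, OFF or VTK
#'
#' @param mesh a `TriMesh` or `QuadMesh`.
#' @param path output file path.
#' @param format as in [read_mesh()]; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  stopifnot(inherits(mesh, "TriMesh") || inherits(mesh, "QuadMesh"))
  format <- toupper(format %||% tools::file_ext(path))
  is_quad <- inherits(mesh, "QuadMesh")
  if (format == "STL" && is_quad) stop("STL export supports triangle meshes only")
  lines <- switch(format,
    PLY = fmt_ply(mesh),
    STL = fmt_stl(mesh),
    OFF = fmt_off(mesh),
    VTK = fmt_vtk(mesh),
    stop("unsupported mesh format: ", format)
  )
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || !nzchar(a)) b else a

fmt_coord <- function(m) {
  apply(m, 1L, function(r) paste(formatC(r, format = "g", digits = 17),
                                 collapse = " "))
}

build_mesh_from_polys <- function(verts, polys, path) {
  sizes <- vapply(polys, length, integer(1))
  if (all(sizes == 3L)) {
    TriMesh(verts, do.call(rbind, polys))
  } else if (all(sizes == 4L)) {
    QuadMesh(verts, do.call(rbind, polys))
  } else stop("mixed or unsupported polygon sizes in ", path)
}

# ---- PLY -------------------------------------------------------------------

read_ply <- function(lines, path) {
  if (!grepl("^ply", lines[1])) stop("not a PLY file (first line): ", path)
  hdr_end <- match(TRUE, trimws(lines) == "end_header")
  if (is.na(hdr_end)) stop("PLY header without end_header in ", path)
  hdr <- lines[seq_len(hdr_end)]
  if (any(grepl("format\\s+binary", hdr)))
    stop("binary PLY not supported: ", path)
  nv <- as.integer(sub(".*element\\s+vertex\\s+", "",
                       grep("element\\s+vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element\\s+face\\s+", "",
                       grep("element\\s+face", hdr, value = TRUE)[1]))
  if (is.na(nv)) stop("PLY missing vertex element in ", path)
  if (is.na(nf)) nf <- 0L
  body <- lines[(hdr_end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("truncated PLY body in ", path)
  vv <- utils::read.table(text = body[seq_len(nv)])
  verts <- as.matrix(vv[, 1:3])
  polys <- lapply(body[nv + seq_len(nf)], function(l) {
    x <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    n <- x[1]
    if (length(x) < n + 1) stop("malformed PLY face line: ", l)
    as.integer(x[2:(n + 1)]) + 1L
  })
  build_mesh_from_polys(verts, polys, path)
}

fmt_ply <- function(mesh) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  k <- ncol(mesh$faces)
  c("ply", "format ascii 1.0", "comment produced by bonessm",
    paste("element vertex", nv),
    "property double x", "property double y", "property double z",
    paste("element face", nf),
    "property list uchar int vertex_indices",
    "end_header",
    fmt_coord(mesh$vertices),
    apply(mesh$faces, 1L, function(f) paste(c(k, f - 1L), collapse = " ")))
}

# ---- STL (ASCII) -----------------------------------------------------------

read_stl <- function(lines, path) {
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L) stop("no vertex records in STL file ", path)
  if (length(vl) %% 3L != 0L) stop("STL vertex count not a multiple of 3 in ", path)
  co <- do.call(rbind, lapply(vl, function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4])))
  # deduplicate within 1e-9 mm
  key <- apply(round(co / 1e-9) * 1e-9, 1L, paste, collapse = "|")
  uid <- !duplicated(key)
  verts <- co[uid, , drop = FALSE]
  idx <- match(key, key[uid])
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  TriMesh(verts, faces)
}

fmt_stl <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- mesh_face_normals(mesh)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  out <- character(2L + 7L * nrow(f))
  out[1] <- "solid bonessm"
  line3 <- function(prefix, m) paste(prefix, fmt_coord(m))
  body <- rbind(paste("  facet normal", fmt_coord(n)),
                "    outer loop",
                line3("      vertex", v[f[, 1], , drop = FALSE]),
                line3("      vertex", v[f[, 2], , drop = FALSE]),
                line3("      vertex", v[f[, 3], , drop = FALSE]),
                "    endloop",
                "  endfacet")
  c("solid bonessm", as.vector(body), "endsolid bonessm")
}

# ---- OFF -------------------------------------------------------------------

read_off <- function(lines, path) {
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (!grepl("^OFF", trimws(lines[1]))) stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]
  nf <- counts[2]
  verts <- as.matrix(utils::read.table(text = lines[2L + seq_len(nv)]))[, 1:3]
  polys <- lapply(lines[2L + nv + seq_len(nf)], function(l) {
    x <- as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    as.integer(x[2:(x[1] + 1)]) + 1L
  })
  build_mesh_from_polys(verts, polys, path)
}

fmt_off <- function(mesh) {
  k <- ncol(mesh$faces)
  c("OFF",
    paste(nrow(mesh$vertices), nrow(mesh$faces), 0),
    fmt_coord(mesh$vertices),
    apply(mesh$faces, 1L, function(f) paste(c(k, f - 1L), collapse = " ")))
}

# ---- VTK legacy polydata ---------------------------------------------------

read_vtk <- function(lines, path) {
  ip <- grep("^POINTS", lines)
  if (length(ip) == 0L) stop("no POINTS section in VTK file ", path)
  np <- as.integer(strsplit(trimws(lines[ip[1]]), "\\s+")[[1]][2])
  # points may wrap across lines: read numbers until np*3 collected
  nums <- numeric(0)
  i <- ip[1] + 1L
  while (length(nums) < 3L * np) {
    nums <- c(nums, as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    i <- i + 1L
  }
  verts <- matrix(nums[seq_len(3L * np)], ncol = 3L, byrow = TRUE)
  ic <- grep("^POLYGONS", lines)
  if (length(ic) == 0L) stop("no POLYGONS section in VTK file ", path)
  nc <- as.integer(strsplit(trimws(lines[ic[1]]), "\\s+")[[1]][2])
  polys <- lapply(lines[ic[1] + seq_len(nc)], function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    x[2:(x[1] + 1)] + 1L
  })
  build_mesh_from_polys(verts, polys, path)
}

fmt_vtk <- function(mesh) {
  k <- ncol(mesh$faces)
  nf <- nrow(mesh$faces)
  c("# vtk DataFile Version 3.0",
    "bonessm surface", "ASCII", "DATASET POLYDATA",
    paste("POINTS", nrow(mesh$vertices), "double"),
    fmt_coord(mesh$vertices),
    paste("POLYGONS", nf, nf * (k + 1L)),
    apply(mesh$faces, 1L, function(f) paste(c(k, f - 1L), collapse = " ")))
}

# ---- NIfTI masks -----------------------------------------------------------

#' Read a binary segmentation mask from a NIfTI file
#'
#' Any nonzero label maps to foreground.  Spacing and origin are taken from
#' the header affine, which must be orthogonal and axis-aligned (axis flips
#' are folded into the stored array so spacing stays positive).
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @return A [VoxelMask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  A <- xf[1:3, 1:3]
  off_diag <- A
  diag(off_diag) <- 0
  if (any(abs(off_diag) > 1e-6 * max(abs(A))))
    stop("non-orthogonal or oblique NIfTI affine is not supported")
  vals <- as.array(img)
  if (length(dim(vals)) > 3L) dim(vals) <- dim(vals)[1:3]
  spacing <- abs(diag(A))
  origin <- xf[1:3, 4]
  for (ax in 1:3) {
    if (diag(A)[ax] < 0) {  # flip axis so stored spacing is positive
      vals <- flip_axis(vals, ax)
      origin[ax] <- origin[ax] + (dim(vals)[ax] - 1L) * diag(A)[ax]
    }
  }
  m <- VoxelMask(vals, spacing, origin)
  if (sum(m$values) == 0L)
    warning("mask has no foreground voxels: ", path)
  m
}

flip_axis <- function(a, ax) {
  idx <- lapply(dim(a), seq_len)
  idx[[ax]] <- rev(idx[[ax]])
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Write a [VoxelMask()] to a NIfTI file
#'
#' @param mask a `VoxelMask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "VoxelMask"))
  img <- RNifti::asNifti(array(as.double(mask$values), dim = dim(mask$values)))
  RNifti::pixdim(img) <- mask$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- mask$spacing
  aff[1:3, 4] <- mask$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
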