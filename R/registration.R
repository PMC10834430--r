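#' Similarity transform (rotation, translation, scale)
#'
#' Applies as `x -> scale * R x + translation`.
#'
#' @param rotation 3 x 3 rotation matrix, `det = +1`.
#' @param translation length-3 numeric (mm).
#' @param scale positive scalar.
#' @return An object of class `SimilarityTransform`.
#' @export
SimilarityTransform <- function(rotation = diag(3), translation = c(0, 0, 0),
                                scale = 1) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L,
            length(scale) == 1L)
  if (scale <= 0) stop("scale must be positive")
  if (abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be a proper rotation (det = +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = as.numeric(scale)), class = "SimilarityTransform")
}

#' Apply a [SimilarityTransform()] to points
#'
#' @param transform a `SimilarityTransform`.
#' @param points N x 3 matrix.
#' @return Transformed N x 3 matrix.
#' @export
apply_similarity <- function(transform, points) {
  points <- as.matrix(points)
  sweep(transform$scale * points %*% t(transform$rotation), 2L,
        -transform$translation)
}

#' Invert a [SimilarityTransform()]
#' @param transform a `SimilarityTransform`.
#' @return The inverse `SimilarityTransform`.
#' @export
invert_similarity <- function(transform) {
  Rinv <- t(transform$rotation)
  SimilarityTransform(Rinv, -Rinv %*% transform$translation / transform$scale,
                      1 / transform$scale)
}

#' Compose two similarity transforms (`a` after `b`)
#' @param a,b `SimilarityTransform` objects.
#' @return `SimilarityTransform` equal to `x -> a(b(x))`.
#' @export
compose_similarity <- function(a, b) {
  SimilarityTransform(a$rotation %*% b$rotation,
                      a$scale * a$rotation %*% b$translation + a$translation,
                      a$scale * b$scale)
}

as_points <- function(x) {
  if (inherits(x, "SurfacePointSet")) x$points
  else if (inherits(x, "TriMesh")) x$vertices
  else as.matrix(x)
}

#' Coarse similarity alignment by centroid, centroid size and principal axes
#'
#' Maps `moving` so that its centroid, centroid size (RMS distance to the
#' centroid) and principal axes match those of `reference`.  Principal-axis
#' sign ambiguity is resolved by matching third moments along each axis;
#' reflections are forbidden.
#'
#' @param moving,reference point sets ([SurfacePointSet()] or N x 3 matrices).
#' @return A [SimilarityTransform()] mapping `moving` onto `reference`.
#' @export
coarse_align <- function(moving, reference) {
  X <- as_points(moving)
  Y <- as_points(reference)
  if (nrow(X) < 4L || nrow(Y) < 4L) stop("need at least 4 points per set")
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx)
  Yc <- sweep(Y, 2L, cy)
  sx <- sqrt(mean(rowSums(Xc^2)))
  sy <- sqrt(mean(rowSums(Yc^2)))
  ex <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  ey <- eigen(crossprod(Yc) / nrow(Yc), symmetric = TRUE)
  if (ex$values[3] < 1e-10 * ex$values[1] || ey$values[3] < 1e-10 * ey$values[1])
    stop("degenerate (coplanar or collinear) point set")
  skew <- function(Z, E) apply(Z %*% E, 2L, function(u) mean(u^3))
  kx <- skew(Xc, ex$vectors)
  ky <- skew(Yc, ey$vectors)
  signs <- ifelse(kx * ky >= 0, 1, -1)
  R <- ey$vectors %*% diag(signs) %*% t(ex$vectors)
  if (det(R) < 0) {
    weakest <- which.min(abs(ky))
    signs[weakest] <- -signs[weakest]
    R <- ey$vectors %*% diag(signs) %*% t(ex$vectors)
  }
  s <- sy / sx
  SimilarityTransform(R, cy - s * R %*% cx, s)
}

# ---------------------------------------------------------------------------
# Coherent point drift
# ---------------------------------------------------------------------------

cpd_init_sigma2 <- function(X, Y) {
  N <- nrow(X)
  M <- nrow(Y)
  sx <- colSums(X)
  sy <- colSums(Y)
  (M * sum(X^2) + N * sum(Y^2) - 2 * sum(sx * sy)) / (3 * N * M)
}

#' Rigid/similarity coherent point drift registration
#'
#' EM over a Gaussian mixture whose centroids are the (similarity
#' transformed) source points, with a uniform outlier component of weight
#' `w`.  Iterates until the relative change of the negative log-likelihood
#' drops below `tol`.
#'
#' @param source,target point sets ([SurfacePointSet()] or N x 3 matrices);
#'   the source is moved onto the target.
#' @param w uniform outlier weight in `[0, 1)`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param scale estimate a scale factor (`TRUE`, similarity) or keep scale
#'   fixed at 1 (strict rigid).
#' @return A [SimilarityTransform()] with attributes `sigma2`, `iterations`
#'   and `converged`.
#' @export
cpd_rigid <- function(source, target, w = 0.1, tol = 1e-6, max_iter = 150,
                      scale = TRUE) {
  Y0 <- as_points(source)
  X <- as_points(target)
  if (nrow(Y0) < 4L || nrow(X) < 4L) stop("need at least 4 points per set")
  sigma2 <- cpd_init_sigma2(X, Y0)
  R <- diag(3)
  s <- 1
  t0 <- c(0, 0, 0)
  L_old <- Inf
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    TY <- sweep(s * Y0 %*% t(R), 2L, -t0)
    e <- cpp_cpd_estep(X, TY, sigma2, w)
    e$P1 <- as.numeric(e$P1)
    e$Pt1 <- as.numeric(e$Pt1)
    Np <- sum(e$P1)
    if (Np < 1e-12) break
    mu_x <- colSums(X * e$Pt1) / Np
    mu_y <- colSums(Y0 * e$P1) / Np
    A <- t(e$PX) %*% Y0 - Np * outer(mu_x, mu_y)
    sv <- svd(A)
    C <- diag(c(1, 1, det(sv$u %*% t(sv$v))))
    R <- sv$u %*% C %*% t(sv$v)
    yPy <- sum(e$P1 * rowSums(Y0^2)) - Np * sum(mu_y^2)
    xPx <- sum(e$Pt1 * rowSums(X^2)) - Np * sum(mu_x^2)
    trAR <- sum(diag(t(A) %*% R))
    s <- if (scale) trAR / yPy else 1
    t0 <- mu_x - s * R %*% mu_y
    sigma2 <- max((xPx - s * trAR) / (3 * Np), 1e-12)
    if (sigma2 <= 1e-11) {
      converged <- TRUE
      break
    }
    if (is.finite(L_old) && abs(L_old - e$L) < tol * abs(e$L)) {
      converged <- TRUE
      break
    }
    L_old <- e$L
  }
  if (!converged && iters == max_iter)
    warning("cpd_rigid did not converge within max_iter; returning best-so-far")
  out <- SimilarityTransform(R, t0, s)
  attr(out, "sigma2") <- sigma2
  attr(out, "iterations") <- iters
  attr(out, "converged") <- converged
  out
}

#' Non-rigid coherent point drift registration
#'
#' Displacement field `v = G W` over the source points with Gaussian kernel
#' width `beta` and motion-coherence penalty `lam * tr(W' G W)`.  Clouds are
#' centred and scaled to unit RMS internally; the displaced source is
#' returned in original units (the target frame).
#'
#' @inheritParams cpd_rigid
#' @param beta Gaussian kernel width in unit-RMS normalized coordinates.
#' @param lam motion-coherence regularization weight.
#' @return List with `points` (displaced source, N x 3), `sigma2`,
#'   `iterations`, `converged`.
#' @export
cpd_nonrigid <- function(source, target, beta = 2.0, lam = 3.0, w = 0.1,
                         tol = 1e-6, max_iter = 150) {
  Y0 <- as_points(source)
  X0 <- as_points(target)
  if (nrow(Y0) < 4L || nrow(X0) < 4L) stop("need at least 4 points per set")
  cy <- colMeans(Y0)
  cx <- colMeans(X0)
  sc <- sqrt(mean(rowSums(sweep(X0, 2L, cx)^2)))
  Y <- sweep(Y0, 2L, cy) / sc
  X <- sweep(X0, 2L, cx) / sc
  M <- nrow(Y)
  D2 <- as.matrix(stats::dist(Y))^2
  G <- exp(-D2 / (2 * beta^2))
  sigma2 <- cpd_init_sigma2(X, Y)
  TY <- Y
  L_old <- Inf
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    e <- cpp_cpd_estep(X, TY, sigma2, w)
    e$P1 <- as.numeric(e$P1)
    e$Pt1 <- as.numeric(e$Pt1)
    Np <- sum(e$P1)
    if (Np < 1e-12) break
    A <- e$P1 * G
    diag(A) <- diag(A) + lam * sigma2
    B <- e$PX - e$P1 * Y
    W <- solve(A, B)
    TY <- Y + G %*% W
    xPx <- sum(e$Pt1 * rowSums(X^2))
    trPXT <- sum(e$PX * TY)
    trTdT <- sum(e$P1 * rowSums(TY^2))
    sigma2 <- max((xPx - 2 * trPXT + trTdT) / (3 * Np), 1e-12)
    if (sigma2 <= 1e-11) {
      converged <- TRUE
      break
    }
    if (is.finite(L_old) && abs(L_old - e$L) < tol * abs(e$L)) {
      converged <- TRUE
      break
    }
    L_old <- e$L
  }
  if (!converged && iters == max_iter)
    warning("cpd_nonrigid did not converge within max_iter; returning best-so-far")
  list(points = sweep(TY * sc, 2L, -cx), sigma2 = sigma2,
       iterations = iters, converged = converged)
}

# ---------------------------------------------------------------------------
# Generalized Procrustes analysis (rigid-only)
# ---------------------------------------------------------------------------

# optimal Q (right-multiplication, rows are points) minimizing ||A Q - B||
# for centered A, B (Kabsch)
kabsch_rotation <- function(A, B) {
  sv <- svd(crossprod(A, B))
  d <- det(sv$u %*% t(sv$v))
  sv$u %*% diag(c(1, 1, sign(d))) %*% t(sv$v)
}

#' Generalized Procrustes analysis over corresponded point sets
#'
#' Iteratively aligns each set to the evolving mean by rotation and
#' translation only (no scaling: absolute size is preserved), until the
#' mean stabilizes.  The objective (sum of squared deviations from the
#' mean) is non-increasing across iterations.
#'
#' @param sets list of K x 3 matrices in point-wise correspondence.
#' @param tol mean-movement convergence tolerance (RMS mm).
#' @param max_iter maximum iterations.
#' @return A `CorrespondedSets` list with `sets` (aligned), `mean` and the
#'   per-iteration `objective` trace.
#' @export
gpa <- function(sets, tol = 1e-8, max_iter = 100) {
  sets <- lapply(sets, as_points)
  if (length(sets) < 2L) stop("need at least 2 sets")
  K <- nrow(sets[[1]])
  if (any(vapply(sets, nrow, integer(1)) != K))
    stop("all sets must have the same number of points")
  # translation: optimal alignment centers every set at the origin
  sets <- lapply(sets, function(S) sweep(S, 2L, colMeans(S)))
  m <- Reduce(`+`, sets) / length(sets)
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    sets <- lapply(sets, function(S) S %*% kabsch_rotation(S, m))
    m_new <- Reduce(`+`, sets) / length(sets)
    objective <- c(objective,
                   sum(vapply(sets, function(S) sum((S - m_new)^2), numeric(1))))
    if (sqrt(mean((m_new - m)^2)) < tol) {
      m <- m_new
      break
    }
    m <- m_new
  }
  structure(list(sets = sets, mean = m, objective = objective),
            class = "CorrespondedSets")
}

# ---------------------------------------------------------------------------
# Thin-plate splines, 3-D kernel U(r) = r
# ---------------------------------------------------------------------------

#' Fit a thin-plate-spline transform between landmark sets
#'
#' Solves the standard bordered TPS system with kernel `U(r) = r` (3-D
#' biharmonic spline), decomposing the mapping into an affine part plus
#' non-rigid kernel weights.  With `lam_tps = 0` the transform interpolates
#' the landmarks exactly; as `lam_tps` grows it tends to the best affine fit.
#'
#' @param source_landmarks,target_landmarks K x 3 matrices, K >= 4,
#'   non-coplanar sources.
#' @param lam_tps regularization weight (>= 0) on the kernel block.
#' @return An object of class `TPSTransform` with `control_points`, `affine`
#'   (`matrix` 3 x 3 and `translation`), `weights` (K x 3) and
#'   `regularization`.
#' @export
tps_fit <- function(source_landmarks, target_landmarks, lam_tps = 0.0) {
  S <- as_points(source_landmarks)
  Tm <- as_points(target_landmarks)
  K <- nrow(S)
  if (K < 4L) stop("need at least 4 landmarks")
  if (nrow(Tm) != K) stop("landmark sets differ in size")
  if (lam_tps < 0) stop("lam_tps must be >= 0")
  P <- cbind(1, S)
  if (qr(P)$rank < 4L) stop("source landmarks are coplanar")
  U <- as.matrix(stats::dist(S))
  L <- rbind(cbind(U + diag(lam_tps, K), P),
             cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(Tm, matrix(0, 4L, 3L))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular TPS system (coincident landmarks?)"))
  structure(list(control_points = S,
                 affine = list(matrix = t(sol[K + 2:4, , drop = FALSE]),
                               translation = as.numeric(sol[K + 1L, ])),
                 weights = sol[seq_len(K), , drop = FALSE],
                 regularization = lam_tps),
            class = "TPSTransform")
}

#' Apply a [tps_fit()] transform to points
#'
#' @param transform a `TPSTransform`.
#' @param points N x 3 matrix.
#' @return Warped N x 3 matrix.
#' @export
tps_apply <- function(transform, points) {
  X <- as_points(points)
  C <- transform$control_points
  # pairwise distances points x controls
  D2 <- outer(rowSums(X^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(X)), rowSums(C^2)) - 2 * X %*% t(C)
  D2[D2 < 0] <- 0
  U <- sqrt(D2)
  aff <- X %*% t(transform$affine$matrix)
  sweep(aff + U %*% transform$weights, 2L, -transform$affine$translation)
}

# ---------------------------------------------------------------------------
# Transform serialization (JSON named-array container)
# ---------------------------------------------------------------------------

#' Save or load registration transforms
#'
#' Transforms serialize to a JSON named-array container; point sets to CSV
#' with columns x, y, z (mm).
#'
#' @param transform a `SimilarityTransform` or `TPSTransform`.
#' @param path file path.
#' @return `save_transform` returns `path` invisibly; `load_transform` the
#'   restored transform.
#' @export
save_transform <- function(transform, path) {
  if (inherits(transform, "SimilarityTransform")) {
    obj <- list(type = "similarity", rotation = transform$rotation,
                translation = transform$translation, scale = transform$scale)
  } else if (inherits(transform, "TPSTransform")) {
    obj <- list(type = "tps", control_points = transform$control_points,
                affine_matrix = transform$affine$matrix,
                affine_translation = transform$affine$translation,
                weights = transform$weights,
                regularization = transform$regularization)
  } else stop("unsupported transform class")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_transform
#' @export
load_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "similarity")) {
    SimilarityTransform(obj$rotation, obj$translation, obj$scale)
  } else if (identical(obj$type, "tps")) {
    structure(list(control_points = as.matrix(obj$control_points),
                   affine = list(matrix = as.matrix(obj$affine_matrix),
                                 translation = as.numeric(obj$affine_translation)),
                   weights = as.matrix(obj$weights),
                   regularization = obj$regularization),
              class = "TPSTransform")
  } else stop("unknown transform type in ", path)
}

#' Write/read a point set as CSV (columns x, y, z in mm)
#' @param points a [SurfacePointSet()] or N x 3 matrix.
#' @param path file path.
#' @export
write_points_csv <- function(points, path) {
  p <- as_points(points)
  utils::write.csv(data.frame(x = p[, 1], y = p[, 2], z = p[, 3]), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path) {
  d <- utils::read.csv(path)
  SurfacePointSet(as.matrix(d[, c("x", "y", "z")]), path)
}
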