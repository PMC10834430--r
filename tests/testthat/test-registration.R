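# shared anisotropic, skewed test cloud (unambiguous principal axes)
reg_cloud <- function(n = 120, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(3 * n), ncol = 3)
  X[, 1] <- 3 * X[, 1] + 0.1 * X[, 1]^2
  X[, 2] <- 2 * X[, 2] + 0.05 * X[, 2]^3
  X
}

test_that("coarse alignment recovers similarity transforms and the identity", {
  X <- reg_cloud()
  ca <- coarse_align(X, X)
  expect_lt(max(abs(ca$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(ca$translation)), 1e-9)
  expect_equal(ca$scale, 1)

  R0 <- rot_axis(c(0, 0, 1), 30 * pi / 180)
  Y <- 1.5 * X %*% t(R0) + matrix(rep(c(5, 0, 0), each = nrow(X)), ncol = 3)
  ca2 <- coarse_align(X, Y)
  expect_lt(max(abs(apply_similarity(ca2, X) - Y)), 1e-6)
})

test_that("coarse alignment rejects coplanar point sets", {
  X <- reg_cloud()
  X[, 3] <- 0
  expect_error(coarse_align(X, reg_cloud()), "degenerate")
})

test_that("rigid CPD recovers known motions, with and without outliers", {
  X <- reg_cloud()
  R1 <- rot_axis(c(0.3, -1, 2), 25 * pi / 180)
  Y <- X %*% t(R1) + matrix(rep(c(3, -2, 1), each = nrow(X)), ncol = 3)
  tf <- cpd_rigid(X, Y)
  expect_lt(geodesic_angle(tf$rotation, R1), 1e-3)
  expect_equal(tf$scale, 1, tolerance = 1e-4)

  set.seed(7)
  Yout <- rbind(Y[seq_len(108), ], matrix(runif(36, -6, 6), ncol = 3))
  tf2 <- cpd_rigid(X, Yout, w = 0.1)
  expect_lt(geodesic_angle(tf2$rotation, R1), 1e-2)

  tf3 <- cpd_rigid(X, X)
  expect_lt(geodesic_angle(tf3$rotation, diag(3)), 1e-6)
  expect_lt(max(abs(tf3$translation)), 1e-6)
})

test_that("rigid CPD is equivariant under a common rotation", {
  X <- reg_cloud()
  R1 <- rot_axis(c(0.3, -1, 2), 25 * pi / 180)
  Y <- X %*% t(R1) + matrix(rep(c(3, -2, 1), each = nrow(X)), ncol = 3)
  Q <- rot_axis(c(1, 1, 0), 0.7)
  t1 <- suppressWarnings(cpd_rigid(X, Y))
  t2 <- suppressWarnings(cpd_rigid(X %*% t(Q), Y %*% t(Q)))
  expect_lt(max(abs(t2$rotation - Q %*% t1$rotation %*% t(Q))), 1e-4)
})

test_that("non-rigid CPD recovers smooth warps and respects the penalty limit", {
  X <- reg_cloud(200)
  scale <- max(apply(X, 2, function(c3) diff(range(c3))))
  warp <- X + 0.05 * scale * cbind(sin(2 * pi * X[, 2] / scale),
                                   sin(2 * pi * X[, 3] / scale),
                                   sin(2 * pi * X[, 1] / scale))
  pre <- mean(sqrt(rowSums((X - warp)^2)))
  nr <- cpd_nonrigid(X, warp)
  post <- mean(sqrt(rowSums((nr$points - warp)^2)))
  expect_lt(post, 0.2 * pre)

  ident <- cpd_nonrigid(X, X)
  expect_lt(max(abs(ident$points - X)) / scale, 1e-6)

  # penalty limit: deformation is strongly suppressed at very large lam
  disp <- vapply(c(3, 1e3, 1e6), function(l) {
    r <- suppressWarnings(cpd_nonrigid(X, warp, lam = l))
    max(sqrt(rowSums((r$points - X)^2)))
  }, numeric(1))
  expect_lt(disp[3], disp[2])
  expect_lt(disp[3], 0.05 * disp[1])
  expect_lt(disp[3] / scale, 5e-3)
})

test_that("GPA collapses rigid scatter exactly and decreases its objective", {
  set.seed(12)
  shp <- matrix(rnorm(30), ncol = 3)
  sets <- lapply(1:3, function(i)
    shp %*% t(rot_axis(rnorm(3), runif(1, 0, 2))) +
      matrix(rep(rnorm(3, 0, 5), each = 10), ncol = 3))
  g <- gpa(sets)
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(sqrt(mean((g$sets[[i]] - g$sets[[j]])^2)), 1e-9)
  expect_true(all(diff(g$objective) <= 1e-9))

  # fixed point: aligned sets stay put
  g2 <- gpa(g$sets)
  for (i in 1:3)
    expect_lt(max(abs(g2$sets[[i]] - g$sets[[i]])), 1e-6)

  expect_error(gpa(list(shp, shp[1:5, ])), "same number")
})

test_that("GPA beats naive centroid-only alignment on jittered shapes", {
  set.seed(3)
  shp <- matrix(rnorm(60), ncol = 3) * 4
  sets <- lapply(1:10, function(i)
    (shp + matrix(rnorm(60, 0, 0.3), ncol = 3)) %*%
      t(rot_axis(rnorm(3), runif(1, 0, 1))) +
      matrix(rep(rnorm(3, 0, 2), each = 20), ncol = 3))
  g <- gpa(sets)
  obj_gpa <- utils::tail(g$objective, 1)
  centered <- lapply(sets, function(S) sweep(S, 2, colMeans(S)))
  m <- Reduce(`+`, centered) / length(centered)
  obj_naive <- sum(vapply(centered, function(S) sum((S - m)^2), numeric(1)))
  expect_lte(obj_gpa, obj_naive)
})

test_that("TPS interpolates landmarks and reproduces affine maps exactly", {
  set.seed(21)
  S <- matrix(rnorm(45), ncol = 3)
  A <- matrix(rnorm(9), 3, 3) + diag(3)
  tv <- c(1, -2, 0.5)
  Tgt <- S %*% t(A) + matrix(rep(tv, each = 15), ncol = 3)
  tp <- tps_fit(S, Tgt)
  expect_lt(max(abs(tp$weights)), 1e-8)
  expect_lt(max(abs(tps_apply(tp, S) - Tgt)), 1e-8)
  # affine linearity: midpoints map to midpoints
  mid <- (S[1, ] + S[2, ]) / 2
  expect_lt(max(abs(tps_apply(tp, rbind(mid)) - (Tgt[1, ] + Tgt[2, ]) / 2)),
            1e-8)

  bend <- S + 0.3 * cbind(sin(S[, 1]), cos(S[, 2]), sin(S[, 3]))
  tp2 <- tps_fit(S, bend)
  expect_lt(max(abs(tps_apply(tp2, S) - bend)), 1e-8)
  # side conditions: weights orthogonal to [1 | control points]
  expect_lt(max(abs(t(tp2$weights) %*% cbind(1, S))), 1e-8)

  tp3 <- tps_fit(S, S)
  expect_lt(max(abs(tp3$affine$matrix - diag(3))), 1e-8)
  expect_lt(max(abs(tp3$weights)), 1e-8)
})

test_that("large TPS regularization tends to the best affine fit", {
  set.seed(2)
  S <- matrix(rnorm(60), ncol = 3)
  bend <- S + 0.5 * cbind(sin(S[, 1]), cos(S[, 2]), sin(S[, 3]))
  tp <- tps_fit(S, bend, lam_tps = 1e8)
  expect_lt(max(abs(tp$weights)), 1e-6)
})

test_that("TPS rejects degenerate landmark configurations", {
  S <- matrix(rnorm(45), ncol = 3)
  flat <- S
  flat[, 3] <- 1
  expect_error(tps_fit(flat, S), "coplanar")
  expect_error(tps_fit(S[1:3, ], S[1:3, ]), "4 landmarks")
})

test_that("transforms serialize and restore through the JSON container", {
  tf <- SimilarityTransform(rot_axis(c(1, 2, 3), 0.4), c(1, -2, 3), 1.2)
  p1 <- tempfile(fileext = ".json")
  save_transform(tf, p1)
  tf2 <- load_transform(p1)
  expect_equal(tf2$rotation, tf$rotation, tolerance = 1e-12)
  expect_equal(tf2$translation, tf$translation)
  expect_equal(tf2$scale, tf$scale)

  S <- matrix(rnorm(45), ncol = 3)
  tp <- tps_fit(S, S + 0.2 * sin(S))
  p2 <- tempfile(fileext = ".json")
  save_transform(tp, p2)
  tp2 <- load_transform(p2)
  X <- matrix(rnorm(30), ncol = 3)
  expect_equal(tps_apply(tp2, X), tps_apply(tp, X), tolerance = 1e-12)

  ps <- SurfacePointSet(S)
  p3 <- tempfile(fileext = ".csv")
  write_points_csv(ps, p3)
  expect_equal(read_points_csv(p3)$points, S, tolerance = 1e-12,
               ignore_attr = TRUE)
})
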