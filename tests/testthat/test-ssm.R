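test_that("two-sample PCA matches the closed-form single-mode solution", {
  s1 <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), ncol = 3, byrow = TRUE)
  s2 <- s1 * 1.2
  corr <- structure(list(sets = list(s1, s2), mean = (s1 + s2) / 2),
                    class = "CorrespondedSets")
  m <- build_ssm(corr, variance_fraction = 1.0)
  expect_length(m$components, 1L)
  # variance of a 2-point PCA: each sample is ||s_i - mean|| from the mean,
  # eigenvalue = sum of squared deviations / (n - 1) = 2 * ||d||^2 / 1
  d <- as.vector(s1 - (s1 + s2) / 2)
  expect_equal(m$variances[1], 2 * sum(d^2) / 1, tolerance = 1e-12)
  # component is the unit vector along the difference
  expect_equal(abs(sum(as.vector(m$components[[1]]) * d / sqrt(sum(d^2)))), 1,
               tolerance = 1e-12)
  expect_error(build_ssm(corr, variance_fraction = 0), "variance_fraction")
})

test_that("shape instances follow the linear generative model exactly", {
  fx <- fixture_small_ssm()
  m <- fx$model
  expect_equal(ssm_instance(m, numeric(0)), m$mean)
  b1 <- c(2, -1)
  b2 <- c(-0.5, 3)
  i1 <- ssm_instance(m, b1)
  i2 <- ssm_instance(m, b2)
  lin <- ssm_instance(m, 0.3 * b1 + 0.7 * b2)
  expect_equal(lin, m$mean + 0.3 * (i1 - m$mean) + 0.7 * (i2 - m$mean),
               tolerance = 1e-9)
  # symmetry: instance(b) + instance(-b) = 2 * mean
  expect_equal(i1 + ssm_instance(m, -b1), 2 * m$mean, tolerance = 1e-9)
  expect_error(ssm_instance(m, rep(1, 50)), "weights")
})

test_that("components are orthonormal and training shapes reconstruct", {
  fx <- fixture_small_ssm()
  m <- fx$model
  PC <- vapply(m$components, as.vector, numeric(3L * nrow(m$mean)))
  G <- crossprod(PC)
  expect_lt(max(abs(G - diag(ncol(PC)))), 1e-8)
  expect_true(all(diff(m$variances) <= 1e-9))
  # full-rank reconstruction of a training member
  x <- as.vector(fx$aligned$sets[[3]])
  mu <- as.vector(m$mean)
  rec <- mu + PC %*% crossprod(PC, x - mu)
  scale <- sqrt(mean(x^2))
  expect_lt(sqrt(mean((rec - x)^2)) / scale, 1e-9)
})

test_that("correspondence returns identical K across samples and checks input", {
  fx <- fixture_small_ssm()
  K <- vapply(fx$corr$sets, nrow, integer(1))
  expect_true(all(K == K[1]))
  # non-manifold sample is refused with its index in the message
  bad <- fx$pop$meshes[[1]]
  bad$faces <- rbind(bad$faces, bad$faces[1, c(1, 3, 2)] )
  expect_error(suppressWarnings(
    correspond(fx$template, list(fx$pop$meshes[[2]], bad), n_points = 350)),
    "sample 2")
})

test_that("groupwise refinement lowers off-model variance, points on-surface", {
  fx <- fixture_small_ssm()
  sets <- refine_correspondence(fx$corr$sets, fx$pop$meshes[seq_len(8)],
                                max_iter = 4)
  trace <- attr(sets, "off_model")
  expect_true(all(diff(trace) <= 0))
  d <- bonessm:::mesh_closest(sets[[5]], fx$pop$meshes[[5]])$dist
  expect_lt(max(d), 1e-8)
})

test_that("rigidly scattered template copies collapse after GPA", {
  fx <- fixture_small_ssm()
  tpl <- fx$template
  set.seed(77)
  copies <- lapply(1:3, function(i)
    TriMesh(tpl$vertices %*% t(rot_axis(rnorm(3), runif(1, 0, 0.8))) +
              matrix(rep(rnorm(3, 0, 10), each = nrow(tpl$vertices)),
                     ncol = 3), tpl$faces))
  corr <- suppressWarnings(correspond(tpl, copies, n_points = 300, seed = 2))
  # an exact zero-mode correspondence exists; the groupwise refinement with
  # no retained modes finds it to machine precision
  sets <- refine_correspondence(corr$sets, copies, d = 0, max_iter = 400,
                                tol = 1e-6)
  al <- gpa(sets)
  scale <- sqrt(mean(al$mean^2))
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(sqrt(mean((al$sets[[i]] - al$sets[[j]])^2)) / scale, 1e-3)
})

test_that("instance meshes keep the template connectivity and affine maps", {
  fx <- fixture_small_ssm()
  m <- fx$model
  im <- instance_mesh(m, m$mean)
  expect_identical(im$faces, m$template_mesh$faces)
  expect_lt(max(abs(im$vertices - m$template_mesh$vertices)), 1e-6)
  # similarity-transformed mean reproduces a transformed template (TPS
  # reproduces affine maps)
  tf <- SimilarityTransform(rot_axis(c(1, 0.5, 2), 0.3), c(4, -2, 1), 1.1)
  im2 <- instance_mesh(m, apply_similarity(tf, m$mean))
  expect_lt(max(abs(im2$vertices -
                    apply_similarity(tf, m$template_mesh$vertices))), 1e-6)
})

test_that("fitting the model to its own mean shape returns near-zero modes", {
  fx <- fixture_small_ssm()
  m <- fx$model
  target <- instance_mesh(m, m$mean)
  fit <- suppressWarnings(ssm_fit(m, target, tol = 1e-3, seed = 3))
  expect_lt(fit$residual_rms, 0.5)
  expect_lt(max(abs(fit$b) / sqrt(m$variances)), 0.25)
})

test_that("known mode weights are recovered from noiseless instances", {
  fx <- fixture_small_ssm()
  m <- fx$model
  sds <- sqrt(m$variances[1:2])
  set.seed(15)
  bs <- NULL
  hats <- NULL
  for (i in 1:4) {
    b_true <- c(runif(1, -1.5, 1.5) * sds[1], runif(1, -1.5, 1.5) * sds[2])
    target <- instance_mesh(m, ssm_instance(m, b_true))
    fit <- suppressWarnings(ssm_fit(m, target, lam_b = 1e-6, polish = TRUE,
                                    seed = i))
    bs <- c(bs, b_true)
    hats <- c(hats, fit$b[1:2])
  }
  expect_gt(cor(bs, hats), 0.99)
  expect_lt(sqrt(mean((hats - bs)^2)) / sqrt(mean(bs^2)), 0.05)
})

test_that("models serialize to JSON and restore", {
  fx <- fixture_small_ssm()
  path <- tempfile(fileext = ".json")
  save_ssm(fx$model, path)
  back <- load_ssm(path)
  expect_equal(back$mean, fx$model$mean, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$variances, fx$model$variances, tolerance = 1e-12)
  expect_equal(length(back$components), length(fx$model$components))
  expect_equal(back$components[[1]], fx$model$components[[1]],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$template_mesh$vertices, fx$model$template_mesh$vertices,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$n_training, fx$model$n_training)
})
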