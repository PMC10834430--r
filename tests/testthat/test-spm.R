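test_that("trajectory resampling is exact for data already on the grid", {
  v <- sin(seq(0, 2 * pi, length.out = 101))
  tr <- resample_trajectory(v, seq(0, 100, length.out = 101), Q = 101)
  expect_equal(tr$values, v, tolerance = 1e-12)
  # linear ramps reproduce exactly under linear interpolation
  ramp <- resample_trajectory(c(0, 10), c(0, 100), Q = 51)
  expect_equal(ramp$values, seq(0, 10, length.out = 51), tolerance = 1e-12)
  # dense sine resampled to Q=101 stays within 1e-3 of the analytic curve
  t1k <- seq(0, 1, length.out = 1000)
  sin1k <- resample_trajectory(sin(2 * pi * t1k), t1k, Q = 101)
  expect_lt(max(abs(sin1k$values - sin(2 * pi * sin1k$nodes))), 1e-3)
  expect_error(resample_trajectory(c(1, 2, 3), c(0, 2, 1)), "increasing")
})

test_that("FWHM estimation recovers the generating smoothness", {
  set.seed(5)
  est <- replicate(60, {
    tr <- synth_trajectories(9, 0, fwhm_nodes = 20,
                             seed = sample.int(2^31 - 1, 1))
    estimate_fwhm(do.call(rbind, lapply(c(tr$A, tr$B), `[[`, "values")))
  })
  expect_lt(abs(mean(est) - 20) / 20, 0.15)
  expect_error(estimate_fwhm(matrix(1, 4, 10)), "zero-variance")
})

test_that("FWHM of white noise matches its Monte-Carlo expectation", {
  # iid N(0,1) residuals: v_j = E[(dR)^2]/E[R^2] = 2 for adjacent nodes,
  # so the estimator concentrates near sqrt(4 log 2 / 2)
  set.seed(8)
  est <- replicate(300, estimate_fwhm(matrix(rnorm(12 * 101), 12)))
  expect_lt(abs(mean(est) - sqrt(4 * log(2) / 2)) / sqrt(4 * log(2) / 2), 0.10)
})

test_that("the RFT threshold has the smooth-field limit and monotonicity", {
  expect_equal(rft_critical_t(0.05, df = 16, Q = 101, fwhm = 1e9),
               qt(0.975, 16), tolerance = 1e-4)
  expect_gt(rft_critical_t(0.05, 16, 101, 10), rft_critical_t(0.05, 16, 101, 20))
  expect_gt(rft_critical_t(0.05, 16, 101, 20), rft_critical_t(0.05, 16, 101, 40))
  expect_error(rft_critical_t(1.5, 16, 101, 20), "alpha")
})

test_that("the RFT threshold matches a Monte-Carlo oracle of smooth t fields", {
  # simulate the null max|t| distribution at the generator's conditions and
  # compare the RFT threshold with the empirical 95th percentile
  set.seed(13)
  mx <- replicate(400, {
    tr <- synth_trajectories(9, 0, fwhm_nodes = 20,
                             seed = sample.int(2^31 - 1, 1))
    max(abs(spm_ttest2(tr$A, tr$B)$t_curve))
  })
  t_rft <- rft_critical_t(0.05, df = 16, Q = 101, fwhm = 20)
  t_emp <- unname(quantile(mx, 0.95))
  expect_lt(abs(t_rft - t_emp) / t_emp, 0.08)
})

test_that("pointwise t equals the scalar two-sample statistic to 1e-12", {
  tr <- synth_trajectories(9, effect_size = 0.5, fwhm_nodes = 20, seed = 2)
  res <- spm_ttest2(tr$A, tr$B)
  A <- do.call(rbind, lapply(tr$A, `[[`, "values"))
  B <- do.call(rbind, lapply(tr$B, `[[`, "values"))
  manual <- vapply(seq_len(101), function(q)
    unname(t.test(A[, q], B[, q], var.equal = TRUE)$statistic), numeric(1))
  expect_lt(max(abs(res$t_curve - manual)), 1e-12)
  expect_equal(res$df, 16)
})

test_that("the t curve is scale invariant and identical groups give t == 0", {
  tr <- synth_trajectories(5, 0, 20, seed = 6)
  r1 <- spm_ttest2(tr$A, tr$B)
  scaled_A <- lapply(tr$A, function(t) Trajectory(3.7 * t$values, t$nodes))
  scaled_B <- lapply(tr$B, function(t) Trajectory(3.7 * t$values, t$nodes))
  r2 <- spm_ttest2(scaled_A, scaled_B)
  expect_equal(r2$t_curve, r1$t_curve, tolerance = 1e-9)

  r0 <- spm_ttest2(tr$A, tr$A)
  expect_true(all(r0$t_curve == 0))
  expect_false(r0$significant)
  expect_length(r0$clusters, 0)
})

test_that("a huge group offset is detected across nearly all nodes", {
  tr <- synth_trajectories(9, effect_size = 10, fwhm_nodes = 20, seed = 4)
  res <- spm_ttest2(tr$A, tr$B)
  expect_true(res$significant)
  span <- sum(vapply(res$clusters, function(cl) cl["end"] - cl["start"] + 1,
                     numeric(1)))
  expect_gte(span, 0.9 * 101)
  # significance flag is bit-consistent with clusters and the threshold
  expect_identical(res$significant, length(res$clusters) > 0L)
  expect_identical(res$significant, max(abs(res$t_curve)) > res$t_critical)
})

test_that("trajectory CSV input and SPM result output round-trip", {
  tr <- synth_trajectories(3, 1, 20, Q = 21, seed = 3)
  rows <- do.call(rbind, lapply(c(A = "A", B = "B"), function(gp) {
    do.call(rbind, lapply(seq_len(3), function(i) {
      t <- tr[[gp]][[i]]
      data.frame(subject = paste0(gp, i), group = gp, time_pct = t$nodes,
                 parameter = "fluid_pressure", value = t$values)
    }))
  }))
  path <- tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE)
  got <- read_trajectories_csv(path, parameter = "fluid_pressure", Q = 21)
  expect_named(got$groups, c("A", "B"))
  expect_length(got$groups$A, 3)
  expect_equal(got$groups$A[[1]]$values, tr$A[[1]]$values, tolerance = 1e-9)

  res <- spm_ttest2(tr$A, tr$B)
  jp <- tempfile(fileext = ".json")
  cp <- tempfile(fileext = ".csv")
  write_spm_result(res, jp, cp)
  js <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(js$t_critical, res$t_critical, tolerance = 1e-9)
  cc <- read.csv(cp)
  expect_equal(cc$t, unname(res$t_curve), tolerance = 1e-9)
})
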