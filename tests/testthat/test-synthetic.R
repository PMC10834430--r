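test_that("population generation is seed-deterministic and validates specs", {
  sp <- PopulationSpec(n_shapes = 3, seed = 11)
  a <- synth_population(sp)
  b <- synth_population(sp)
  expect_identical(a$params, b$params)
  expect_identical(a$meshes[[2]]$vertices, b$meshes[[2]]$vertices)
  expect_error(PopulationSpec(n_shapes = 1), "n_shapes")
  expect_error(PopulationSpec(modes = list(condyle_width = c(-5, 1))),
               "positive mean")
  expect_error(PopulationSpec(modes = list(nonsense = c(1, 1))), "unknown")
})

test_that("zero-SD populations are identical shapes; all are closed surfaces", {
  sp <- PopulationSpec(n_shapes = 3,
                       modes = list(condyle_width = c(12, 0),
                                    condyle_separation = c(26, 0)),
                       seed = 2)
  pop <- synth_population(sp)
  expect_identical(pop$meshes[[1]]$vertices, pop$meshes[[2]]$vertices)
  expect_identical(pop$meshes[[1]]$faces, pop$meshes[[3]]$faces)
  for (m in pop$meshes) {
    expect_true(bonessm:::mesh_is_closed(m))
    expect_gt(bonessm:::mesh_signed_volume(m), 0)
  }
})

test_that("degradation with all parameters zero equals the clean voxelization", {
  pop <- synth_population(PopulationSpec(n_shapes = 2, seed = 4))
  gt <- pop$meshes[[1]]
  spec0 <- DegradationSpec(spacing = 1, jitter_sd = 0, n_holes = 0,
                           hole_radius = 0, flip_prob = 0, seed = 9)
  degraded <- synth_degrade(gt, spec0)
  clean <- voxelize_surface(gt, bonessm:::grid_for_mesh(gt, 1, margin = 2))
  expect_identical(degraded$values, clean$values)
})

test_that("carved holes push the surface at least a hole radius away", {
  pop <- synth_population(PopulationSpec(n_shapes = 2, seed = 4))
  gt <- pop$meshes[[1]]
  spec <- DegradationSpec(spacing = 1, jitter_sd = 0, n_holes = 3,
                          hole_radius = 2.5, flip_prob = 0, seed = 5)
  degraded <- synth_degrade(gt, spec)
  surf <- mask_to_surface(degraded)
  d <- surface_distances(surf, gt)
  expect_gte(d$hausdorff, 2.5 - 1)  # hole radius minus one voxel
  # determinism
  expect_identical(synth_degrade(gt, spec)$values, degraded$values)
  expect_error(synth_degrade(gt, DegradationSpec(hole_radius = 1000)),
               "hole_radius")
})

test_that("Dice against the clean mask degrades monotonically with flips", {
  pop <- synth_population(PopulationSpec(n_shapes = 2, seed = 4))
  gt <- pop$meshes[[1]]
  clean <- synth_degrade(gt, DegradationSpec(spacing = 1, jitter_sd = 0,
                                             n_holes = 0, flip_prob = 0,
                                             seed = 1))
  dscs <- vapply(c(0.02, 0.1, 0.3), function(p) {
    noisy <- synth_degrade(gt, DegradationSpec(spacing = 1, jitter_sd = 0,
                                               n_holes = 0, flip_prob = p,
                                               seed = 1))
    as.numeric(dice(noisy, clean))
  }, numeric(1))
  expect_true(all(dscs < 1))
  expect_true(all(diff(dscs) < 0))
})

test_that("synthetic cartilage surfaces follow the thickness profile", {
  sheet <- fixture_random_sheet(8, z_amp = 0)
  art <- synth_cartilage_surface(sheet, seq_len(nrow(sheet$faces)),
                                 thickness_profile = 2)
  expect_lt(max(abs(abs(art$vertices[, 3]) - 2)), 1e-9)  # plane at +-2 mm

  profile <- function(p) 1 + 0.3 * p[, 1]  # linear in x
  art2 <- synth_cartilage_surface(sheet, seq_len(nrow(sheet$faces)), profile)
  sub <- bonessm:::mesh_subset_faces(sheet, seq_len(nrow(sheet$faces)))
  got <- abs(art2$vertices[, 3])
  expect_lt(max(abs(got - (1 + 0.3 * sub$vertices[, 1]))), 1e-2)
  expect_error(synth_cartilage_surface(sheet, seq_len(nrow(sheet$faces)),
                                       function(p) p[, 1] - 10), "positive")
})

test_that("extrusion against a constant-offset cartilage gives equal layers", {
  sph <- fixture_sphere_mesh(r = 5, h = 0.5)
  cap_faces <- which(apply(matrix(sph$vertices[t(sph$faces), 3], ncol = 3,
                                  byrow = TRUE), 1, mean) < -3.5)
  art <- synth_cartilage_surface(sph, cap_faces, thickness_profile = 2)
  qp <- quad_patch(sph, cap_faces, grid = c(4, 4))
  hx <- extrude_cartilage(qp, art, n_layers = 5)
  q <- hex_quality(hx)
  expect_equal(q$n_inverted, 0L)
  # per-element thickness approx 2/5 mm
  expect_lt(abs(q$min_thickness - 0.4), 0.1)
  expect_lt(abs(q$max_thickness - 0.4), 0.1)
})

test_that("trajectory ensembles are seed-deterministic with the stated FWHM", {
  a <- synth_trajectories(4, 1.5, 20, seed = 9)
  b <- synth_trajectories(4, 1.5, 20, seed = 9)
  expect_identical(a$A[[2]]$values, b$A[[2]]$values)
  expect_identical(a$B[[4]]$values, b$B[[4]]$values)
  # group B carries the mean shift
  mA <- mean(vapply(a$A, function(t) mean(t$values), numeric(1)))
  mB <- mean(vapply(a$B, function(t) mean(t$values), numeric(1)))
  expect_gt(mB - mA, 0.5)
  expect_error(synth_trajectories(4, 0, 20, Q = 5), "Q")
  expect_error(synth_trajectories(4, 0, fwhm_nodes = 0), "fwhm")
})
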