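test_that("mask_to_surface recovers a digitized ball's geometry", {
  mask <- fixture_sphere_mask(r = 5, h = 0.5)
  surf <- fixture_sphere_mesh(r = 5, h = 0.5)
  expect_true(bonessm:::mesh_is_closed(surf))
  area <- bonessm:::mesh_area(surf)
  expect_lt(abs(area - 4 * pi * 25) / (4 * pi * 25), 0.10)
  expect_gt(bonessm:::mesh_signed_volume(surf), 0)  # outward orientation
})

test_that("a single foreground voxel yields a closed genus-0 surface", {
  vals <- array(0L, c(3, 3, 3))
  vals[2, 2, 2] <- 1L
  surf <- mask_to_surface(VoxelMask(vals, c(1, 1, 1)))
  expect_true(bonessm:::mesh_is_closed(surf))
  expect_equal(bonessm:::mesh_euler_characteristic(surf), 2L)
})

test_that("empty masks are rejected", {
  expect_error(mask_to_surface(VoxelMask(array(0L, c(4, 4, 4)), c(1, 1, 1))),
               "foreground")
})

test_that("voxelization matches the analytic ball volume and round-trips", {
  mask <- fixture_sphere_mask(r = 5, h = 0.5)
  surf <- fixture_sphere_mesh(r = 5, h = 0.5)
  vm <- voxelize_surface(surf, grid_from_mask(mask))
  vol <- sum(vm$values) * 0.5^3
  expect_lt(abs(vol - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.05)
  expect_gt(dice(vm, mask), 0.95)
})

test_that("voxelizing a mesh fully outside the grid gives an all-zero mask", {
  cube <- fixture_cube()
  g <- grid_spec(c(1, 1, 1), c(100, 100, 100), c(5, 5, 5))
  expect_equal(sum(voxelize_surface(cube, g)$values), 0L)
})

test_that("voxelization refuses open meshes, naming the boundary edges", {
  sheet <- fixture_random_sheet(5)
  g <- grid_spec(c(1, 1, 1), c(0, 0, 0), c(4, 4, 4))
  expect_error(voxelize_surface(sheet, g), "[0-9]+ boundary edges")
})

test_that("Taubin smoothing is identity at 0 iterations and validates factors", {
  m <- fixture_sphere_mesh()
  expect_identical(taubin_smooth(m, iterations = 0), m)
  expect_error(taubin_smooth(m, lam = -0.1), "lam")
  expect_error(taubin_smooth(m, mu = 0.2), "mu")
})

test_that("Taubin smoothing reduces noise and shrinks less than Laplacian", {
  base <- fixture_sphere_mesh(r = 5, h = 0.5)
  set.seed(4)
  noisy <- TriMesh(base$vertices + matrix(rnorm(length(base$vertices), 0, 0.2),
                                          ncol = 3), base$faces)
  dev <- function(m) mean(abs(sqrt(rowSums(m$vertices^2)) - 5))
  sm <- taubin_smooth(noisy)
  expect_lt(dev(sm), dev(noisy))
  vol_t <- bonessm:::mesh_signed_volume(sm)
  vol_l <- bonessm:::mesh_signed_volume(bonessm:::laplacian_smooth(noisy))
  vol_0 <- bonessm:::mesh_signed_volume(noisy)
  expect_lt(abs(vol_0 - vol_t), abs(vol_0 - vol_l))  # less shrinkage
})

test_that("remeshing hits the vertex budget while staying on the surface", {
  fine <- mask_to_surface(fixture_sphere_mask(r = 5, h = 0.25))
  expect_gt(nrow(fine$vertices), 8000)
  out <- remesh_template(fine, 2000)
  expect_lt(abs(nrow(out$vertices) - 2000), 200)
  d <- surface_distances(out, fine)
  expect_lt(d$hausdorff, 0.1)
  # near-identity branch when the budget matches the current count
  same <- remesh_template(fine, nrow(fine$vertices))
  expect_gte(bonessm:::mesh_min_angle(same), bonessm:::mesh_min_angle(fine))
  expect_error(remesh_template(fine, 3), "target_vertex_count")
})

test_that("Poisson-disk sampling is deterministic, on-surface and packed", {
  m <- fixture_sphere_mesh()
  a <- poisson_disk_sample(m, 300, seed = 5)
  b <- poisson_disk_sample(m, 300, seed = 5)
  expect_identical(a$points, b$points)
  expect_equal(nrow(a$points), 300L)
  expect_lt(max(bonessm:::mesh_closest(a$points, m)$dist), 1e-6)
  r_ideal <- sqrt(bonessm:::mesh_area(m) / (2 * sqrt(3) * 300))
  nn <- bonessm:::cpp_all_nn(a$points)
  expect_gte(min(nn$dist), 0.5 * r_ideal)
})

test_that("Poisson-disk packing bound holds on a flat unit square", {
  # unit-area square as two triangles, oversampled pool
  sq <- TriMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                rbind(c(1, 2, 3), c(1, 3, 4)))
  p <- poisson_disk_sample(sq, 100, seed = 2)
  nn <- bonessm:::cpp_all_nn(p$points)
  expect_gte(min(nn$dist), 0.5 * sqrt(1 / (2 * sqrt(3) * 100)))
})

test_that("sampling more points than the pool can hold errors", {
  tet <- fixture_tetra()
  expect_error(poisson_disk_sample(tet, 5000, seed = 1, oversample = 0.5),
               "budget")
})

test_that("uniformization tightens clumped samples and fixes uniform ones", {
  m <- fixture_sphere_mesh()
  # clumped: every point duplicated a small surface distance away
  a <- poisson_disk_sample(m, 150, seed = 1)$points
  twin <- bonessm:::mesh_closest(a + 0.01, m)$closest
  clump <- SurfacePointSet(rbind(a, twin))
  cv <- function(p) {
    d <- bonessm:::cpp_all_nn(p)$dist
    stats::sd(d) / mean(d)
  }
  out <- uniformize_points(clump, m)
  expect_lt(cv(out$points), 0.7 * cv(clump$points))
  expect_lt(max(bonessm:::mesh_closest(out$points, m)$dist), 1e-6)
  # identity cases
  ps <- poisson_disk_sample(m, 100, seed = 3)
  expect_identical(uniformize_points(ps, m, iterations = 0), ps)
  expect_error(uniformize_points(SurfacePointSet(a[1:3, ]), m), "4 points")
})
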