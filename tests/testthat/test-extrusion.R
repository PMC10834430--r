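# flat 3x3-node patch on z=0 with a flat articular plane 2 mm above
flat_fixture <- function() {
  v <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0))
  qm <- QuadMesh(v, rbind(c(1, 2, 5, 4), c(2, 3, 6, 5),
                          c(4, 5, 8, 7), c(5, 6, 9, 8)))
  art <- TriMesh(rbind(c(-5, -5, 2), c(7, -5, 2), c(7, 7, 2), c(-5, 7, 2)),
                 rbind(c(1, 2, 3), c(1, 3, 4)))
  list(patch = qm, articular = art)
}

test_that("flat-patch extrusion has the exact element/node bookkeeping", {
  fx <- flat_fixture()
  hx <- extrude_cartilage(fx$patch, fx$articular, n_layers = 5)
  expect_equal(nrow(hx$elements), 4L * 5L)            # quads x layers
  expect_equal(nrow(hx$nodes), 9L * 6L)               # nodes x (layers+1)
  expect_equal(length(hx$element_sets), 5L)
  expect_setequal(unique(hx$layer_id), 1:5)
  q <- hex_quality(hx)
  expect_equal(q$n_inverted, 0L)
  expect_equal(q$min_thickness, 0.4, tolerance = 1e-12)
  expect_equal(q$max_thickness, 0.4, tolerance = 1e-12)
  expect_equal(q$min_scaled_jacobian, 1, tolerance = 1e-12)
  # interface nodes shared bit-identically with the patch
  expect_identical(hx$nodes[hx$node_sets$bone_interface, ],
                   fx$patch$vertices)
  # top layer on the articular surface
  top <- hx$nodes[hx$node_sets$articular_surface, ]
  expect_lt(max(abs(top[, 3] - 2)), 1e-3)
  # layer segments of each node column are equal
  col1 <- hx$nodes[seq(1, nrow(hx$nodes), by = 9), 3]
  expect_lt(max(abs(diff(col1) - 0.4)), 1e-9)
})

test_that("a coincident articular surface floors thickness with a warning", {
  fx <- flat_fixture()
  art0 <- TriMesh(fx$articular$vertices - matrix(rep(c(0, 0, 2), each = 4),
                                                 ncol = 3), fx$articular$faces)
  expect_warning(hx <- extrude_cartilage(fx$patch, art0, n_layers = 5),
                 "min_thickness")
  q <- hex_quality(hx)
  # the floored 0.1 mm column is split into 5 equal element layers
  expect_equal(q$max_thickness, 0.1 / 5, tolerance = 1e-9)
  top <- hx$nodes[hx$node_sets$articular_surface, ]
  expect_lt(max(abs(top[, 3] - 0.1)), 1e-9)
})

test_that("scaled Jacobian matches the hand-computed sheared-hex value", {
  cube <- HexMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                        c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),
                  matrix(c(1:4, 5:8), 1))
  expect_equal(hex_quality(cube)$min_scaled_jacobian, 1, tolerance = 1e-12)
  # top face sheared by (1,0,0): corner frames [e1,e2,e3+x] -> det 1, norms
  # 1,1,sqrt(2) -> scaled jacobian 1/sqrt(2)
  shear <- HexMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                         c(1, 0, 1), c(2, 0, 1), c(2, 1, 1), c(1, 1, 1)),
                   matrix(1:8, 1))
  expect_equal(hex_quality(shear)$min_scaled_jacobian, 1 / sqrt(2),
               tolerance = 1e-12)
  # swapping two top nodes inverts the element
  bad <- HexMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                       c(1, 0, 1), c(0, 0, 1), c(1, 1, 1), c(0, 1, 1)),
                 matrix(1:8, 1))
  expect_gte(hex_quality(bad)$n_inverted, 1L)
})

test_that("INP export is re-parseable and preserves the mesh exactly", {
  fx <- flat_fixture()
  hx <- extrude_cartilage(fx$patch, fx$articular, n_layers = 5)
  path <- tempfile(fileext = ".inp")
  write_inp(hx, path)
  txt <- readLines(path)
  expect_true(any(grepl("TYPE=C3D8P", txt)))
  elem_hdr <- grep("^\\*ELEMENT", txt)
  next_kw <- min(grep("^\\*", txt)[grep("^\\*", txt) > elem_hdr])
  expect_equal(next_kw - elem_hdr - 1L, 20L)  # exactly 20 element lines
  back <- read_inp(path)
  expect_lt(max(abs(back$nodes - hx$nodes)), 1e-6)
  expect_identical(unname(back$elements), unname(hx$elements))
  expect_setequal(back$node_sets$bone_interface, hx$node_sets$bone_interface)
  expect_identical(back$layer_id, hx$layer_id)
  expect_error(write_inp(HexMesh(matrix(0, 0, 3), matrix(0L, 0, 8)),
                         tempfile()), "empty")
})

test_that("contact-patch selection matches an analytic spherical cap", {
  sph <- fixture_sphere_mesh(r = 5, h = 0.5)
  # cap: offset of the z < -3.5 portion (analytic cap on the sphere)
  cap_faces <- which(apply(matrix(sph$vertices[t(sph$faces), 3], ncol = 3,
                                  byrow = TRUE), 1, mean) < -3.5)
  cap <- synth_cartilage_surface(sph, cap_faces, thickness_profile = 2)
  sel <- select_contact_patch(sph, cap, max_distance = 2.2)
  area_sel <- sum(bonessm:::mesh_face_areas(sph)[sel])
  # analytic cap area 2*pi*r*h_cap (h_cap = r - 3.5); the selection may
  # legitimately add a boundary ring of width sqrt(md^2 - t^2) (+ one face)
  # around the cap edge, whose radius is sqrt(r^2 - 3.5^2)
  a_cap <- 2 * pi * 5 * 1.5
  ring <- (sqrt(2.2^2 - 2^2) + 0.6) * 2 * pi * sqrt(25 - 3.5^2)
  expect_gt(area_sel, 0.9 * a_cap)
  expect_lt(area_sel, a_cap + ring)
  expect_error(select_contact_patch(sph, cap, max_distance = 1e-9),
               "max_distance")
  sel_all <- select_contact_patch(sph, cap, max_distance = Inf)
  expect_equal(length(sel_all), nrow(sph$faces))
})

test_that("quad patches are regular grids whose nodes lie on the surface", {
  sheet <- fixture_random_sheet(9, z_amp = 0)  # planar patch
  qp <- quad_patch(sheet, seq_len(nrow(sheet$faces)), grid = c(4, 4))
  expect_equal(nrow(qp$faces), 9L)
  expect_lt(max(abs(qp$vertices[, 3])), 1e-9)  # coplanar
  qp2 <- quad_patch(sheet, seq_len(nrow(sheet$faces)), grid = c(7, 5))
  expect_equal(nrow(qp2$faces), 6L * 4L)

  sph <- fixture_sphere_mesh(r = 5, h = 0.5)
  cap_faces <- which(apply(matrix(sph$vertices[t(sph$faces), 3], ncol = 3,
                                  byrow = TRUE), 1, mean) < -3.5)
  qs <- quad_patch(sph, cap_faces, grid = c(5, 5))
  expect_lt(max(bonessm:::mesh_closest(qs$vertices,
                                       bonessm:::mesh_subset_faces(sph, cap_faces))$dist),
            1e-3)
})

test_that("hex meshes export to legacy VTK unstructured grids", {
  fx <- flat_fixture()
  hx <- extrude_cartilage(fx$patch, fx$articular, n_layers = 2)
  path <- tempfile(fileext = ".vtk")
  write_vtk_hex(hx, path)
  txt <- readLines(path)
  expect_true(any(grepl("DATASET UNSTRUCTURED_GRID", txt)))
  expect_equal(sum(txt == "12"), nrow(hx$elements))
})
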