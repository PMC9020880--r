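# Geometry validation and the structured tetrahedral mesher.

test_that("geometry derives gaps and rejects bubble-wall contact", {
  g <- build_geometry(geometry_spec())
  expect_equal(g$gap, 8e-6)
  g7 <- build_geometry(geometry_spec(bubble_offset = 7e-6))
  expect_equal(g7$gap, 1e-6)
  expect_error(build_geometry(geometry_spec(bubble_offset = 8.5e-6)),
               "contact")
  expect_error(geometry_spec(vessel_inner_radius = -1), "positive")
})

test_that("meshes are watertight: interior facets shared by 2 tets,
           boundary facets by 1", {
  m <- fixture_mesh()
  tets <- m$tets
  faces <- rbind(tets[, c(2, 3, 4)], tets[, c(1, 4, 3)],
                 tets[, c(1, 2, 4)], tets[, c(1, 3, 2)])
  key <- apply(faces, 1L, function(f) paste(sort(f), collapse = "_"))
  cnt <- table(key)
  expect_true(all(cnt %in% c(1L, 2L)))
  # tagged boundary facets each appear once, interface facets twice
  ft <- m$facets
  bd <- ft$tag %in% c("symmetry_plane", "axial_ends", "pml_outer")
  bkey <- apply(ft$facets, 1L, function(f) paste(sort(f), collapse = "_"))
  expect_true(all(cnt[bkey[bd]] == 1L))
  expect_true(all(cnt[bkey[!bd]] == 2L))
})

test_that("half-symmetry holds: x >= 0 everywhere, symmetry facets exactly
           on the plane", {
  m <- fixture_mesh("offset_coarse")
  expect_true(all(m$vertices[, 1L] >= -1e-18))
  symv <- unique(as.vector(m$facets$facets[m$facets$tag == "symmetry_plane", ]))
  expect_true(all(abs(m$vertices[symv, 1L]) < 1e-18))
})

test_that("region volumes approach the analytic half-model volumes", {
  m <- fixture_mesh()
  q <- m$quality
  vols <- q$region_volumes[names(m$geometry$volumes)]
  rel <- abs(vols - m$geometry$volumes) / m$geometry$volumes
  expect_true(all(rel < 0.06))     # inscribed coarse polyhedra
  expect_equal(q$inverted_count, 0L)
})

test_that("bubble volume deficit is positive and converges at second
           order under refinement", {
  specs <- list(
    list(n_phi = 8L, n_cap = 2L, n_lat = 8L, n_shell = 4L, n_gas = 2L,
         n_wall = 1L, n_tissue = 1L, n_pml = 1L),
    list(n_phi = 16L, n_cap = 4L, n_lat = 16L, n_shell = 4L, n_gas = 2L,
         n_wall = 1L, n_tissue = 1L, n_pml = 1L))
  defs <- vapply(specs, function(p)
    generate_mesh(geometry_spec(), p, quality_floor = 0.05)$quality$volume_deficit,
    numeric(1))
  expect_true(all(defs > 0))
  order_obs <- log2(defs[1] / defs[2])     # angular h halved
  expect_gt(order_obs, 1.6)
  # preset ladder strictly decreases the deficit
  d1 <- fixture_mesh()$quality$volume_deficit
  d2 <- generate_mesh(geometry_spec(), "medium")$quality$volume_deficit
  expect_lt(d2, d1)
})

test_that("quality report recovers the closed-form dihedral of a regular
           tetrahedron", {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(vescav:::.min_dihedral(v, matrix(1:4, 1)),
               acos(1 / 3) * 180 / pi, tolerance = 1e-10)
})

test_that("bubble-interface facet count sits near the reference surface
           resolution at medium", {
  m <- generate_mesh(geometry_spec(), "medium")
  n <- m$quality$bubble_surface_facet_count
  expect_gt(n, 622 / 3)
  expect_lt(n, 622 * 3)
})

test_that("identical spec and resolution reproduce the identical mesh", {
  m1 <- generate_mesh(geometry_spec(bubble_offset = 2e-6), "coarse")
  m2 <- generate_mesh(geometry_spec(bubble_offset = 2e-6), "coarse")
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$tets, m2$tets)
})

test_that("meshes round-trip through the MSH writer and VTK export is
           well-formed", {
  m <- fixture_mesh()
  p <- tempfile(fileext = ".msh")
  write_msh(m, p)
  back <- read_msh(p)
  expect_equal(unname(back$vertices), unname(m$vertices),
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_identical(back$tets, unname(m$tets))
  expect_identical(back$region, unname(m$region))
  pv <- tempfile(fileext = ".vtk")
  write_vtk(m, pv, point_data = list(r = sqrt(rowSums(m$vertices^2))))
  lines <- readLines(pv)
  expect_true(any(grepl("^POINTS", lines)))
  expect_true(any(grepl("^CELLS", lines)))
  expect_true(any(grepl("SCALARS r", lines)))
})

test_that("interior mesh smoothing is rigid under rigid boundary data and
           survives a 10% bubble expansion", {
  m <- fixture_mesh()
  bub <- sort(unique(as.vector(
    m$facets$facets[m$facets$tag == "bubble_interface", ])))
  m0 <- smooth_mesh(m, matrix(0, length(bub), 3L), bub)
  expect_equal(m0$vertices, m$vertices, tolerance = 1e-12)
  # uniform translation of all region boundary nodes -> rigid interior
  tets_bl <- m$tets[m$region == "blood", ]
  rnodes <- sort(unique(as.vector(tets_bl)))
  tagged <- intersect(sort(unique(as.vector(m$facets$facets))), rnodes)
  shift <- matrix(rep(c(1e-7, 0, 0), each = length(tagged)), ncol = 3L)
  mt <- smooth_mesh(m, shift, tagged)
  moved <- mt$vertices[rnodes, ] - m$vertices[rnodes, ]
  expect_equal(max(abs(moved[, 1L] - 1e-7)), 0, tolerance = 1e-12)
  # 10% radial bubble expansion: no inversion, quality above floor
  ctr <- matrix(m$maps$bubble_center, length(bub), 3L, byrow = TRUE)
  disp <- 0.1 * (m$vertices[bub, ] - ctr)
  me <- smooth_mesh(m, disp, bub)
  expect_equal(sum(vescav:::.tet_volumes(me$vertices, me$tets) <= 0), 0L)
})
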