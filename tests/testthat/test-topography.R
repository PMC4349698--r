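# Surface areas, projection with union semantics, RFI, basin crop, OR.

test_that("total surface area is the exact triangle-area sum", {
  m <- square_mesh()
  expect_equal(total_surface_area(m), 1)

  # duplicated faces double the area (no repair, deterministic additivity)
  dbl <- tooth_mesh(m$vertices, rbind(m$faces, m$faces))
  expect_equal(total_surface_area(dbl), 2)

  hemi <- hemisphere_mesh(r = 5, n_theta = 128, n_phi = 64)
  expect_equal(total_surface_area(hemi), 2 * pi * 25,
               tolerance = 0.005)
})

test_that("projected area uses union semantics", {
  expect_equal(projected_area(square_mesh()), 1, tolerance = 1e-12)

  # two identical squares stacked at different heights project to 1, not 2
  m <- square_mesh()
  stacked <- tooth_mesh(rbind(m$vertices,
                              cbind(m$vertices[, 1:2], 2)),
                        rbind(m$faces, m$faces + 4L))
  expect_equal(projected_area(stacked, method = "union"), 1,
               tolerance = 1e-12)

  # partially overlapping squares: union = 2 - 0.25 = 1.75
  shifted <- m$vertices
  shifted[, 1] <- shifted[, 1] + 0.5
  shifted[, 2] <- shifted[, 2] + 0.5
  shifted[, 3] <- 1
  two <- tooth_mesh(rbind(m$vertices, shifted), rbind(m$faces, m$faces + 4L))
  expect_equal(projected_area(two, method = "union"), 1.75,
               tolerance = 1e-12)

  hemi <- hemisphere_mesh(r = 3, n_theta = 96, n_phi = 48)
  expect_equal(projected_area(hemi, method = "union"), pi * 9,
               tolerance = 0.005)

  # vertical sheet has no projection
  sheet <- tooth_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1)),
                      rbind(c(1, 2, 3)))
  expect_error(projected_area(sheet), "degenerate projection")
})

test_that("union and rasterization agree within the pixel-area bound", {
  crown <- make_tooth_mesh(n_cusps = 4, cusp_height = 2, resolution = 32,
                           seed = 6)
  a_union <- projected_area(crown, method = "union")
  a_raster <- projected_area(crown, method = "raster", resolution = 2048L)
  # error bound ~ boundary length * pixel size (base radius 3 mm)
  px <- 2 * 3 / 2048
  bound <- 2 * pi * 3 * px * 2
  expect_lt(abs(a_union - a_raster), bound)
})

test_that("relief index follows its closed form", {
  expect_equal(relief_index(2, 2), 0)
  expect_equal(relief_index(exp(2) * 5, 5), 1)
  expect_error(relief_index(-1, 1), "positive")
  expect_warning(relief_index(1, 2), "TSA < PSA")

  hemi <- hemisphere_mesh(r = 3, n_theta = 96, n_phi = 48)
  rfi <- relief_index(total_surface_area(hemi),
                      projected_area(hemi, method = "union"))
  expect_equal(rfi, 0.5 * log(2), tolerance = 0.01)
})

test_that("basin crop retains geometry above the plane exactly", {
  # flat plate: basin point on it -> nothing cropped, warning
  m <- square_mesh(z0 = 1)
  expect_warning(cr <- basin_crop(m, basin_point = 1L), "global minimum")
  expect_equal(cr$crop_height, 1)
  expect_equal(total_surface_area(cr$mesh), 1)

  # hemisphere with the basin at the rim -> full hemisphere retained
  hemi <- hemisphere_mesh(r = 3, n_theta = 48, n_phi = 24)
  rim_vertex <- which.min(hemi$vertices[, 3])
  expect_warning(cr2 <- basin_crop(hemi, basin_point = rim_vertex),
                 "global minimum")
  expect_equal(total_surface_area(cr2$mesh), total_surface_area(hemi))

  # synthetic two-cusp crown with a known saddle: cropped area equals the
  # brute-force sum of exactly clipped triangle parts
  crown <- make_tooth_mesh(n_cusps = 2, cusp_height = 2, cusp_width = 0.5,
                           cusp_positions = rbind(c(-1.2, 0), c(1.2, 0)),
                           resolution = 32, seed = 1)
  h <- 0.8
  # find a vertex near that height to crop at
  v <- which.min(abs(crown$vertices[, 3] - h))
  h_v <- unname(crown$vertices[v, 3])
  cr3 <- basin_crop(crown, basin_point = v)
  oracle <- sum(vapply(seq_len(nrow(crown$faces)), function(fi) {
    sh_clip_area(crown$vertices[crown$faces[fi, ], , drop = FALSE], h_v)
  }, numeric(1)))
  expect_equal(total_surface_area(cr3$mesh), oracle, tolerance = 1e-10)
  expect_equal(cr3$crop_height, h_v)
})

test_that("basin auto-detection finds the saddle between two cusps", {
  crown <- make_tooth_mesh(n_cusps = 2, cusp_height = 2, cusp_width = 0.5,
                           cusp_positions = rbind(c(-1.2, 0), c(1.2, 0)),
                           resolution = 48, seed = 1)
  hfun <- attr(crown, "height_fun")
  saddle_true <- hfun(0, 0)              # analytic saddle height
  cr <- basin_crop(crown)
  expect_lt(abs(cr$crop_height - saddle_true), 0.12)
  or_val <- occlusal_relief(cr$mesh)
  expect_gt(or_val, 1)
})

test_that("occlusal relief matches analytic values", {
  disc <- make_tooth_mesh(n_cusps = 0, cusp_height = 0, resolution = 32,
                          base_ecc = 1, seed = 1)
  expect_equal(occlusal_relief(disc), 1, tolerance = 1e-9)

  hemi <- hemisphere_mesh(r = 3, n_theta = 96, n_phi = 48)
  # cropped at the equator = the full hemisphere mesh
  expect_equal(occlusal_relief(hemi, method = "union"), 2, tolerance = 0.01)

  # OR >= 1 - epsilon for any height-field crown
  for (seed in 1:3) {
    crown <- make_tooth_mesh(n_cusps = 4, cusp_height = 1.5, resolution = 24,
                             seed = seed)
    expect_gte(occlusal_relief(crown), 1 - 1e-9)
  }
})

test_that("TSA >= PSA on height-field crowns, with equality only when flat", {
  for (seed in 1:5) {
    crown <- make_tooth_mesh(n_cusps = 4, cusp_height = 1 + seed / 2,
                             resolution = 24, seed = seed)
    tsa <- total_surface_area(crown)
    psa <- projected_area(crown)
    expect_gt(tsa, psa)
  }
  flat <- make_tooth_mesh(n_cusps = 0, cusp_height = 0, resolution = 24,
                          seed = 1)
  expect_equal(total_surface_area(flat), projected_area(flat),
               tolerance = 1e-9)
})

test_that("RFI and OR are invariant to rotation and scale, monotone in relief", {
  crown <- make_tooth_mesh(n_cusps = 4, cusp_height = 2, resolution = 24,
                           seed = 3)
  metrics <- function(m) {
    tsa <- total_surface_area(m); psa <- projected_area(m, method = "union")
    c(rfi = relief_index(tsa, psa), or = tsa / psa)
  }
  base <- metrics(crown)
  rot <- metrics(rotate_mesh_up(crown, 0.77))
  scl <- metrics(scale_mesh(crown, 3.2))
  expect_equal(rot, base, tolerance = 1e-6)
  expect_equal(scl, base, tolerance = 1e-6)

  heights <- seq(0.3, 3, length.out = 10)
  rfis <- vapply(heights, function(h) {
    m <- make_tooth_mesh(n_cusps = 1, cusp_height = h, resolution = 24,
                         seed = 1)
    relief_index(total_surface_area(m), projected_area(m))
  }, numeric(1))
  expect_true(all(diff(rfis) > 0))
})

test_that("mesh TSA agrees with analytic quadrature of the height field", {
  for (h in c(0.5, 1, 2, 4)) {
    m <- make_tooth_mesh(n_cusps = 1, cusp_height = h, base_ecc = 1,
                         resolution = 64, seed = 1)
    analytic <- tooth_analytic_area(attr(m, "height_fun"), n = 300)
    expect_equal(total_surface_area(m), analytic, tolerance = 0.01)
  }
})
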