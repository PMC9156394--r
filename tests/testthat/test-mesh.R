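test_that("triangle cell count matches the area-based estimate", {
  h <- 0.115e-3
  m <- generate_mesh(channel_outline(2.3e-3, 23e-3), h, element = "tri")
  est <- 2.3e-3 * 23e-3 / (0.43 * h^2)
  expect_gt(nrow(m$cells) / est, 0.7)
  expect_lt(nrow(m$cells) / est, 1.3)
})

test_that("halving the target edge length quadruples the cell count", {
  m1 <- generate_mesh(channel_outline(2.3e-3, 23e-3), 0.2e-3)
  m2 <- generate_mesh(channel_outline(2.3e-3, 23e-3), 0.1e-3)
  ratio <- nrow(m2$cells) / nrow(m1$cells)
  expect_gte(ratio, 3.5)
  expect_lte(ratio, 4.5)
  mj1 <- generate_mesh(build_outline(study_geometry(45)), 0.24e-3)
  mj2 <- generate_mesh(build_outline(study_geometry(45)), 0.12e-3)
  ratio_j <- nrow(mj2$cells) / nrow(mj1$cells)
  expect_gte(ratio_j, 3.0)     # graded axial spacing dilutes pure scaling
  expect_lte(ratio_j, 4.8)
})

test_that("boundary patches partition the boundary with no unlabeled face", {
  for (a in c(30, 90)) {
    m <- generate_mesh(build_outline(study_geometry(a)), 0.25e-3)
    bnd <- is.na(m$face_neigh)
    expect_false(anyNA(m$face_patch[bnd]))
    expect_setequal(unique(m$face_patch[bnd]),
                    c("inlet", "outlet_donor", "outlet_graft", "wall"))
    expect_true(all(is.na(m$face_patch[!bnd])))
    # inlet spans the donor diameter
    expect_equal(sum(m$face_length[bnd][m$face_patch[bnd] == "inlet"]),
                 2.3e-3, tolerance = 1e-9)
    expect_equal(sum(m$face_length[bnd][m$face_patch[bnd] == "outlet_graft"]),
                 2.3e-3, tolerance = 1e-9)
  }
})

test_that("closed-cell outward normals sum to zero (discrete divergence)", {
  for (a in c(30, 60, 90)) {
    m <- generate_mesh(build_outline(study_geometry(a)), 0.3e-3)
    closure <- etsflow:::cell_normal_closure(m)
    expect_lt(max(abs(closure)), 1e-15)
  }
  mt <- generate_mesh(channel_outline(2.3e-3, 12e-3), 0.2e-3, element = "tri")
  expect_lt(max(abs(etsflow:::cell_normal_closure(mt))), 1e-15)
})

test_that("mesh quality is reported and gates the solver", {
  # structured right-triangle split: min angle exactly 45 degrees
  mt <- channel_mesh(2e-3, 4e-3, 20, 10, element = "tri")
  q <- mesh_quality(mt)
  expect_equal(q$min_angle_deg, 45, tolerance = 1e-9)
  # study junction at 45 degrees passes the 15-degree gate
  mj <- generate_mesh(build_outline(study_geometry(45)), 0.25e-3)
  expect_gte(mesh_quality(mj)$min_angle_deg, 15)
  # a sliver-cell mesh is flagged below threshold and refused by the solver
  sliver <- channel_mesh(2e-3, 40e-3, 4, 2, element = "tri")  # 5:1 aspect
  qs <- mesh_quality(sliver)
  expect_lt(qs$min_angle_deg, 15)
  expect_error(solve_steady(sliver, fluid_properties(), boundary_conditions(),
                            solver_config()),
               "quality gate")
})

test_that("target edge length must resolve the channel width", {
  expect_error(generate_mesh(channel_outline(2.3e-3, 23e-3), 1e-3),
               "quarter")
})
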