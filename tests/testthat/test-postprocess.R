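test_that("wall shear stress matches the planar-channel closed form", {
  m <- channel_mesh(2.3e-3, 11.5e-3, 50, 20)
  fl <- fluid_properties()
  pf <- poiseuille_field(m, 0.1, fl)
  w <- wall_shear_stress(pf, m, fl)
  tau0 <- 6 * fl$viscosity * 0.1 / 2.3e-3           # ~0.913 Pa
  # uniform along the wall within 3%, within 5% of the closed form
  inner <- w$profile$x > 1e-3 & w$profile$x < 10.5e-3
  expect_lt(max(abs(w$profile$tau_pa[inner] - tau0)) / tau0, 0.05)
  expect_lt(diff(range(w$profile$tau_pa[inner])) / tau0, 0.03)
  # zero field gives zero stress
  zf <- pf; zf$u[] <- 0; zf$v[] <- 0
  wz <- wall_shear_stress(zf, m, fl)
  expect_true(all(wz$profile$tau_pa == 0))
})

test_that("wall patch is required for wall shear stress", {
  m <- channel_mesh(2.3e-3, 11.5e-3, 10, 8)
  m$face_patch[m$face_patch == "wall"] <- "inlet"
  pf <- poiseuille_field(channel_mesh(2.3e-3, 11.5e-3, 10, 8))
  expect_error(wall_shear_stress(pf, m, fluid_properties()), "wall")
})

test_that("poiseuille flow has no recirculation zones", {
  m <- channel_mesh(2.3e-3, 11.5e-3, 50, 20)
  pf <- poiseuille_field(m)
  z <- recirculation_zones(pf, m)
  expect_length(z, 0)
  expect_equal(attr(z, "total_area_m2"), 0)
})

test_that("solid-body vortex zone area matches the analytic half-disc", {
  m <- channel_mesh(4.6e-3, 23e-3, 200, 40)      # fine enough for 5%
  R <- 1.4e-3
  # slow vortex: every in-disc speed is below 0.5 x background
  vx <- vortex_fixture(m, c(10e-3, 2.3e-3), R, omega = 0.5 * 0.1 / R)
  z <- recirculation_zones(vx, m)
  expect_length(z, 1)
  expect_lt(abs(z[[1]]$area_m2 - pi * R^2 / 2) / (pi * R^2 / 2), 0.05)
  # every recirculating cell lies in a cross-section with nonzero stagnant
  # fraction once the threshold covers the reversed-flow speed scale
  # (in-disc speeds <= 0.5 U < threshold 0.6 U < background U)
  sp <- stagnation_profile(vx, m, threshold_fraction = 0.6, n_sections = 60)
  cl <- sp$centerline
  srange <- range(m$cell_centroid[z[[1]]$cells, 1]) - cl$origin[1]
  covered <- sp$profile$position_m + cl$s_start
  in_zone <- covered >= srange[1] & covered <= srange[2]
  expect_true(all(sp$profile$stagnant_pct[in_zone] > 0))
  # and sections clear of the disc report no stagnation at all
  expect_true(any(sp$profile$stagnant_pct == 0))
})

test_that("stagnant fraction is non-decreasing in the threshold", {
  cs <- coarse_case(60)
  p1 <- stagnation_profile(cs$field, cs$mesh, threshold_fraction = 0.03,
                           n_sections = 20)
  p2 <- stagnation_profile(cs$field, cs$mesh, threshold_fraction = 0.06,
                           n_sections = 20)
  p3 <- stagnation_profile(cs$field, cs$mesh, threshold_fraction = 0.12,
                           n_sections = 20)
  expect_true(all(p2$profile$stagnant_pct >= p1$profile$stagnant_pct))
  expect_true(all(p3$profile$stagnant_pct >= p2$profile$stagnant_pct))
  expect_error(stagnation_profile(cs$field, cs$mesh, threshold_fraction = 0),
               "threshold_fraction")
})

test_that("junction solve carries coupled recirculation and WSS landmarks", {
  cs <- coarse_case(60)
  met <- cs$metrics
  expect_true(met$peak_wss_landmark %in% c("heel", "toe", "hood", "floor"))
  expect_gte(met$recirc_area_mm2, 0)
  expect_true(met$max_stagnation_pct >= 0 && met$max_stagnation_pct <= 100)
  # recirculation zones live inside the fluid domain
  rz <- met$recirculation
  if (length(rz)) {
    cells <- unlist(lapply(rz, `[[`, "cells"))
    expect_true(all(cells >= 1 & cells <= nrow(cs$mesh$cells)))
  }
})

test_that("flow rendering is deterministic and writes PNG files", {
  m <- channel_mesh(2.3e-3, 11.5e-3, 30, 12)
  pf <- poiseuille_field(m)
  f1 <- file.path(tempdir(), "speed1.png")
  f2 <- file.path(tempdir(), "speed2.png")
  render_flow(pf, m, "speed_map", file = f1)
  render_flow(pf, m, "speed_map", file = f2)
  expect_true(file.exists(f1) && file.size(f1) > 0)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # streamlines of a unidirectional field never turn back
  paths <- etsflow:::trace_streamlines(pf, m)
  expect_gt(length(paths), 0)
  for (p in paths) expect_true(all(diff(p[, 1]) > -1e-12))
  fw <- file.path(tempdir(), "wss.png")
  render_flow(pf, m, "wss_map", file = fw, fluid = fluid_properties())
  expect_true(file.exists(fw) && file.size(fw) > 0)
})
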