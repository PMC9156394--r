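test_that("single-angle sweep yields one row and no fit", {
  res <- run_sweep(60, coarse_config(), verbose = FALSE)
  expect_s3_class(res, "sweep_result")
  expect_equal(nrow(res$summary), 1L)
  expect_null(res$fit)
})

test_that("sweep writes a stable report and is bit-identical on rerun", {
  cfg <- coarse_config()
  d1 <- file.path(tempdir(), "sweep1"); d2 <- file.path(tempdir(), "sweep2")
  r1 <- run_sweep(c(45, 90), cfg, report_dir = d1, verbose = FALSE)
  r2 <- run_sweep(c(45, 90), cfg, report_dir = d2, verbose = FALSE)
  expect_identical(names(r1$summary),
                   c("angle_deg", "max_stagnation_pct", "recirc_area_mm2",
                     "peak_wss_pa", "peak_wss_landmark", "iterations"))
  expect_identical(r1$summary, r2$summary)
  s1 <- file.path(d1, "sweep_summary.csv"); s2 <- file.path(d2, "sweep_summary.csv")
  expect_true(file.exists(s1))
  expect_identical(readLines(s1), readLines(s2))
  expect_equal(r1$fit$n, 2L)
  for (f in c("angle_045.vtk", "angle_045_stagnation.csv", "angle_045_wss.csv",
              "angle_045_metrics.json", "angle_045_residuals.csv",
              "resolved_config.yaml", "fit_summary.json"))
    expect_true(file.exists(file.path(d1, f)))
})

test_that("sweep aborts naming the failing angle", {
  cfg <- coarse_config()
  cfg$solver$max_outer_iterations <- 3
  expect_error(run_sweep(c(45), cfg, verbose = FALSE),
               "sweep aborted at angle 45")
  expect_error(run_sweep(c(45, 120), coarse_config(), verbose = FALSE))
})

test_that("yaml configuration merges over the defaults", {
  p <- file.path(tempdir(), "cfg.yaml")
  writeLines(c("mesh:", "  target_edge_length_mm: 0.3",
               "flow:", "  inlet_velocity_mm_s: 50"), p)
  cfg <- read_config(p)
  expect_equal(cfg$mesh$target_edge_length_mm, 0.3)
  expect_equal(cfg$flow$inlet_velocity_mm_s, 50)
  expect_equal(cfg$fluid$viscosity_pa_s, 3.5e-3)      # untouched default
  expect_equal(cfg$geometry$donor_diameter_mm, 2.3)
})

test_that("vtk export writes a readable legacy unstructured grid", {
  m <- channel_mesh(2.3e-3, 11.5e-3, 10, 6)
  pf <- poiseuille_field(m)
  f <- file.path(tempdir(), "field.vtk")
  write_field_vtk(pf, m, f)
  lines <- readLines(f)
  expect_equal(lines[1], "# vtk DataFile Version 2.0")
  expect_true(any(grepl("^DATASET UNSTRUCTURED_GRID", lines)))
  expect_true(any(grepl(sprintf("^POINTS %d double", nrow(m$nodes)), lines)))
  expect_true(any(grepl(sprintf("^CELL_DATA %d", nrow(m$cells)), lines)))
  expect_true(any(grepl("^VECTORS velocity double", lines)))
  expect_true(any(grepl("^SCALARS pressure double 1", lines)))
})
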