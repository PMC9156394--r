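# Shared fixtures. Junction solves are expensive, so they are built lazily
# and cached for the whole test session.

study_vessels <- function() {
  list(donor = vessel_spec(2.3e-3, 200e-6, 184e-3),
       graft = vessel_spec(2.3e-3, 200e-6, 103e-3))
}

study_geometry <- function(angle_deg) {
  v <- study_vessels()
  anastomosis_geometry(v$donor, v$graft, angle_deg, 100e-3)
}

# Coarse configuration for fast end-to-end junction tests: short truncation
# and a coarse grid, still respecting every geometric invariant.
coarse_config <- function() {
  cfg <- default_config()
  cfg$geometry$truncation_diameters <- list(upstream = 5, downstream = 5,
                                            graft = 5)
  cfg$mesh$target_edge_length_mm <- 0.22
  cfg
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# Coarse junction case solved once per session.
coarse_case <- function(angle_deg = 60) {
  cached(paste0("case", angle_deg), {
    run_case(angle_deg, coarse_config(), keep_field = TRUE)
  })
}

# Converged straight-channel solution (20 cells across), solved once.
channel_case <- function() {
  cached("channel", {
    mesh <- channel_mesh(2.3e-3, 23e-3, 100, 20)
    fluid <- fluid_properties()
    bc <- boundary_conditions()
    field <- solve_steady(mesh, fluid, bc, solver_config())
    list(mesh = mesh, field = field, fluid = fluid, bc = bc)
  })
}

# Independent brute-force OLS oracle (closed form).
ols_oracle <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - slope * x - intercept
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}
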