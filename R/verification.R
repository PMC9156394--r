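# Analytic fields and constructed fixtures for verifying the solver and
# the post-processing chain without any flow solution. Everything here is
# deterministic: fixtures are closed forms evaluated on a mesh.

#' Uniform structured channel mesh (verification fixture)
#'
#' A plain rectangular channel meshed with an exactly uniform `nx` by `ny`
#' grid (no grading, no wall refinement), as needed by the analytic
#' benchmarks where uniform spacing makes the discrete operators exact.
#'
#' @param width channel width (m).
#' @param length channel length (m).
#' @param nx,ny cell counts along and across the channel.
#' @param element `"quad"` or `"tri"`.
#' @return an `ets_mesh` of a channel with patches `inlet`,
#'   `outlet_donor`, `wall`.
#' @export
channel_mesh <- function(width, length, nx, ny, element = c("quad", "tri")) {
  element <- match.arg(element)
  outline <- channel_outline(width, length)
  structured_block_mesh(seq(0, length, length.out = nx + 1L),
                        seq(0, width, length.out = ny + 1L),
                        outline, element, length / nx, region = "channel")
}

# Assemble a flow_field-shaped object from analytic cell values.
analytic_field <- function(mesh, u, v, p, bc, fluid, provenance) {
  structure(list(u = u, v = v, p = p,
                 p_ref = bc$outlet_reference_pressure,
                 face_flux = NULL, residual_history = NULL,
                 iterations = 0L, converged = NA,
                 fluid = fluid, bc = bc, provenance = provenance),
            class = "flow_field")
}

#' Exact plane Poiseuille field on a channel mesh
#'
#' `u(y) = 6 U y (h - y) / h^2`, `v = 0`, with the matching linear pressure
#' (gauge zero at the outlet). Exactly divergence-free in the continuum;
#' the discrete continuity residual of the evaluated field vanishes to
#' rounding on a uniform channel mesh.
#'
#' @param mesh a channel `ets_mesh` (from [channel_mesh()] or
#'   [generate_mesh()] on a [channel_outline()]).
#' @param U_mean mean speed (m/s).
#' @param fluid [fluid_properties()].
#' @return a `flow_field` with analytic cell values.
#' @export
poiseuille_field <- function(mesh, U_mean = 0.1, fluid = fluid_properties()) {
  if (mesh$outline$kind != "channel")
    stop("fixture error: poiseuille_field needs a straight channel mesh")
  h <- mesh$outline$params$d
  L <- mesh$outline$params$x_end
  y <- mesh$cell_centroid[, 2]; x <- mesh$cell_centroid[, 1]
  u <- 6 * U_mean * y * (h - y) / h^2
  p <- 12 * fluid$viscosity * U_mean / h^2 * (L - x)
  bc <- boundary_conditions(inlet_mean_velocity = U_mean)
  analytic_field(mesh, u, numeric(length(u)), p, bc, fluid, "poiseuille")
}

#' Manufactured steady Navier-Stokes case
#'
#' A smooth divergence-free velocity field derived from the stream function
#' `psi = A sin(kx x) sin(ky y)` with pressure `B cos(kx x) cos(ky y)`,
#' together with the exact body force that makes the pair a steady
#' incompressible Navier-Stokes solution. Used as the solver convergence
#' oracle (method of manufactured solutions): solving with this body force
#' and the exact Dirichlet boundary velocities must recover the field at
#' first order or better under mesh refinement.
#'
#' @param mesh any `ets_mesh`.
#' @param wavenumbers integer vector `c(a, b)`: `kx = a pi / Lx`,
#'   `ky = b pi / Ly` over the mesh bounding box. `c(0, 0)` gives the zero
#'   field and zero force.
#' @param amplitude stream-function amplitude `A` (m^2/s); the default
#'   gives peak speeds of ~0.02 m/s on millimetre-scale meshes, mild
#'   enough that convergence studies sit in the asymptotic regime.
#' @param fluid [fluid_properties()].
#' @return list with `field` (exact `flow_field`), `body_force` (function
#'   of `x, y` returning the force density matrix), `velocity` (function
#'   returning exact `cbind(u, v)`, usable as the solver's `dirichlet`
#'   argument) and `exact` (list of scalar field functions).
#' @export
manufactured_case <- function(mesh, wavenumbers = c(1, 1),
                              amplitude = NULL, fluid = fluid_properties()) {
  xr <- range(mesh$nodes[, 1]); yr <- range(mesh$nodes[, 2])
  kx <- wavenumbers[1] * pi / diff(xr)
  ky <- wavenumbers[2] * pi / diff(yr)
  A <- amplitude %||% (0.02 / max(ky, 1e-12))
  if (all(wavenumbers == 0)) A <- 0
  rho <- fluid$density; mu <- fluid$viscosity
  B <- rho * 0.25 * (A * max(kx, ky))^2 + 1e-3   # arbitrary smooth pressure
  x0 <- xr[1]; y0 <- yr[1]
  uf <- function(x, y)  A * ky * sin(kx * (x - x0)) * cos(ky * (y - y0))
  vf <- function(x, y) -A * kx * cos(kx * (x - x0)) * sin(ky * (y - y0))
  pf <- function(x, y)  B * cos(kx * (x - x0)) * cos(ky * (y - y0))
  # analytic derivatives
  ux <- function(x, y)  A * ky * kx * cos(kx * (x - x0)) * cos(ky * (y - y0))
  uy <- function(x, y) -A * ky^2 * sin(kx * (x - x0)) * sin(ky * (y - y0))
  vx <- function(x, y)  A * kx^2 * sin(kx * (x - x0)) * sin(ky * (y - y0))
  vy <- function(x, y) -A * kx * ky * cos(kx * (x - x0)) * cos(ky * (y - y0))
  px_ <- function(x, y) -B * kx * sin(kx * (x - x0)) * cos(ky * (y - y0))
  py_ <- function(x, y) -B * ky * cos(kx * (x - x0)) * sin(ky * (y - y0))
  lap <- -(kx^2 + ky^2)
  body_force <- function(x, y) {
    u <- uf(x, y); v <- vf(x, y)
    fx <- rho * (u * ux(x, y) + v * uy(x, y)) + px_(x, y) - mu * lap * u
    fy <- rho * (u * vx(x, y) + v * vy(x, y)) + py_(x, y) - mu * lap * v
    cbind(fx, fy)
  }
  velocity <- function(x, y) cbind(uf(x, y), vf(x, y))
  cc <- mesh$cell_centroid
  bc <- boundary_conditions(inlet_mean_velocity = max(abs(A * ky), 1e-6))
  field <- analytic_field(mesh, uf(cc[, 1], cc[, 2]), vf(cc[, 1], cc[, 2]),
                          pf(cc[, 1], cc[, 2]), bc, fluid, "manufactured")
  list(field = field, body_force = body_force, velocity = velocity,
       exact = list(u = uf, v = vf, p = pf))
}

#' Constructed stagnation fixture
#'
#' A piecewise plug field on a channel mesh in which exactly
#' `stagnant_width_fraction` of every cross-section (the band nearest the
#' lower wall) has zero speed and the rest moves at the inlet speed, so the
#' stagnation profile of the fixture is known by construction at any
#' positive threshold.
#'
#' @param mesh a channel `ets_mesh`.
#' @param stagnant_width_fraction fraction in [0, 1] of the width at rest.
#' @param U_mean moving-band speed (m/s).
#' @param fluid [fluid_properties()].
#' @return a `flow_field`.
#' @export
stagnation_fixture <- function(mesh, stagnant_width_fraction, U_mean = 0.1,
                               fluid = fluid_properties()) {
  if (mesh$outline$kind != "channel")
    stop("fixture error: stagnation_fixture needs a straight channel mesh")
  if (stagnant_width_fraction < 0 || stagnant_width_fraction > 1)
    stop("stagnant_width_fraction must lie in [0, 1]")
  h <- mesh$outline$params$d
  y <- mesh$cell_centroid[, 2]
  u <- ifelse(y < stagnant_width_fraction * h, 0, U_mean)
  bc <- boundary_conditions(inlet_mean_velocity = U_mean)
  analytic_field(mesh, u, numeric(length(u)), numeric(length(u)), bc, fluid,
                 sprintf("stagnation_fixture_%g", stagnant_width_fraction))
}

#' Solid-body vortex fixture
#'
#' A disc of solid-body rotation embedded in a uniform background stream:
#' inside radius `R` around `center` the velocity is `omega x r`, outside
#' it is `(U, 0)`. The reversed-axial region is exactly the half-disc where
#' the rotational `u` is negative, giving an analytic recirculation-area
#' oracle of `pi R^2 / 2`.
#'
#' @param mesh an `ets_mesh`.
#' @param center disc centre (m).
#' @param radius disc radius (m).
#' @param omega angular speed (rad/s); choose `omega * R` of the order of
#'   the background speed.
#' @param U_background background axial speed (m/s).
#' @param fluid [fluid_properties()].
#' @return a `flow_field`.
#' @export
vortex_fixture <- function(mesh, center, radius, omega = NULL,
                           U_background = 0.1, fluid = fluid_properties()) {
  cc <- mesh$cell_centroid
  omega <- omega %||% (2 * U_background / radius)
  dx <- cc[, 1] - center[1]; dy <- cc[, 2] - center[2]
  inside <- dx^2 + dy^2 <= radius^2
  u <- ifelse(inside, -omega * dy, U_background)
  v <- ifelse(inside, omega * dx, 0)
  bc <- boundary_conditions(inlet_mean_velocity = U_background)
  analytic_field(mesh, u, v, numeric(length(u)), bc, fluid, "vortex")
}
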