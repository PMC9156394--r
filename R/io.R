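# Plain-text exporters: VTK legacy unstructured grids, CSV profiles,
# JSON metrics, and the YAML run configuration.

#' Write mesh (and optional cell data) as VTK legacy unstructured grid
#'
#' ASCII VTK 2.0 legacy format, readable by ParaView/VTK. Cell data arrays
#' are written as scalars (numeric vectors) or 3-component vectors
#' (2-column matrices, zero-padded to 3-D). Patch labels are encoded as an
#' integer cell array on a companion boundary mesh is not written; the
#' landmark points are appended as field data comments.
#'
#' @param mesh an `ets_mesh`.
#' @param file output path (`.vtk`).
#' @param cell_data named list of per-cell numeric vectors or 2-column
#'   matrices.
#' @return invisibly, `file`.
#' @export
write_vtk <- function(mesh, file, cell_data = list()) {
  nodes <- mesh$nodes; cells <- mesh$cells
  nv <- ncol(cells); nc <- nrow(cells)
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 2.0")
  wl("ets anastomosis planar mesh (lengths in m)")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS %d double", nrow(nodes))
  writeLines(paste(format(nodes[, 1], digits = 17),
                   format(nodes[, 2], digits = 17), "0"), con)
  wl("CELLS %d %d", nc, nc * (nv + 1L))
  writeLines(paste(nv, apply(cells - 1L, 1, paste, collapse = " ")), con)
  wl("CELL_TYPES %d", nc)
  writeLines(as.character(rep(if (nv == 4L) 9L else 5L, nc)), con)
  wl("CELL_DATA %d", nc)
  wl("SCALARS region int 1")
  wl("LOOKUP_TABLE default")
  writeLines(as.character(match(mesh$cell_region,
                                c("channel", "donor", "graft")) - 1L), con)
  if (length(cell_data)) {
    for (nm in names(cell_data)) {
      v <- cell_data[[nm]]
      if (is.matrix(v)) {
        wl("VECTORS %s double", nm)
        writeLines(paste(format(v[, 1], digits = 17),
                         format(v[, 2], digits = 17), "0"), con)
      } else {
        wl("SCALARS %s double 1", nm)
        wl("LOOKUP_TABLE default")
        writeLines(format(v, digits = 17), con)
      }
    }
  }
  lm <- mesh$outline$landmarks
  if (length(lm)) {
    wl("FIELD landmarks %d", length(lm))
    for (nm in names(lm)) {
      wl("landmark_%s 3 1 double", nm)
      wl("%s %s 0", format(lm[[nm]][1], digits = 17),
         format(lm[[nm]][2], digits = 17))
    }
  }
  invisible(file)
}

#' Write the boundary of a mesh as VTK line cells with patch codes
#'
#' Each boundary face becomes a `VTK_LINE` cell carrying an integer
#' `patch` cell array; the code-to-name mapping is written in the header
#' comment line.
#'
#' @param mesh an `ets_mesh`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_boundary_vtk <- function(mesh, file) {
  bnd <- which(is.na(mesh$face_neigh))
  patches <- sort(unique(mesh$face_patch[bnd]))
  code <- match(mesh$face_patch[bnd], patches)
  con <- file(file, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 2.0")
  wl("boundary patches: %s",
     paste(sprintf("%d=%s", seq_along(patches), patches), collapse = " "))
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl("POINTS %d double", nrow(mesh$nodes))
  writeLines(paste(format(mesh$nodes[, 1], digits = 17),
                   format(mesh$nodes[, 2], digits = 17), "0"), con)
  wl("CELLS %d %d", length(bnd), 3 * length(bnd))
  writeLines(paste(2, mesh$face_nodes[bnd, 1] - 1L,
                   mesh$face_nodes[bnd, 2] - 1L), con)
  wl("CELL_TYPES %d", length(bnd))
  writeLines(as.character(rep(3L, length(bnd))), con)
  wl("CELL_DATA %d", length(bnd))
  wl("SCALARS patch int 1")
  wl("LOOKUP_TABLE default")
  writeLines(as.character(code), con)
  invisible(file)
}

#' Write a solved field as VTK
#'
#' Convenience wrapper around [write_vtk()] adding `velocity` (m/s),
#' `pressure` (Pa, absolute: gauge plus the outlet reference) and `speed`.
#'
#' @param field a `flow_field`.
#' @param mesh its mesh.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_field_vtk <- function(field, mesh, file) {
  write_vtk(mesh, file, cell_data = list(
    velocity = cbind(field$u, field$v),
    pressure = field$p + field$p_ref,
    speed = sqrt(field$u^2 + field$v^2)))
}

#' Write a profile as CSV with unit-bearing headers
#' @param profile data.frame (e.g. from [wall_shear_stress()] or
#'   [stagnation_profile()]).
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_profile_csv <- function(profile, file) {
  utils::write.csv(profile, file, row.names = FALSE)
  invisible(file)
}

#' Write run metrics as JSON
#' @param metrics named list of scalars (numbers or strings).
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_metrics_json <- function(metrics, file) {
  jsonlite::write_json(metrics, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' Default run configuration
#'
#' All geometry in millimetres and degrees, pressure in mmHg (the units of
#' the surgical literature); converted to SI internally. The defaults are
#' the study conditions: 2.3 mm vessels, 200 micron walls, 184/103 mm
#' donor/graft lengths, junction 100 mm from the donor inlet, blood
#' viscosity 3.5e-3 Pa s and density 1060 kg/m^3, inlet mean speed
#' 100 mm/s, outlets pressurized to 100 mmHg, convergence tolerance 1e-4.
#'
#' @return nested named list of configuration values.
#' @export
default_config <- function() {
  list(
    geometry = list(
      donor_diameter_mm = 2.3, graft_diameter_mm = 2.3,
      wall_thickness_um = 200,
      donor_length_mm = 184, graft_length_mm = 103,
      junction_offset_mm = 100,
      truncation_diameters = list(upstream = 15, downstream = 15, graft = 15)),
    mesh = list(target_edge_length_mm = 0.12, element = "quad",
                axial_growth = 1.15, axial_cap = 5),
    fluid = list(viscosity_pa_s = 3.5e-3, density_kg_m3 = 1060),
    flow = list(inlet_velocity_mm_s = 100, inlet_profile = "parabolic",
                pressure_mmhg = 100),
    solver = list(convergence_tolerance = 1e-4, max_outer_iterations = 2000,
                  relax_velocity = 0.7, relax_pressure = 0.3,
                  min_mesh_angle_deg = 15),
    postprocess = list(stagnation_threshold = 0.05, n_sections = 50,
                       n_samples = 200, recirc_min_area_mm2 = 0.01),
    angles_deg = c(30, 45, 60, 75, 90))
}

#' Read a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_config()]: any key not
#' present keeps its default.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_rec <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_rec(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_rec(cfg, user)
}

# Construct the typed model objects from a configuration list.
config_objects <- function(config, angle_deg) {
  g <- config$geometry
  donor <- vessel_spec(mm_to_m(g$donor_diameter_mm),
                       g$wall_thickness_um * 1e-6,
                       mm_to_m(g$donor_length_mm))
  graft <- vessel_spec(mm_to_m(g$graft_diameter_mm),
                       g$wall_thickness_um * 1e-6,
                       mm_to_m(g$graft_length_mm))
  geom <- anastomosis_geometry(donor, graft, angle_deg,
                               mm_to_m(g$junction_offset_mm))
  trunc <- domain_truncation(g$truncation_diameters$upstream,
                             g$truncation_diameters$downstream,
                             g$truncation_diameters$graft)
  fluid <- fluid_properties(config$fluid$viscosity_pa_s,
                            config$fluid$density_kg_m3)
  bc <- boundary_conditions(mm_to_m(config$flow$inlet_velocity_mm_s),
                            config$flow$inlet_profile,
                            mmhg_to_pa(config$flow$pressure_mmhg))
  scfg <- solver_config(config$solver$convergence_tolerance,
                        config$solver$max_outer_iterations,
                        config$solver$relax_velocity,
                        config$solver$relax_pressure,
                        config$solver$min_mesh_angle_deg)
  list(geom = geom, trunc = trunc, fluid = fluid, bc = bc, solver = scfg)
}
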