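# The five-angle experiment: mesh, solve and post-process each anastomotic
# angle, aggregate the metrics and fit the stagnation-versus-angle line.

#' Run one anastomosis case end to end
#'
#' Builds the outline and mesh for one anastomotic angle, solves the steady
#' flow and computes the per-case metrics.
#'
#' @param angle_deg anastomotic angle (degrees).
#' @param config configuration list (see [default_config()]).
#' @param keep_field keep the full `flow_field` and mesh in the result.
#' @return list with `angle_deg`, `metrics` (see [case_metrics()]), and
#'   optionally `mesh`, `field`.
#' @export
run_case <- function(angle_deg, config = default_config(),
                     keep_field = FALSE) {
  obj <- config_objects(config, angle_deg)
  outline <- build_outline(obj$geom, obj$trunc)
  mesh <- generate_mesh(outline, mm_to_m(config$mesh$target_edge_length_mm),
                        element = config$mesh$element,
                        axial_growth = config$mesh$axial_growth,
                        axial_cap = config$mesh$axial_cap)
  field <- solve_steady(mesh, obj$fluid, obj$bc, obj$solver)
  met <- case_metrics(field, mesh, obj$fluid,
                      threshold_fraction = config$postprocess$stagnation_threshold,
                      n_sections = config$postprocess$n_sections)
  out <- list(angle_deg = angle_deg, metrics = met)
  if (keep_field) { out$mesh <- mesh; out$field <- field }
  out
}

#' Run the anastomotic-angle sweep
#'
#' Meshes, solves and post-processes every requested angle, aggregates the
#' summary table (one row per angle: maximum graft stagnation percentage,
#' total recirculation area, peak wall shear stress and its landmark,
#' solver iterations) and, when at least two angles are present, fits the
#' stagnation-versus-angle line by OLS. Deterministic: rerunning with the
#' same configuration reproduces the summary bit for bit.
#'
#' @param angles angles in degrees, each in (0, 90].
#' @param config configuration list (see [default_config()]).
#' @param report_dir optional directory; when given, per-angle VTK fields,
#'   profile CSVs, optional images, the summary CSV, the resolved
#'   configuration and a metrics JSON are written there.
#' @param write_images also render speed/streamline/WSS PNGs per angle
#'   (requires `report_dir`).
#' @param keep_fields keep all solved fields in the returned object.
#' @param verbose print progress.
#' @return an object of class `sweep_result`: `summary` data.frame, `fit`
#'   (`linear_fit` or `NULL`), `config`, and per-angle details in `cases`.
#' @export
run_sweep <- function(angles = default_config()$angles_deg,
                      config = default_config(), report_dir = NULL,
                      write_images = FALSE, keep_fields = FALSE,
                      verbose = interactive()) {
  stopifnot(length(angles) >= 1, all(angles > 0 & angles <= 90))
  if (!is.null(report_dir))
    dir.create(report_dir, showWarnings = FALSE, recursive = TRUE)
  cases <- list()
  rows <- vector("list", length(angles))
  for (i in seq_along(angles)) {
    a <- angles[i]
    if (verbose) message(sprintf("angle %g: meshing and solving ...", a))
    cs <- tryCatch(
      run_case(a, config, keep_field = keep_fields || !is.null(report_dir)),
      error = function(e)
        stop(sprintf("sweep aborted at angle %g (stage: %s)", a,
                     conditionMessage(e)), call. = FALSE))
    m <- cs$metrics
    rows[[i]] <- data.frame(
      angle_deg = a,
      max_stagnation_pct = m$max_stagnation_pct,
      recirc_area_mm2 = m$recirc_area_mm2,
      peak_wss_pa = m$peak_wss_pa,
      peak_wss_landmark = m$peak_wss_landmark,
      iterations = m$iterations)
    if (!is.null(report_dir)) {
      base <- file.path(report_dir, sprintf("angle_%03d", round(a)))
      write_field_vtk(cs$field, cs$mesh, paste0(base, ".vtk"))
      write_profile_csv(m$stagnation$profile, paste0(base, "_stagnation.csv"))
      write_profile_csv(m$wss$profile, paste0(base, "_wss.csv"))
      write_profile_csv(cs$field$residual_history,
                        paste0(base, "_residuals.csv"))
      write_metrics_json(list(
        angle_deg = a, max_stagnation_pct = m$max_stagnation_pct,
        recirculation_area_mm2 = m$recirc_area_mm2,
        peak_wss_pa = m$peak_wss_pa,
        peak_wss_landmark = m$peak_wss_landmark,
        iterations = m$iterations), paste0(base, "_metrics.json"))
      if (write_images) {
        render_flow(cs$field, cs$mesh, "speed_map",
                    file = paste0(base, "_speed.png"))
        render_flow(cs$field, cs$mesh, "streamlines",
                    file = paste0(base, "_streamlines.png"))
        render_flow(cs$field, cs$mesh, "wss_map",
                    file = paste0(base, "_wss.png"))
      }
      if (!keep_fields) { cs$field <- NULL; cs$mesh <- NULL }
    }
    cases[[as.character(a)]] <- cs
  }
  summary <- do.call(rbind, rows)
  fit <- if (length(angles) >= 2)
    ols_fit(summary$angle_deg, summary$max_stagnation_pct) else NULL
  res <- structure(list(summary = summary, fit = fit, config = config,
                        cases = cases), class = "sweep_result")
  if (!is.null(report_dir)) {
    utils::write.csv(summary, file.path(report_dir, "sweep_summary.csv"),
                     row.names = FALSE)
    yaml::write_yaml(config, file.path(report_dir, "resolved_config.yaml"))
    if (!is.null(fit))
      write_metrics_json(list(slope_pct_per_deg = fit$slope,
                              intercept_pct = fit$intercept,
                              r_squared = fit$r_squared, n = fit$n),
                         file.path(report_dir, "fit_summary.json"))
  }
  res
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("anastomotic angle sweep\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$fit)) {
    cat("stagnation vs angle: ")
    print(x$fit)
  }
  invisible(x)
}
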