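# Post-processing of converged flow fields: wall shear stress profiles,
# cross-sectional stagnation in the graft, recirculation zones and raster
# renderings of the solution.

# Order all boundary faces into the closed boundary walk of the domain and
# return them with cumulative arc length. Orientation follows the outline
# polygon (counter-clockwise).
boundary_walk <- function(mesh) {
  bnd <- which(is.na(mesh$face_neigh))
  fn <- mesh$face_nodes[bnd, , drop = FALSE]
  nxt <- integer(max(fn))
  nxt[fn[, 1]] <- seq_along(bnd)     # face leaving node a (owner traversal a->b)
  ord <- integer(length(bnd))
  cur <- 1L
  for (k in seq_along(bnd)) {
    ord[k] <- cur
    cur <- nxt[fn[cur, 2]]
  }
  faces <- bnd[ord]
  len <- mesh$face_length[faces]
  data.frame(face = faces, arc = cumsum(len) - len / 2,
             patch = mesh$face_patch[faces])
}

#' Wall shear stress profile
#'
#' Computes the wall shear stress magnitude `tau = eta * |u_t| / dn` on
#' every wall face from the tangential velocity of the wall-adjacent cell
#' and its wall-normal distance (one-sided first-order difference). Faces
#' are ordered by arc length along the boundary walk; the location of the
#' global peak is assigned to the nearest junction landmark (heel, toe,
#' hood, floor) when the mesh carries landmarks.
#'
#' @param field a converged `flow_field`.
#' @param mesh the `ets_mesh` it was solved on.
#' @param fluid [fluid_properties()].
#' @return an object of class `wss_profile`: data.frame `profile` with
#'   columns `arc_m`, `tau_pa`, `x`, `y`; `peak_tau_pa`; `peak_landmark`
#'   (or `NA`); `peak_xy`.
#' @export
wall_shear_stress <- function(field, mesh, fluid) {
  stopifnot(inherits(mesh, "ets_mesh"))
  bw <- boundary_walk(mesh)
  wall <- bw[bw$patch == "wall", ]
  if (nrow(wall) == 0) stop("mesh has no wall patch")
  f <- wall$face
  o <- mesh$face_owner[f]
  nrm <- mesh$face_normal[f, , drop = FALSE]
  fcent <- mesh$face_centroid[f, , drop = FALSE]
  dvec <- fcent - mesh$cell_centroid[o, , drop = FALSE]
  dn <- abs(dvec[, 1] * nrm[, 1] + dvec[, 2] * nrm[, 2])
  un <- field$u[o] * nrm[, 1] + field$v[o] * nrm[, 2]
  ut1 <- field$u[o] - un * nrm[, 1]
  ut2 <- field$v[o] - un * nrm[, 2]
  tau <- fluid$viscosity * sqrt(ut1^2 + ut2^2) / dn
  prof <- data.frame(arc_m = wall$arc, tau_pa = tau,
                     x = fcent[, 1], y = fcent[, 2])
  ipk <- which.max(tau)
  peak_xy <- c(prof$x[ipk], prof$y[ipk])
  lm <- mesh$outline$landmarks
  peak_landmark <- NA_character_
  if (length(lm)) {
    dists <- vapply(lm, function(p) sum((p - peak_xy)^2), numeric(1))
    peak_landmark <- names(lm)[which.min(dists)]
  }
  structure(list(profile = prof, peak_tau_pa = tau[ipk],
                 peak_landmark = peak_landmark, peak_xy = peak_xy),
            class = "wss_profile")
}

#' @export
print.wss_profile <- function(x, ...) {
  cat(sprintf("wall shear stress: %d wall faces, peak %.3g Pa%s\n",
              nrow(x$profile), x$peak_tau_pa,
              if (!is.na(x$peak_landmark))
                paste0(" at ", x$peak_landmark) else ""))
  invisible(x)
}

# Speed magnitude at mesh nodes: inverse-distance average of adjacent cell
# values; no-slip wall nodes pinned to zero.
node_speed <- function(field, mesh) {
  spd <- sqrt(field$u^2 + field$v^2)
  nn <- nrow(mesh$nodes); nv <- ncol(mesh$cells); nc <- nrow(mesh$cells)
  ni <- as.vector(mesh$cells); cj <- rep(seq_len(nc), nv)
  d <- sqrt((mesh$nodes[ni, 1] - mesh$cell_centroid[cj, 1])^2 +
            (mesh$nodes[ni, 2] - mesh$cell_centroid[cj, 2])^2)
  w <- 1 / pmax(d, 1e-300)
  num <- den <- numeric(nn)
  sw <- tapply(w * spd[cj], ni, sum); num[as.integer(names(sw))] <- sw
  sd_ <- tapply(w, ni, sum); den[as.integer(names(sd_))] <- sd_
  out <- ifelse(den > 0, num / den, 0)
  # solver fields honour no-slip: pin wall nodes to zero so the near-wall
  # speed ramp is resolved; constructed fixtures (no convergence flag) are
  # taken at face value
  if (isTRUE(field$converged)) {
    bnd <- which(is.na(mesh$face_neigh))
    wall_nodes <- unique(as.vector(
      mesh$face_nodes[bnd[mesh$face_patch[bnd] == "wall"], ]))
    out[wall_nodes] <- 0
  }
  out
}

# Default sampling centreline of a mesh: along the graft axis for junction
# meshes (starting at the first fully-in-graft perpendicular section),
# along the channel axis for channel meshes.
default_centerline <- function(mesh, span_diameters = 10) {
  p <- mesh$outline$params
  if (mesh$outline$kind == "junction") {
    s0 <- (p$dg / 2) / tan(p$theta) * 1.0001   # first section inside the graft
    span <- min(span_diameters * p$dg, p$L_g * 0.98 - s0)
    list(origin = p$mouth, dir = p$e, width = p$dg,
         s_start = s0, s_end = s0 + span, region = "graft")
  } else {
    L <- p$x_end
    list(origin = c(0, p$d / 2), dir = c(1, 0), width = p$d,
         s_start = 0.02 * L, s_end = 0.98 * L, region = "channel")
  }
}

#' Cross-sectional stagnation profile
#'
#' At `n_sections` evenly spaced cross-sections perpendicular to the graft
#' centreline (junction meshes) or channel axis (channel meshes), the
#' stagnant fraction is the percentage of the section width where the flow
#' speed falls below `threshold_fraction` times the inlet mean speed.
#' Sections are sampled with `n_samples` points each, assigned the speed of
#' the nearest cell in the sampled region.
#'
#' @param field a `flow_field` (solver output or analytic fixture).
#' @param mesh the mesh the field lives on.
#' @param centerline optional list (`origin`, `dir`, `width`, `s_start`,
#'   `s_end`, `region`) as produced internally by the default; `NULL` uses
#'   the graft/channel default.
#' @param threshold_fraction stagnation speed threshold as a fraction of the
#'   inlet mean speed (default 0.05).
#' @param n_sections number of cross-sections (default 50).
#' @param n_samples sample points per section (default 200).
#' @return an object of class `stagnation_profile`: data.frame `profile`
#'   (`position_m` along the centreline from its start, `stagnant_pct`),
#'   `max_stagnation` (%), `threshold_fraction`.
#' @export
stagnation_profile <- function(field, mesh, centerline = NULL,
                               threshold_fraction = 0.05,
                               n_sections = 50, n_samples = 200) {
  stopifnot(inherits(mesh, "ets_mesh"))
  if (threshold_fraction <= 0) stop("threshold_fraction must be > 0")
  cl <- centerline %||% default_centerline(mesh)
  U <- field$bc$inlet_mean_velocity
  thr <- threshold_fraction * U
  e <- cl$dir / sqrt(sum(cl$dir^2))
  nperp <- c(-e[2], e[1])
  sel <- if (cl$region == "all") rep(TRUE, nrow(mesh$cells)) else
    mesh$cell_region == cl$region
  if (!any(sel)) sel <- rep(TRUE, nrow(mesh$cells))
  cc <- mesh$cell_centroid[sel, , drop = FALSE]
  cell_size <- sqrt(max(mesh$cell_area[sel]))
  # Sampling rule: converged solver fields are sampled through node-
  # interpolated speeds (wall nodes exactly zero by no-slip, so the
  # near-wall ramp is resolved instead of inheriting the first cell-centre
  # value across the whole wall band); constructed fixture fields are
  # piecewise-constant cell data and are sampled at cell values, keeping
  # their built-in fractions exact to cell quantization.
  use_nodes <- isTRUE(field$converged)
  if (use_nodes) {
    nspd <- node_speed(field, mesh)
    cells_sel <- mesh$cells[sel, , drop = FALSE]
    nvv <- ncol(cells_sel)
  } else {
    cspd <- sqrt(field$u[sel]^2 + field$v[sel]^2)
  }
  ss <- seq(cl$s_start, cl$s_end, length.out = n_sections)
  tt <- (seq_len(n_samples) - 0.5) / n_samples - 0.5   # across the width
  pct <- numeric(n_sections)
  for (i in seq_along(ss)) {
    px <- cl$origin[1] + ss[i] * e[1] + tt * cl$width * nperp[1]
    py <- cl$origin[2] + ss[i] * e[2] + tt * cl$width * nperp[2]
    d2 <- outer(px, cc[, 1], `-`)^2 + outer(py, cc[, 2], `-`)^2
    j <- max.col(-d2, ties.method = "first")
    if (sqrt(max(d2[cbind(seq_along(j), j)])) > 4 * cell_size)
      stop("sampling error: cross-section leaves the fluid domain")
    if (use_nodes) {
      # inverse-distance interpolation from the corner nodes of the host cell
      acc <- numeric(length(j)); wsum <- numeric(length(j))
      for (k in seq_len(nvv)) {
        nk <- cells_sel[j, k]
        dk2 <- (mesh$nodes[nk, 1] - px)^2 + (mesh$nodes[nk, 2] - py)^2
        wk <- 1 / pmax(dk2, 1e-24)
        acc <- acc + wk * nspd[nk]; wsum <- wsum + wk
      }
      pct[i] <- 100 * mean(acc / wsum < thr)
    } else {
      pct[i] <- 100 * mean(cspd[j] < thr)
    }
  }
  structure(list(profile = data.frame(position_m = ss - cl$s_start,
                                      stagnant_pct = pct),
                 max_stagnation = max(pct),
                 threshold_fraction = threshold_fraction,
                 centerline = cl),
            class = "stagnation_profile")
}

#' @export
print.stagnation_profile <- function(x, ...) {
  cat(sprintf(
    "stagnation profile: %d sections, threshold %.3g x inlet speed, max %.1f%%\n",
    nrow(x$profile), x$threshold_fraction, x$max_stagnation))
  invisible(x)
}

#' Recirculation zones
#'
#' Cells whose velocity component along the local vessel axis (graft axis
#' inside the graft, donor axis inside the donor/channel) is negative,
#' grouped into edge-connected components; components below `min_area` are
#' discarded. Each zone is assigned the nearest junction landmark of its
#' area-weighted centroid.
#'
#' @param field a `flow_field`.
#' @param mesh the mesh it was solved on.
#' @param min_area area floor in m^2 (default 1e-8, i.e. 0.01 mm^2).
#' @return list of `recirculation_zone` objects (fields `cells`, `area_m2`,
#'   `centroid`, `landmark`), with attribute `total_area_m2`; the list
#'   carries class `recirculation_zones`.
#' @export
recirculation_zones <- function(field, mesh, min_area = 1e-8) {
  stopifnot(inherits(mesh, "ets_mesh"))
  U <- field$bc$inlet_mean_velocity
  p <- mesh$outline$params
  ax <- matrix(c(1, 0), nrow(mesh$cells), 2, byrow = TRUE)
  if (mesh$outline$kind == "junction") {
    gr <- mesh$cell_region == "graft"
    ax[gr, 1] <- p$e[1]; ax[gr, 2] <- p$e[2]
  }
  axial <- field$u * ax[, 1] + field$v * ax[, 2]
  rev <- which(axial < -1e-9 * U)
  zones <- list()
  total <- 0
  if (length(rev)) {
    int <- !is.na(mesh$face_neigh)
    o <- mesh$face_owner[int]; n <- mesh$face_neigh[int]
    keep <- o %in% rev & n %in% rev
    idx <- match(seq_len(nrow(mesh$cells)), rev)   # cell -> vertex id
    g <- igraph::make_graph(as.vector(rbind(idx[o[keep]], idx[n[keep]])),
                            n = length(rev), directed = FALSE)
    comp <- igraph::components(g)
    lm <- mesh$outline$landmarks
    for (k in seq_len(comp$no)) {
      cells <- rev[comp$membership == k]
      area <- sum(mesh$cell_area[cells])
      if (area < min_area) next
      w <- mesh$cell_area[cells] / area
      centroid <- c(sum(mesh$cell_centroid[cells, 1] * w),
                    sum(mesh$cell_centroid[cells, 2] * w))
      landmark <- NA_character_
      if (length(lm)) {
        dists <- vapply(lm, function(q) sum((q - centroid)^2), numeric(1))
        landmark <- names(lm)[which.min(dists)]
      }
      zones[[length(zones) + 1L]] <- structure(
        list(cells = cells, area_m2 = area, centroid = centroid,
             landmark = landmark), class = "recirculation_zone")
      total <- total + area
    }
  }
  zones <- zones[order(vapply(zones, `[[`, numeric(1), "area_m2"),
                       decreasing = TRUE)]
  structure(zones, total_area_m2 = total, class = "recirculation_zones")
}

#' @export
print.recirculation_zones <- function(x, ...) {
  cat(sprintf("recirculation: %d zone(s), total area %.4g mm^2\n",
              length(x), attr(x, "total_area_m2") * 1e6))
  for (z in x)
    cat(sprintf("  area %.4g mm^2 near %s\n", z$area_m2 * 1e6,
                z$landmark %||% "?"))
  invisible(x)
}

#' Render a flow field to a raster image
#'
#' `speed_map` fills each cell with a colour for its speed magnitude;
#' `streamlines` integrates and draws streamlines from a deterministic seed
#' grid over the speed map; `wss_map` colours the domain boundary by wall
#' shear stress. Output is deterministic given the field and mode.
#'
#' @param field a `flow_field`.
#' @param mesh the mesh it was solved on.
#' @param mode one of `"streamlines"`, `"speed_map"`, `"wss_map"`.
#' @param file output PNG path; `NULL` draws on the active device.
#' @param fluid [fluid_properties()], needed for `wss_map`.
#' @param width,height device size in pixels.
#' @return invisibly, the `file` argument.
#' @export
render_flow <- function(field, mesh, mode = c("speed_map", "streamlines",
                                              "wss_map"),
                        file = NULL, fluid = NULL,
                        width = 1200, height = 500) {
  mode <- match.arg(mode)
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off())
  }
  nodes <- mesh$nodes * 1e3                       # draw in mm
  cells <- mesh$cells
  spd <- sqrt(field$u^2 + field$v^2)
  pal <- grDevices::hcl.colors(64, "viridis")
  graphics::par(mar = c(4, 4, 3, 6))
  rngx <- range(nodes[, 1]); rngy <- range(nodes[, 2])
  graphics::plot(NA, xlim = rngx, ylim = rngy, asp = 1,
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = switch(mode, speed_map = "speed (m/s)",
                               streamlines = "streamlines",
                               wss_map = "wall shear stress (Pa)"))
  if (mode %in% c("speed_map", "streamlines")) {
    zmax <- max(spd, 1e-300)
    col <- pal[pmin(64L, 1L + floor(63.999 * spd / zmax))]
    nv <- ncol(cells)
    px <- t(cbind(matrix(nodes[cells, 1], nrow(cells), nv), NA))
    py <- t(cbind(matrix(nodes[cells, 2], nrow(cells), nv), NA))
    graphics::polygon(as.vector(px), as.vector(py), col = col, border = NA)
    draw_colorbar(pal, 0, zmax, rngx, rngy)
  }
  if (mode == "streamlines") {
    paths <- trace_streamlines(field, mesh)
    for (pth in paths)
      graphics::lines(pth[, 1] * 1e3, pth[, 2] * 1e3, col = "white",
                      lwd = 0.8)
  }
  if (mode == "wss_map") {
    if (is.null(fluid)) fluid <- field$fluid
    w <- wall_shear_stress(field, mesh, fluid)
    zmax <- max(w$profile$tau_pa, 1e-300)
    col <- pal[pmin(64L, 1L + floor(63.999 * w$profile$tau_pa / zmax))]
    graphics::points(w$profile$x * 1e3, w$profile$y * 1e3, col = col,
                     pch = 15, cex = 0.7)
    draw_colorbar(pal, 0, zmax, rngx, rngy)
  }
  lm <- mesh$outline$landmarks
  if (length(lm)) {
    for (nm in names(lm)) {
      graphics::points(lm[[nm]][1] * 1e3, lm[[nm]][2] * 1e3, pch = 4,
                       col = "red", cex = 1.2)
      graphics::text(lm[[nm]][1] * 1e3, lm[[nm]][2] * 1e3, nm, pos = 3,
                     col = "red", cex = 0.9)
    }
  }
  invisible(file)
}

draw_colorbar <- function(pal, zmin, zmax, rngx, rngy) {
  usr <- graphics::par("usr")
  xl <- usr[2] + 0.01 * (usr[2] - usr[1])
  xr <- usr[2] + 0.03 * (usr[2] - usr[1])
  yy <- seq(usr[3], usr[4], length.out = length(pal) + 1)
  graphics::rect(xl, yy[-length(yy)], xr, yy[-1], col = pal, border = NA,
                 xpd = NA)
  graphics::text(xr, c(usr[3], usr[4]),
                 signif(c(zmin, zmax), 3), pos = 4, xpd = NA, cex = 0.8)
}

# Deterministic streamline tracing: RK2 with nearest-cell velocity lookup
# on a coarse helper grid.
trace_streamlines <- function(field, mesh, n_seeds = 24, max_steps = 600) {
  cc <- mesh$cell_centroid
  cell_size <- sqrt(stats::median(mesh$cell_area))
  # coarse occupancy grid for nearest-cell lookup
  gx0 <- min(cc[, 1]); gy0 <- min(cc[, 2])
  gh <- 2 * cell_size
  gi <- floor((cc[, 1] - gx0) / gh); gj <- floor((cc[, 2] - gy0) / gh)
  key <- paste(gi, gj)
  buckets <- split(seq_len(nrow(cc)), key)
  lookup <- function(x, y) {
    ki <- floor((x - gx0) / gh); kj <- floor((y - gy0) / gh)
    cand <- integer(0)
    for (dx in -1:1) for (dy in -1:1)
      cand <- c(cand, buckets[[paste(ki + dx, kj + dy)]])
    if (!length(cand)) return(NA_integer_)
    cand[which.min((cc[cand, 1] - x)^2 + (cc[cand, 2] - y)^2)]
  }
  U <- field$bc$inlet_mean_velocity
  dt <- 0.5 * cell_size / U
  xr <- range(mesh$nodes[, 1]); yr <- range(mesh$nodes[, 2])
  seeds <- cbind(
    rep(xr[1] + (xr[2] - xr[1]) * c(0.05, 0.35, 0.65), each = n_seeds / 3),
    rep(seq(yr[1], yr[2], length.out = n_seeds / 3), 3))
  paths <- list()
  for (s in seq_len(nrow(seeds))) {
    pos <- seeds[s, ]
    pth <- matrix(NA_real_, max_steps, 2)
    for (k in seq_len(max_steps)) {
      i <- lookup(pos[1], pos[2])
      if (is.na(i)) break
      d2 <- (cc[i, 1] - pos[1])^2 + (cc[i, 2] - pos[2])^2
      if (d2 > (3 * cell_size)^2) break
      v1 <- c(field$u[i], field$v[i])
      mid <- pos + 0.5 * dt * v1
      j <- lookup(mid[1], mid[2])
      if (is.na(j)) break
      v2 <- c(field$u[j], field$v[j])
      pos <- pos + dt * v2
      pth[k, ] <- pos
      if (sum(v2^2) < (1e-4 * U)^2) break
    }
    pth <- pth[stats::complete.cases(pth), , drop = FALSE]
    if (nrow(pth) > 2) paths[[length(paths) + 1L]] <- pth
  }
  paths
}

#' Summary metrics of a solved anastomosis case
#'
#' Bundles the post-processing of one converged junction solution into the
#' metric set reported per angle: maximum cross-sectional graft stagnation,
#' total recirculation area, peak wall shear stress and its landmark.
#'
#' @param field converged `flow_field`.
#' @param mesh junction `ets_mesh`.
#' @param fluid [fluid_properties()].
#' @param threshold_fraction stagnation threshold (see
#'   [stagnation_profile()]).
#' @param n_sections cross-section count.
#' @return named list with entries `max_stagnation_pct`,
#'   `recirc_area_mm2`, `peak_wss_pa`, `peak_wss_landmark`, `iterations`,
#'   plus the underlying profile objects.
#' @export
case_metrics <- function(field, mesh, fluid,
                         threshold_fraction = 0.05, n_sections = 50) {
  stag <- stagnation_profile(field, mesh,
                             threshold_fraction = threshold_fraction,
                             n_sections = n_sections)
  rz <- recirculation_zones(field, mesh)
  wss <- wall_shear_stress(field, mesh, fluid)
  list(max_stagnation_pct = stag$max_stagnation,
       recirc_area_mm2 = attr(rz, "total_area_m2") * 1e6,
       peak_wss_pa = wss$peak_tau_pa,
       peak_wss_landmark = wss$peak_landmark,
       iterations = field$iterations,
       stagnation = stag, recirculation = rz, wss = wss)
}
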