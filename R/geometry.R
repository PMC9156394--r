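#' Vessel specification
#'
#' Describes one straight vessel segment. Wall thickness is carried as
#' metadata only: the flow model is rigid-walled and uses the lumen
#' (internal) diameter alone.
#'
#' @param internal_diameter lumen diameter in metres (> 0).
#' @param wall_thickness wall thickness in metres (metadata only).
#' @param length physical vessel length in metres; must exceed ten diameters
#'   so that a truncated computational domain always fits inside it.
#' @return an object of class `vessel_spec`.
#' @examples
#' ima <- vessel_spec(2.3e-3, 200e-6, 184e-3)  # internal mammary artery
#' @export
vessel_spec <- function(internal_diameter, wall_thickness = 0, length = Inf) {
  stopifnot(is.numeric(internal_diameter), length(internal_diameter) == 1L)
  if (internal_diameter <= 0) stop("internal_diameter must be > 0")
  if (wall_thickness < 0) stop("wall_thickness must be >= 0")
  if (length <= 10 * internal_diameter)
    stop("vessel length must exceed 10 internal diameters")
  structure(list(internal_diameter = internal_diameter,
                 wall_thickness = wall_thickness,
                 length = length),
            class = "vessel_spec")
}

#' Parametric end-to-side anastomosis geometry
#'
#' The graft vessel joins the side of the donor vessel at `angle_deg`,
#' measured between the graft centreline and the distal (downstream) donor
#' direction, so a smaller angle means a more flow-aligned graft. The graft
#' centreline crosses the donor centreline `junction_offset` metres from the
#' donor inlet.
#'
#' @param donor,graft [vessel_spec()] objects.
#' @param angle_deg anastomotic angle in degrees, in (0, 90].
#' @param junction_offset distance (m) from donor inlet to the centreline
#'   crossing point.
#' @return an object of class `anastomosis_geometry`.
#' @examples
#' geom <- anastomosis_geometry(
#'   donor = vessel_spec(2.3e-3, 200e-6, 184e-3),
#'   graft = vessel_spec(2.3e-3, 200e-6, 103e-3),
#'   angle_deg = 45, junction_offset = 100e-3)
#' @export
anastomosis_geometry <- function(donor, graft, angle_deg, junction_offset) {
  stopifnot(inherits(donor, "vessel_spec"), inherits(graft, "vessel_spec"))
  if (!is.numeric(angle_deg) || length(angle_deg) != 1L || !is.finite(angle_deg))
    stop("angle_deg must be a finite number")
  if (angle_deg <= 0 || angle_deg > 90)
    stop("degenerate geometry: angle_deg must lie in (0, 90]")
  if (junction_offset <= 0 || junction_offset >= donor$length)
    stop("junction_offset must lie strictly inside the donor length")
  g <- structure(list(donor = donor, graft = graft, angle_deg = angle_deg,
                      junction_offset = junction_offset),
                 class = "anastomosis_geometry")
  jl <- junction_landmarks_full(g)
  # The opening cut into the donor wall (width d_g / sin(theta)) must fit
  # within the physical donor vessel.
  if (jl$heel_x <= 0 || jl$toe_x >= donor$length)
    stop("junction opening does not fit within the donor vessel length")
  g
}

#' Domain truncation for the computational model
#'
#' Physical vessel lengths (184 mm donor, 103 mm graft) are far longer than
#' needed to obtain fully developed laminar flow at the operating Reynolds
#' number (~70; laminar entrance length ~4.2 diameters). The computational
#' domain keeps `upstream_diameters` donor diameters upstream of the heel,
#' `downstream_diameters` downstream of the toe and `graft_diameters` graft
#' diameters along the graft; each must be at least 5.
#'
#' @param upstream_diameters,downstream_diameters,graft_diameters
#'   dimensionless truncation lengths, each >= 5 (defaults 15).
#' @return an object of class `domain_truncation`.
#' @export
domain_truncation <- function(upstream_diameters = 15,
                              downstream_diameters = 15,
                              graft_diameters = 15) {
  v <- c(upstream_diameters, downstream_diameters, graft_diameters)
  if (any(!is.finite(v)) || any(v < 5))
    stop("all truncation lengths must be >= 5 diameters (laminar entrance length)")
  structure(list(upstream_diameters = upstream_diameters,
                 downstream_diameters = downstream_diameters,
                 graft_diameters = graft_diameters),
            class = "domain_truncation")
}

# Junction landmark positions in full (untruncated) donor coordinates:
# donor axis along +x, donor inlet at x = 0, donor lumen occupying
# y in [0, d], graft branching into y > d.
junction_landmarks_full <- function(geom) {
  d  <- geom$donor$internal_diameter
  dg <- geom$graft$internal_diameter
  th <- deg_to_rad(geom$angle_deg)
  xj <- geom$junction_offset
  mouth_x <- xj + (d / 2) / tan(th)       # centreline crosses the wall here
  w <- dg / sin(th)                       # opening width along the donor wall
  list(mouth_x = mouth_x, heel_x = mouth_x - w / 2, toe_x = mouth_x + w / 2,
       opening_width = w, theta = th, d = d, dg = dg)
}

#' Build the planar mid-plane outline of the anastomosis
#'
#' Constructs the closed boundary polygon of the truncated 2-D mid-plane
#' fluid domain: a donor channel of width equal to the donor diameter with a
#' graft channel of width equal to the graft diameter leaving the upper wall
#' at the anastomotic angle. Boundary edges carry patch labels (`inlet`,
#' `outlet_donor`, `outlet_graft`, `wall`) and the four junction landmarks
#' (heel, toe, hood, floor) are recorded.
#'
#' Corners at heel and toe are sharp (no suture-line fillet is modelled).
#'
#' @param geom an [anastomosis_geometry()].
#' @param trunc a [domain_truncation()].
#' @return an object of class `ets_outline` with elements `vertices`
#'   (n x 2 matrix, closed implicitly), `edge_patch` (patch label of the edge
#'   from vertex i to i+1), `landmarks` (list of named 2-vectors) and
#'   `params` (all derived dimensions, used by [generate_mesh()]).
#' @export
build_outline <- function(geom, trunc = domain_truncation()) {
  stopifnot(inherits(geom, "anastomosis_geometry"),
            inherits(trunc, "domain_truncation"))
  jl <- junction_landmarks_full(geom)
  d <- jl$d; dg <- jl$dg; th <- jl$theta; w <- jl$opening_width

  L_up   <- trunc$upstream_diameters * d
  L_down <- trunc$downstream_diameters * d
  L_g    <- trunc$graft_diameters * dg

  # Truncated lengths must not exceed what the physical vessels provide.
  if (L_up > jl$heel_x)
    stop("domain too short: upstream truncation overruns the donor inlet side")
  if (L_down > geom$donor$length - jl$toe_x)
    stop("domain too short: downstream truncation overruns the donor outlet side")
  if (L_g > geom$graft$length)
    stop("domain too short: graft truncation exceeds the graft length")
  if (L_g <= (dg / 2) / tan(th) + dg)
    stop("domain too short: graft truncation shorter than the junction mouth region")

  # Truncated coordinates: inlet at x = 0, heel at x = L_up.
  heel <- c(L_up, d)
  toe  <- c(L_up + w, d)
  x_end <- L_up + w + L_down
  e  <- c(cos(th), sin(th))               # graft axis direction
  nL <- c(-sin(th), cos(th))              # heel-side transverse direction
  mouth <- c(L_up + w / 2, d)             # centreline-wall crossing
  p_out <- mouth + L_g * e                # graft outlet centre
  heel_top <- p_out + (dg / 2) * nL
  toe_top  <- p_out - (dg / 2) * nL

  verts <- rbind(c(0, 0), c(x_end, 0), c(x_end, d), toe, toe_top,
                 heel_top, heel, c(0, d))
  patches <- c("wall", "outlet_donor", "wall", "wall",
               "outlet_graft", "wall", "wall", "inlet")
  landmarks <- list(heel = heel, toe = toe,
                    hood = heel + dg * e,          # graft roof over the mouth
                    floor = c(mouth[1], 0))        # donor wall opposite

  out <- structure(list(
    vertices = verts, edge_patch = patches, landmarks = landmarks,
    kind = "junction",
    params = list(d = d, dg = dg, theta = th, angle_deg = geom$angle_deg,
                  opening_width = w, L_up = L_up, L_down = L_down, L_g = L_g,
                  x_end = x_end, heel = heel, toe = toe, mouth = mouth,
                  p_out = p_out, heel_top = heel_top, toe_top = toe_top,
                  e = e, nL = nL),
    geom = geom, trunc = trunc), class = "ets_outline")
  if (!polygon_is_simple(verts))
    stop("geometry error: outline polygon is self-intersecting")
  out
}

#' Straight-channel outline (verification geometry)
#'
#' A plain rectangular channel used by the verification fixtures (Poiseuille
#' benchmark, manufactured solutions, stagnation fixtures). Patches: `inlet`
#' at x = 0, `outlet_donor` at x = length, `wall` on both sides.
#'
#' @param width channel width (m).
#' @param length channel length (m).
#' @return an `ets_outline` of kind `"channel"`.
#' @export
channel_outline <- function(width, length) {
  stopifnot(width > 0, length > 0)
  verts <- rbind(c(0, 0), c(length, 0), c(length, width), c(0, width))
  structure(list(vertices = verts,
                 edge_patch = c("wall", "outlet_donor", "wall", "inlet"),
                 landmarks = list(), kind = "channel",
                 params = list(d = width, x_end = length)),
            class = "ets_outline")
}

# Simple-polygon test by brute-force pairwise segment intersection.
polygon_is_simple <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (segments_intersect(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- cross2(p4 - p3, p1 - p3); d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1); d4 <- cross2(p2 - p1, p4 - p1)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
   ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

#' @export
print.ets_outline <- function(x, ...) {
  cat("ETS planar outline (", x$kind, ")\n", sep = "")
  if (x$kind == "junction") {
    p <- x$params
    cat(sprintf("  angle: %g deg, donor width %.3g mm, graft width %.3g mm\n",
                p$angle_deg, m_to_mm(p$d), m_to_mm(p$dg)))
    cat(sprintf("  opening width: %.3g mm, domain %.3g x %.3g mm\n",
                m_to_mm(p$opening_width), m_to_mm(p$x_end), m_to_mm(p$d)))
  }
  invisible(x)
}
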