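# Block-structured finite-volume meshing of the parametric outline.
#
# The donor channel is a tensor-product grid graded away from the junction;
# the graft channel is a transfinite (bilinear) block between the oblique
# junction mouth and the perpendicular graft outlet. The two blocks share
# their interface nodes, so the mesh is conforming by construction.

# Geometric spacing from a fine end: first spacing d0, growth per cell,
# capped at cap_mult * d0; spacings rescaled to cover L exactly.
# Returns positions 0..L with the fine end at 0.
graded_pts <- function(L, d0, growth = 1.15, cap_mult = 5) {
  if (L <= 0) return(numeric(0))
  if (L <= d0 * 1.5) return(c(0, L))
  sp <- d0
  repeat {
    nxt <- min(sp[length(sp)] * growth, cap_mult * d0)
    sp <- c(sp, nxt)
    if (sum(sp) >= L) break
  }
  sp <- sp * (L / sum(sp))
  cumsum(c(0, sp))
}

# Cross-channel node positions over [0, width] with two wall-adjacent cell
# layers at half the interior spacing on each side (near-wall refinement).
cross_pts <- function(width, d0) {
  if (width <= 3 * d0) {
    n <- max(4L, round(width / d0))
    return(seq(0, width, length.out = n + 1L))
  }
  ni <- max(1L, round((width - 2 * d0) / d0))
  di <- (width - 2 * d0) / ni
  sp <- c(d0 / 2, d0 / 2, rep(di, ni), d0 / 2, d0 / 2)
  cumsum(c(0, sp))
}

uniform_pts <- function(from, to, d0) {
  n <- max(1L, round((to - from) / d0))
  seq(from, to, length.out = n + 1L)
}

#' Generate a finite-volume mesh of a planar outline
#'
#' Discretizes the parametric outline from [build_outline()] (or
#' [channel_outline()]) into a conforming block-structured mesh with labelled
#' boundary patches, near-wall refinement (two wall-adjacent cell layers at
#' half the interior spacing) and axial grading away from the junction.
#'
#' The mesher consumes the parametric description stored in the outline;
#' free-form polygons are not supported (the outline is still checked for
#' self-intersection and rejected with a geometry error if degenerate).
#'
#' @param outline an `ets_outline`.
#' @param target_edge_length target cell edge length (m) in the junction
#'   region and across the channels; must be below a quarter of the smallest
#'   channel width.
#' @param element `"quad"` (default) or `"tri"` (each quad split in two).
#' @param axial_growth geometric growth rate of axial spacing away from the
#'   junction (default 1.15).
#' @param axial_cap maximum axial spacing as a multiple of
#'   `target_edge_length` (default 5).
#' @return an object of class `ets_mesh`.
#' @export
generate_mesh <- function(outline, target_edge_length,
                          element = c("quad", "tri"),
                          axial_growth = 1.15, axial_cap = 5) {
  stopifnot(inherits(outline, "ets_outline"))
  element <- match.arg(element)
  h <- target_edge_length
  p <- outline$params
  wmin <- if (outline$kind == "junction") min(p$d, p$dg) else p$d
  if (!is.finite(h) || h <= 0 || h >= wmin / 4)
    stop("target_edge_length must be positive and below a quarter of the ",
         "smallest channel width")
  if (!polygon_is_simple(outline$vertices))
    stop("geometry error: outline polygon is self-intersecting")

  if (outline$kind == "channel") {
    xs <- uniform_pts(0, p$x_end, h)
    ys <- cross_pts(p$d, h)
    m <- structured_block_mesh(xs, ys, outline, element, h,
                               region = "channel")
    return(m)
  }

  # --- donor axial node positions -----------------------------------------
  heel_x <- p$heel[1]; toe_x <- p$toe[1]
  tt <- cross_pts(p$dg, h) / p$dg                # graft cross distribution
  x_open <- heel_x + tt * p$opening_width
  pad_l <- min(p$d, heel_x)
  pad_r <- min(p$d, p$x_end - toe_x)
  # graded_pts puts the fine end at 0; the upstream run needs it at the right.
  Lg_l <- heel_x - pad_l
  left_graded <- Lg_l - rev(graded_pts(Lg_l, h, axial_growth, axial_cap))
  left_pad  <- uniform_pts(heel_x - pad_l, heel_x, h)
  right_pad <- uniform_pts(toe_x, toe_x + pad_r, h)
  Lg_r <- p$x_end - toe_x - pad_r
  right_graded <- (toe_x + pad_r) + graded_pts(Lg_r, h, axial_growth, axial_cap)
  xs <- c(left_graded, left_pad[-1L], x_open[-1L], right_pad[-1L],
          right_graded[-1L])
  i_op <- (length(left_graded) + length(left_pad) - 1L):
          (length(left_graded) + length(left_pad) - 1L + length(x_open) - 1L)
  stopifnot(max(abs(xs[i_op] - x_open)) < 1e-12)
  ys <- cross_pts(p$d, h)

  # --- node table ----------------------------------------------------------
  nx1 <- length(xs); ny1 <- length(ys)
  dn <- function(i, j) (j - 1L) * nx1 + i
  nodes <- cbind(rep(xs, ny1), rep(ys, each = nx1))
  region <- character(0)

  # donor quads
  ii <- rep(seq_len(nx1 - 1L), ny1 - 1L)
  jj <- rep(seq_len(ny1 - 1L), each = nx1 - 1L)
  cells_d <- cbind(dn(ii, jj), dn(ii + 1L, jj), dn(ii + 1L, jj + 1L),
                   dn(ii, jj + 1L))

  # --- graft block ---------------------------------------------------------
  s_pad <- min(p$dg, p$L_g)
  s_fine <- uniform_pts(0, s_pad, h)
  s_rest <- s_pad + graded_pts(p$L_g - s_pad, h, axial_growth, axial_cap)
  ss <- unique(c(s_fine, s_rest)) / p$L_g
  nt1 <- length(tt); ns1 <- length(ss)
  B <- cbind(p$heel[1] + tt * (p$toe[1] - p$heel[1]),
             p$heel[2] + tt * (p$toe[2] - p$heel[2]))
  TT <- cbind(p$heel_top[1] + tt * (p$toe_top[1] - p$heel_top[1]),
              p$heel_top[2] + tt * (p$toe_top[2] - p$heel_top[2]))
  # graft node ids: row l = 1 reuses donor top-row nodes across the opening
  gid <- matrix(0L, nt1, ns1)
  gid[, 1L] <- dn(i_op, ny1)
  extra <- matrix(0L, nt1, ns1 - 1L)
  new_ids <- nrow(nodes) + seq_len(nt1 * (ns1 - 1L))
  gid[, 2:ns1] <- matrix(new_ids, nt1, ns1 - 1L)
  gx <- outer(B[, 1], 1 - ss[-1L]) + outer(TT[, 1], ss[-1L])
  gy <- outer(B[, 2], 1 - ss[-1L]) + outer(TT[, 2], ss[-1L])
  nodes <- rbind(nodes, cbind(as.vector(gx), as.vector(gy)))

  kk <- rep(seq_len(nt1 - 1L), ns1 - 1L)
  ll <- rep(seq_len(ns1 - 1L), each = nt1 - 1L)
  cells_g <- cbind(gid[cbind(kk, ll)], gid[cbind(kk + 1L, ll)],
                   gid[cbind(kk + 1L, ll + 1L)], gid[cbind(kk, ll + 1L)])

  cells <- rbind(cells_d, cells_g)
  region <- c(rep("donor", nrow(cells_d)), rep("graft", nrow(cells_g)))
  structured_block_mesh(NULL, NULL, outline, element, h,
                        nodes = nodes, cells = cells, region = region)
}

# Assemble an ets_mesh either from tensor grids (xs, ys) or from explicit
# nodes/cells. Splits quads into triangles if requested, extracts the face
# connectivity and assigns boundary patches geometrically.
structured_block_mesh <- function(xs, ys, outline, element, h,
                                  nodes = NULL, cells = NULL,
                                  region = NULL) {
  if (is.null(nodes)) {
    nx1 <- length(xs); ny1 <- length(ys)
    nodes <- cbind(rep(xs, ny1), rep(ys, each = nx1))
    ii <- rep(seq_len(nx1 - 1L), ny1 - 1L)
    jj <- rep(seq_len(ny1 - 1L), each = nx1 - 1L)
    dn <- function(i, j) (j - 1L) * nx1 + i
    cells <- cbind(dn(ii, jj), dn(ii + 1L, jj), dn(ii + 1L, jj + 1L),
                   dn(ii, jj + 1L))
    if (is.null(region) || length(region) == 1L)
      region <- rep(region %||% "channel", nrow(cells))
  }
  if (element == "tri") {
    cells_t <- rbind(cells[, c(1, 2, 3)], cells[, c(1, 3, 4)])
    region <- c(region, region)
    cells <- cells_t
  }
  build_ets_mesh(nodes, cells, outline, region, h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_ets_mesh <- function(nodes, cells, outline, region, h) {
  nc <- nrow(cells); nv <- ncol(cells)

  # cell areas and centroids (shoelace; cells are CCW by construction)
  xs <- matrix(nodes[cells, 1], nc, nv)
  ysm <- matrix(nodes[cells, 2], nc, nv)
  xn <- xs[, c(2:nv, 1)]; yn <- ysm[, c(2:nv, 1)]
  crossp <- xs * yn - xn * ysm
  area <- rowSums(crossp) / 2
  if (any(area <= 0)) stop("geometry error: non-positive cell area")
  cx <- rowSums((xs + xn) * crossp) / (6 * area)
  cy <- rowSums((ysm + yn) * crossp) / (6 * area)

  # face extraction: each cell edge once; shared edges paired owner/neighbour
  a <- as.vector(cells)
  b <- as.vector(cells[, c(2:nv, 1)])
  own <- rep(seq_len(nc), nv)
  key <- pmin(a, b) * (nrow(nodes) + 1) + pmax(a, b)
  ord <- order(key, method = "radix")
  ka <- key[ord]
  first <- !duplicated(ka)
  fidx <- cumsum(first)                # face index for each half-edge (sorted)
  nf <- fidx[length(fidx)]
  f_n1 <- integer(nf); f_n2 <- integer(nf)
  f_own <- integer(nf); f_nei <- rep(NA_integer_, nf)
  is_first <- first
  f_n1[fidx[is_first]] <- a[ord][is_first]
  f_n2[fidx[is_first]] <- b[ord][is_first]
  f_own[fidx[is_first]] <- own[ord][is_first]
  sec <- !is_first
  if (max(tabulate(fidx)) > 2L)
    stop("geometry error: non-conforming mesh (edge shared by >2 cells)")
  f_nei[fidx[sec]] <- own[ord][sec]

  tvec <- nodes[f_n2, , drop = FALSE] - nodes[f_n1, , drop = FALSE]
  flen <- sqrt(rowSums(tvec^2))
  # owner traverses a -> b CCW, interior on the left, outward normal on the right
  fnorm <- cbind(tvec[, 2], -tvec[, 1]) / flen
  fcent <- (nodes[f_n1, , drop = FALSE] + nodes[f_n2, , drop = FALSE]) / 2

  boundary <- is.na(f_nei)
  patch <- rep(NA_character_, nf)
  p <- outline$params
  tol <- 1e-7 * p$x_end
  bc <- fcent[boundary, , drop = FALSE]
  lab <- rep("wall", nrow(bc))
  lab[abs(bc[, 1]) < tol] <- "inlet"
  lab[abs(bc[, 1] - p$x_end) < tol] <- "outlet_donor"
  if (outline$kind == "junction") {
    don_graft <- abs((bc[, 1] - p$p_out[1]) * p$e[1] +
                     (bc[, 2] - p$p_out[2]) * p$e[2]) < tol
    lab[don_graft] <- "outlet_graft"
  }
  patch[boundary] <- lab

  structure(list(
    nodes = nodes, cells = cells,
    cell_area = area, cell_centroid = cbind(cx, cy),
    face_nodes = cbind(f_n1, f_n2), face_owner = f_own, face_neigh = f_nei,
    face_centroid = fcent, face_normal = fnorm, face_length = flen,
    face_patch = patch, cell_region = region, outline = outline,
    target_edge_length = h), class = "ets_mesh")
}

#' @export
print.ets_mesh <- function(x, ...) {
  nb <- sum(!is.na(x$face_patch))
  cat(sprintf("ETS finite-volume mesh: %d cells, %d faces (%d boundary)\n",
              nrow(x$cells), length(x$face_owner), nb))
  cat("  patches:", paste(sort(unique(stats::na.omit(x$face_patch))),
                          collapse = ", "), "\n")
  invisible(x)
}

#' Mesh quality report
#'
#' Computes per-cell interior angles, edge aspect ratios and face
#' non-orthogonality (the skew angle between each internal face normal and
#' the owner-neighbour centroid line). The solver refuses meshes whose
#' minimum cell angle falls below its configured gate.
#'
#' @param mesh an `ets_mesh`.
#' @return an object of class `ets_mesh_quality` with fields
#'   `min_angle_deg`, `mean_angle_deg`, `min_aspect`, `mean_aspect`,
#'   `max_aspect`, `max_skew_deg`, `n_cells`.
#' @export
mesh_quality <- function(mesh) {
  stopifnot(inherits(mesh, "ets_mesh"))
  cells <- mesh$cells; nv <- ncol(cells); nodes <- mesh$nodes
  min_ang <- Inf; sum_min_ang <- 0
  px <- matrix(nodes[cells, 1], nrow(cells), nv)
  py <- matrix(nodes[cells, 2], nrow(cells), nv)
  ang_min <- rep(Inf, nrow(cells))
  for (k in seq_len(nv)) {
    km <- if (k == 1L) nv else k - 1L
    kp <- if (k == nv) 1L else k + 1L
    ax <- px[, km] - px[, k]; ay <- py[, km] - py[, k]
    bx <- px[, kp] - px[, k]; by <- py[, kp] - py[, k]
    cosang <- (ax * bx + ay * by) /
      sqrt((ax^2 + ay^2) * (bx^2 + by^2))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    ang_min <- pmin(ang_min, ang)
  }
  elen <- sapply(seq_len(nv), function(k) {
    kp <- if (k == nv) 1L else k + 1L
    sqrt((px[, kp] - px[, k])^2 + (py[, kp] - py[, k])^2)
  })
  aspect <- apply(elen, 1L, max) / apply(elen, 1L, min)
  int <- !is.na(mesh$face_neigh)
  d <- mesh$cell_centroid[mesh$face_neigh[int], , drop = FALSE] -
       mesh$cell_centroid[mesh$face_owner[int], , drop = FALSE]
  dl <- sqrt(rowSums(d^2))
  cosd <- (d[, 1] * mesh$face_normal[int, 1] +
           d[, 2] * mesh$face_normal[int, 2]) / dl
  skew <- acos(pmin(1, pmax(-1, cosd))) * 180 / pi
  structure(list(min_angle_deg = min(ang_min),
                 mean_angle_deg = mean(ang_min),
                 min_aspect = min(aspect), mean_aspect = mean(aspect),
                 max_aspect = max(aspect),
                 max_skew_deg = if (any(int)) max(skew) else 0,
                 n_cells = nrow(cells)),
            class = "ets_mesh_quality")
}

#' @export
print.ets_mesh_quality <- function(x, ...) {
  cat(sprintf(paste0("mesh quality: %d cells | min angle %.1f deg, ",
                     "max aspect %.2f, max skew %.1f deg\n"),
              x$n_cells, x$min_angle_deg, x$max_aspect, x$max_skew_deg))
  invisible(x)
}

# Sum of outward face normal vectors (times face length) over each cell;
# must vanish for a closed cell (discrete divergence consistency).
cell_normal_closure <- function(mesh) {
  nc <- nrow(mesh$cells)
  nx <- mesh$face_normal[, 1] * mesh$face_length
  ny <- mesh$face_normal[, 2] * mesh$face_length
  agg <- function(v, idx) {
    out <- numeric(nc)
    s <- tapply(v, idx, sum)
    out[as.integer(names(s))] <- s
    out
  }
  int <- !is.na(mesh$face_neigh)
  sx <- agg(nx, mesh$face_owner) - agg(nx[int], mesh$face_neigh[int])
  sy <- agg(ny, mesh$face_owner) - agg(ny[int], mesh$face_neigh[int])
  cbind(sx, sy)
}
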