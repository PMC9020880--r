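# Bubble shape diagnostics: volume and equivalent radius, centroid
# displacement along the offset direction, asymmetric ratio (axial vs
# lateral extent) and microstreaming velocity snapshots.

#' Bubble volume trace
#'
#' The solver's volume state: initialized to the analytic `4/3 pi R0^3` and
#' advanced by the exact discrete interface flux, so it is free of the
#' faceting deficit of the triangulated surface.  The raw polyhedral
#' (mesh) volume is returned alongside for diagnostics.
#'
#' @param run an `fsi_result`
#' @return data frame with `times`, `volume` (m^3, full bubble),
#'   `equiv_radius` (m) and `mesh_volume`
#' @export
bubble_volume <- function(run) {
  stopifnot(inherits(run, "fsi_result"))
  data.frame(times = run$times, volume = run$volume,
             equiv_radius = run$equiv_radius, mesh_volume = run$mesh_volume)
}

#' Centroid displacement along the offset direction
#'
#' Signed y-displacement of the gas-region centroid relative to the initial
#' bubble center; positive toward the near vessel wall (+y).
#'
#' @param run an `fsi_result`
#' @return data frame with `times` and `d_y` [m]
#' @export
centroid_displacement <- function(run) {
  stopifnot(inherits(run, "fsi_result"))
  C <- run$system$mesh$spec$bubble_offset
  data.frame(times = run$times, d_y = run$centroid_y - C)
}

# area of the x = 0 cross-section: the interface boundary ring lies on the
# symmetry plane; shoelace over the ordered ring polygon in (y, z)
.section_area_sym <- function(pts_ring) {
  y <- pts_ring[, 2L]; z <- pts_ring[, 3L]
  abs(sum(y * c(z[-1L], z[1L]) - c(y[-1L], y[1L]) * z)) / 2
}

# area of the z = z0 cross-section of the mirrored closed surface: slice
# the half-surface triangles, integrate x dy along the cut segments
# (the symmetry closure at x = 0 contributes nothing), and double
.section_area_z <- function(Xi, tris, z0) {
  z1 <- Xi[tris[, 1L], 3L]; z2 <- Xi[tris[, 2L], 3L]; z3 <- Xi[tris[, 3L], 3L]
  lo <- pmin(z1, z2, z3); hi <- pmax(z1, z2, z3)
  cross <- which(lo <= z0 & hi > z0)
  if (!length(cross)) return(0)
  tot <- 0
  for (tt in cross) {
    vv <- tris[tt, ]
    zz <- Xi[vv, 3L]
    seg <- matrix(0, 0, 2L)  # columns x, y of the two cut points
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      za <- zz[e[1]]; zb <- zz[e[2]]
      if ((za <= z0 && zb > z0) || (zb <= z0 && za > z0)) {
        w <- (z0 - za) / (zb - za)
        pt <- (1 - w) * Xi[vv[e[1]], 1:2] + w * Xi[vv[e[2]], 1:2]
        seg <- rbind(seg, pt)
      }
    }
    if (nrow(seg) == 2L) {
      # signed contribution of segment to the area integral x dy
      tot <- tot + mean(seg[, 1L]) * (seg[2L, 2L] - seg[1L, 2L])
    }
  }
  2 * abs(tot)
}

#' Asymmetric ratio of the deformed bubble
#'
#' Ratio of the bubble cross-section area in the plane containing the
#' centroid and the vessel axis (the symmetry plane x = 0) to the largest
#' cross-section area over planes normal to the vessel axis.  Greater than
#' one means elongation along the vessel axis.  By default the raw ratio is
#' normalized by its value for the undeformed (spherical) surface mesh,
#' which removes the small polygonization bias of the two differently
#' discretized sections.
#'
#' @param run an `fsi_result`
#' @param sample sample index (default: all samples)
#' @param n_planes number of axial planes scanned for the perpendicular
#'   maximum
#' @param normalize divide by the t = 0 (spherical) ratio
#' @return data frame with `times` and `A`
#' @export
asymmetric_ratio <- function(run, sample = NULL, n_planes = 33L,
                             normalize = TRUE) {
  stopifnot(inherits(run, "fsi_result"))
  maps <- run$system$mesh$maps
  bub_loc <- run$interface_nodes
  tris_loc <- matrix(match(as.vector(run$system$bub_tris), bub_loc),
                     ncol = 3L)
  # ordered symmetry ring: walk phi = 0 column down, phi = pi column up
  ring <- .sym_ring_order(run$system, bub_loc)
  one <- function(k) {
    Xi <- run$interface[[k]]
    a_par <- .section_area_sym(Xi[ring, , drop = FALSE])
    zr <- range(Xi[, 3L])
    zs <- seq(zr[1L] + 1e-4 * diff(zr), zr[2L] - 1e-4 * diff(zr),
              length.out = n_planes)
    a_perp <- max(vapply(zs, function(z0)
      .section_area_z(Xi, tris_loc, z0), numeric(1)))
    a_par / a_perp
  }
  ks <- if (is.null(sample)) seq_along(run$times) else sample
  A <- vapply(ks, one, numeric(1))
  if (normalize) A <- A / one(1L)
  data.frame(times = run$times[ks], A = A)
}

# order the interface nodes lying on the symmetry plane into a closed
# polygon (by angle in the (y, z) plane around the ring centroid)
.sym_ring_order <- function(sys, bub_loc) {
  Xb0 <- sys$mesh$vertices[sys$bl_nodes, , drop = FALSE]
  on_ring <- which(sys$sym_b[bub_loc])
  pts <- Xb0[bub_loc[on_ring], , drop = FALSE]
  cy <- mean(pts[, 2L]); cz <- mean(pts[, 3L])
  ang <- atan2(pts[, 3L] - cz, pts[, 2L] - cy)
  on_ring[order(ang)]
}

#' Microstreaming velocity snapshot
#'
#' Blood velocity vectors on the deformed mesh at the stored snapshot
#' nearest to `t`.
#'
#' @param run an `fsi_result`
#' @param t requested time [s]; must lie within the simulated range
#' @return list with `t` (actual snapshot time), node coordinates `X` and
#'   velocities `v` (m/s), and pressure `p`
#' @export
microstreaming_snapshot <- function(run, t) {
  stopifnot(inherits(run, "fsi_result"))
  if (t < min(run$times) - 1e-12 || t > max(run$times) + 1e-12)
    stop("microstreaming_snapshot: t outside the simulated range")
  ts <- vapply(run$snapshots, `[[`, numeric(1), "t")
  run$snapshots[[which.min(abs(ts - t))]]
}

#' Mirror-symmetry error of the blood velocity field
#'
#' For a centered bubble the flow must be symmetric under reflection of
#' the offset axis (y to -y).  The structured mesh maps onto itself under
#' that reflection, so every blood node has an exact mirror partner; this
#' returns the rms difference of the speed over mirrored pairs, scaled by
#' the rms speed, at the stored snapshot with the strongest flow (or at
#' `t`).
#'
#' @param run an `fsi_result`
#' @param t snapshot time [s], or `NULL` for the strongest snapshot
#' @return dimensionless rms mirror error
#' @export
microstreaming_mirror_error <- function(run, t = NULL) {
  if (is.null(t)) {
    speeds <- vapply(run$snapshots, function(s)
      mean(rowSums(s$v^2)), numeric(1))
    t <- run$snapshots[[which.max(speeds)]]$t
  }
  sn <- microstreaming_snapshot(run, t)
  sys <- run$system
  X0 <- sys$mesh$vertices[sys$bl_nodes, , drop = FALSE]
  Xm <- X0; Xm[, 2L] <- -Xm[, 2L]
  # match mirror partners on the reference configuration
  key <- function(M) paste(round(M[, 1L] * 1e12), round(M[, 2L] * 1e12),
                           round(M[, 3L] * 1e12))
  partner <- match(key(Xm), key(X0))
  ok <- !is.na(partner)
  sp <- sqrt(rowSums(sn$v^2))
  num <- sum((sp[ok] - sp[partner[ok]])^2)
  den <- sum(sp[ok]^2) + 1e-300
  sqrt(num / den)
}

#' Near-wall microstreaming speeds on the near and far side of the bubble
#'
#' Mean blood speed within a sampling ball near the wall at azimuth 0
#' (near side, +y) and azimuth 180 (far side, -y) in the bubble-center
#' plane; used to compare microstreaming intensity on the two sides.
#' With `t = NULL` the stored snapshot with the strongest flow is used
#' (side ratios at a near-quiescent phase are dominated by noise).
#'
#' @param run an `fsi_result`
#' @param t snapshot time [s], or `NULL` for the strongest snapshot
#' @param fraction sampling-ball radius as a fraction of the lumen radius
#' @return named vector with elements `near` and `far` [m/s]
#' @export
microstreaming_sides <- function(run, t = NULL, fraction = 0.35) {
  if (is.null(t)) {
    speeds <- vapply(run$snapshots, function(s)
      mean(rowSums(s$v^2)), numeric(1))
    t <- run$snapshots[[which.max(speeds)]]$t
  }
  sn <- microstreaming_snapshot(run, t)
  r_i <- run$system$mesh$spec$vessel_inner_radius
  rad <- fraction * r_i
  pick <- function(center) {
    d2 <- (sn$X[, 1L] - center[1L])^2 + (sn$X[, 2L] - center[2L])^2 +
      (sn$X[, 3L] - center[3L])^2
    sel <- d2 < rad^2
    mean(sqrt(rowSums(sn$v[sel, , drop = FALSE]^2)))
  }
  c(near = pick(c(0, 0.75 * r_i, 0)), far = pick(c(0, -0.75 * r_i, 0)))
}
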