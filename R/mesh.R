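# Structured mapped tetrahedral mesher for the half-symmetry
# bubble-blood-vessel-tissue-absorbing-layer geometry.
#
# Construction: a structured triangulation of the half unit sphere of ray
# directions around the bubble center (polar angle u from +z, azimuth phi in
# [0, pi] from +y toward +x so that the phi = 0 and phi = pi columns lie
# exactly on the symmetry plane x = 0).  Per azimuth column the polar grid is
# aligned with the cylinder corner circle, so every direction ray exits the
# lumen either purely through the lateral wall or purely through an end
# plane.  Blood is meshed as graded radial shells between the bubble surface
# and the exit surface (prisms split into tetrahedra with an index-based
# diagonal rule, hence conforming); the gas ball as radial shells plus a
# center fan; vessel, tissue and absorbing layer by radial extrusion of the
# lateral wall triangulation.

#' Mesh resolution presets
#'
#' @param resolution `"coarse"`, `"medium"` or `"fine"`, or a named list of
#'   explicit parameters (overrides applied on top of `"medium"`)
#' @return list of mesher parameters
#' @export
resolution_params <- function(resolution = "medium") {
  # azimuth counts are multiples of 8 so the nine 22.5 deg wall stations
  # coincide with node columns
  presets <- list(
    reduced = list(n_phi = 8L, n_cap = 2L, n_lat = 6L, n_shell = 5L,
                   n_gas = 2L, n_wall = 2L, n_tissue = 2L, n_pml = 2L,
                   bl_lambda = 0.55, lat_cluster = 0.4, hb_frac = 0.35),
    coarse = list(n_phi = 8L, n_cap = 2L, n_lat = 8L, n_shell = 6L,
                  n_gas = 3L, n_wall = 2L, n_tissue = 2L, n_pml = 2L,
                  bl_lambda = 0.55, lat_cluster = 0.4),
    medium = list(n_phi = 16L, n_cap = 4L, n_lat = 18L, n_shell = 10L,
                  n_gas = 5L, n_wall = 2L, n_tissue = 3L, n_pml = 3L,
                  bl_lambda = 0.6, lat_cluster = 0.4),
    fine = list(n_phi = 24L, n_cap = 5L, n_lat = 26L, n_shell = 14L,
                n_gas = 7L, n_wall = 3L, n_tissue = 4L, n_pml = 4L,
                bl_lambda = 0.6, lat_cluster = 0.4))
  if (is.character(resolution)) {
    resolution <- match.arg(resolution, names(presets))
    presets[[resolution]]
  } else if (is.list(resolution)) {
    p <- presets$medium
    p[names(resolution)] <- resolution
    p
  } else stop("resolution_params: resolution must be a name or a list")
}

# two-sided graded map [0,1] -> [0,1]: end spacings ~ (1 - lambda) x uniform
.graded01 <- function(s, lambda) (1 - lambda) * s + lambda * s^2 * (3 - 2 * s)

# per-ray shell grading: rows = rays of length D (bubble surface to exit),
# columns = cumulative fractions in [0, 1].  Spacing density is small near
# the bubble (~0.5 R0 absolute) and near the wall (boundary layer), filling
# the middle with roughly uniform cells
.ray_grading <- function(D, R0, n_shell, hb_frac = 0.35) {
  sk <- (seq_len(n_shell) - 0.5) / n_shell
  out <- matrix(0, length(D), n_shell + 1L)
  for (r in seq_along(D)) {
    hb <- min(hb_frac * R0, D[r] / n_shell)
    hw <- min(1.2 * hb, 0.15 * D[r])
    hm <- D[r] / max(2, n_shell - 2)
    dens <- 1 / (exp(-sk / 0.15) / hb + exp(-(1 - sk) / 0.15) / hw + 1 / hm)
    out[r, ] <- c(0, cumsum(dens) / sum(dens))
  }
  out
}

# mid-clustered map for the lateral polar band (refines near z = 0)
.midcluster01 <- function(s, a) s + a * sin(2 * pi * s) / (2 * pi)

#' Generate the tagged tetrahedral mesh
#'
#' @param spec a [geometry_spec()] (or a [build_geometry()] result)
#' @param resolution preset name or parameter list, see [resolution_params()]
#' @param quality_floor minimum admissible dihedral angle [deg]; generation
#'   fails if the mesh falls below it.  The default guards against
#'   degeneracy only: the thin vessel wall and the near-wall boundary layer
#'   are meshed with intentionally anisotropic (flat) tetrahedra whose
#'   smallest dihedral angles are a few degrees by design
#' @param seed unused placeholder for interface stability: the mapped mesher
#'   is fully deterministic, identical spec and resolution give an identical
#'   mesh
#' @return object of class `vc_mesh`: vertices, tetrahedra with region tags
#'   (`gas`, `blood`, `vessel`, `tissue`, `pml`), tagged facets
#'   (`bubble_interface`, `vessel_inner_wall`, `vessel_outer_wall`,
#'   `symmetry_plane`, `axial_ends`, `pml_outer`) and the structured maps
#'   used for the moving-mesh update.
#' @export
generate_mesh <- function(spec = geometry_spec(), resolution = "medium",
                          quality_floor = 0.25, seed = 1L) {
  geo <- if (inherits(spec, "geometry")) spec else build_geometry(spec)
  spec <- geo$spec
  p <- resolution_params(resolution)
  R0 <- spec$bubble_radius; C <- spec$bubble_offset
  r_i <- spec$vessel_inner_radius; r_o <- geo$r_o
  r_t <- spec$tissue_outer_radius; r_p <- geo$r_pml_outer
  L <- spec$axial_half_length
  b0 <- c(0, C, 0)

  n_phi <- p$n_phi; n_cap <- p$n_cap; n_lat <- p$n_lat
  n_u <- 2L * n_cap + n_lat
  phi <- seq(0, pi, length.out = n_phi + 1L)

  # lateral exit distance along direction (u, phi) from the bubble center
  t_lateral <- function(u, ph) {
    sx <- sin(u) * sin(ph); sy <- sin(u) * cos(ph)
    a <- sx^2 + sy^2
    b <- 2 * C * sy
    cc <- C^2 - r_i^2
    ifelse(a < 1e-30, Inf, (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a))
  }
  # per-column corner polar angle: lateral exit has z = +L
  u_star <- vapply(phi, function(ph) {
    f <- function(u) t_lateral(u, ph) * cos(u) - L
    stats::uniroot(f, c(1e-8, pi / 2 - 1e-8), tol = 1e-14)$root
  }, numeric(1))

  # per-column polar rows: caps uniform, lateral band clustered toward z = 0
  u_grid <- matrix(0, n_u + 1L, n_phi + 1L)
  for (j in seq_len(n_phi + 1L)) {
    us <- u_star[j]
    cap_top <- us * seq(0, 1, length.out = n_cap + 1L)
    s <- .midcluster01(seq(0, 1, length.out = n_lat + 1L), p$lat_cluster)
    lat <- us + (pi - 2 * us) * s
    cap_bot <- pi - us * seq(1, 0, length.out = n_cap + 1L)
    u_grid[, j] <- c(cap_top, lat[-1L], cap_bot[-1L])
  }

  # direction nodes: poles shared across columns
  n_dir <- (n_u - 1L) * (n_phi + 1L) + 2L
  dir_id <- matrix(0L, n_u + 1L, n_phi + 1L)  # (row i+1, col j+1) -> node id
  dir_id[1L, ] <- 1L                          # pole +z
  dir_id[n_u + 1L, ] <- n_dir                 # pole -z
  dir_id[2:n_u, ] <- matrix(seq_len((n_u - 1L) * (n_phi + 1L)) + 1L,
                            n_u - 1L, n_phi + 1L)
  dirs <- matrix(0, n_dir, 3L)
  for (j in seq_len(n_phi + 1L)) for (i in seq_len(n_u + 1L)) {
    u <- u_grid[i, j]
    dirs[dir_id[i, j], ] <- c(sin(u) * sin(phi[j]), sin(u) * cos(phi[j]), cos(u))
  }
  # exact symmetry plane
  dirs[dir_id[, 1L], 1L] <- 0
  dirs[dir_id[, n_phi + 1L], 1L] <- 0
  dirs <- dirs / sqrt(rowSums(dirs^2))

  # direction triangles, oriented so that the normal points away from b0
  tri <- matrix(0L, 0L, 3L); tri_band <- integer(0)  # 1 cap+, 2 lateral, 3 cap-
  band_of_row <- function(i) if (i <= n_cap) 1L else if (i <= n_cap + n_lat) 2L else 3L
  for (i in seq_len(n_u)) {
    bi <- band_of_row(i)
    for (j in seq_len(n_phi)) {
      a <- dir_id[i, j]; b <- dir_id[i + 1L, j]
      cc <- dir_id[i + 1L, j + 1L]; d <- dir_id[i, j + 1L]
      if (i == 1L) {                      # top pole fan (a == d)
        tri <- rbind(tri, c(a, cc, b)); tri_band <- c(tri_band, bi)
      } else if (i == n_u) {              # bottom pole fan (b == cc)
        tri <- rbind(tri, c(a, d, b)); tri_band <- c(tri_band, bi)
      } else {
        # one diagonal orientation throughout: the triangulation is then
        # invariant under single-column azimuth shifts, so the nine
        # 22.5-degree wall stations see identical discretizations
        tri <- rbind(tri, c(a, cc, b), c(a, d, cc))
        tri_band <- c(tri_band, bi, bi)
      }
    }
  }
  n_tri <- nrow(tri)

  # exit distance and exit surface per direction node
  row_of <- integer(n_dir); col_of <- integer(n_dir)
  for (j in seq_len(n_phi + 1L)) for (i in seq_len(n_u + 1L)) {
    row_of[dir_id[i, j]] <- i; col_of[dir_id[i, j]] <- j
  }
  t_exit <- numeric(n_dir)
  on_lateral <- logical(n_dir); on_end <- logical(n_dir)
  for (kk in seq_len(n_dir)) {
    i <- row_of[kk]; j <- col_of[kk]
    u <- u_grid[i, j]
    lat_row <- i >= (n_cap + 1L) && i <= (n_cap + n_lat + 1L)
    end_row <- i <= (n_cap + 1L) || i >= (n_cap + n_lat + 1L)
    if (lat_row) t_exit[kk] <- t_lateral(u, phi[j]) else t_exit[kk] <- L / abs(cos(u))
    on_lateral[kk] <- lat_row
    on_end[kk] <- end_row
  }

  # ---- vertices -------------------------------------------------------------
  # per-direction radial grading: the first shell spacing at the bubble is
  # an absolute fraction of R0 (the near-field added mass must be equally
  # resolved along every ray regardless of how far that ray travels), with
  # wall-side boundary-layer refinement and a smooth fill in between
  n_shell <- p$n_shell
  g <- .ray_grading(t_exit - R0, R0, n_shell, p$hb_frac %||% 0.35)
  n_blood_nodes <- n_dir * (n_shell + 1L)
  blood_idx <- matrix(seq_len(n_blood_nodes), n_dir, n_shell + 1L)
  verts <- matrix(0, n_blood_nodes, 3L)
  for (m in seq_len(n_shell + 1L)) {
    rad <- R0 + (t_exit - R0) * g[, m]
    verts[blood_idx[, m], ] <- rep(b0, each = n_dir) + dirs * rad
  }
  # snap exit shell exactly onto the cylinder boundary
  out_ids <- blood_idx[, n_shell + 1L]
  lat_ids <- out_ids[on_lateral]
  rxy <- sqrt(verts[lat_ids, 1L]^2 + verts[lat_ids, 2L]^2)
  verts[lat_ids, 1:2] <- verts[lat_ids, 1:2] * (r_i / rxy)
  endi <- out_ids[on_end & !on_lateral]
  verts[endi, 3L] <- sign(verts[endi, 3L]) * L
  corner <- out_ids[on_end & on_lateral]
  verts[corner, 3L] <- sign(verts[corner, 3L]) * L
  # interior shells as an exact blend of the (snapped) boundary shells, the
  # same rule the moving-mesh update uses
  inner <- verts[blood_idx[, 1L], ]
  outer <- verts[out_ids, ]
  for (m in 2:n_shell) {
    verts[blood_idx[, m], ] <- inner + g[, m] * (outer - inner)
  }

  # solid extrusion of the lateral wall nodes
  wall_dir <- which(on_lateral)                    # direction-node subset
  wall_ids <- blood_idx[wall_dir, n_shell + 1L]
  tis_frac <- .graded01(seq(0, 1, length.out = p$n_tissue + 1L), 0.45)
  layer_r <- c(r_i + (r_o - r_i) * seq(0, 1, length.out = p$n_wall + 1L)[-1L],
               r_o + (r_t - r_o) * tis_frac[-1L],
               r_t + (r_p - r_t) * seq(0, 1, length.out = p$n_pml + 1L)[-1L])
  layer_region <- c(rep("vessel", p$n_wall), rep("tissue", p$n_tissue),
                    rep("pml", p$n_pml))
  n_layer <- length(layer_r)
  n_wl <- length(wall_dir)
  solid_idx <- matrix(0L, n_wl, n_layer + 1L)
  solid_idx[, 1L] <- wall_ids
  base <- n_blood_nodes
  wall_xy <- verts[wall_ids, 1:2]
  for (l in seq_len(n_layer)) {
    ids <- base + seq_len(n_wl); base <- base + n_wl
    solid_idx[, l + 1L] <- ids
    verts <- rbind(verts, cbind(wall_xy * (layer_r[l] / r_i),
                                verts[wall_ids, 3L]))
  }
  # gas interior: shells m = 1..n_gas-1 plus center node
  n_gas <- p$n_gas
  gas_idx <- matrix(0L, n_dir, n_gas + 1L)
  gas_idx[, n_gas + 1L] <- blood_idx[, 1L]         # bubble interface
  for (m in seq_len(n_gas - 1L)) {
    ids <- base + seq_len(n_dir); base <- base + n_dir
    gas_idx[, m + 1L] <- ids
    verts <- rbind(verts, rep(b0, each = n_dir) + dirs * (R0 * m / n_gas))
  }
  gas_center <- base + 1L
  verts <- rbind(verts, b0)
  gas_idx[, 1L] <- gas_center

  # ---- tetrahedra -----------------------------------------------------------
  # structural node keys (radial layer, polar row, azimuth column) drive
  # the prism splits so the pattern is azimuth-shift invariant
  col_key <- col_of
  col_key[c(1L, n_dir)] <- 0L
  dir_key <- row_of * (n_phi + 3L) + col_key
  KB <- max(dir_key) + 1L
  tets <- vector("list", 8L); regs <- vector("list", 8L); tk <- 0L
  add <- function(T4, region) {
    tk <<- tk + 1L; tets[[tk]] <<- T4
    regs[[tk]] <<- rep(region, nrow(T4))
    invisible(NULL)
  }
  tri_key <- matrix(dir_key[tri], n_tri, 3L)
  for (m in seq_len(n_shell)) {
    B <- matrix(blood_idx[tri, m], n_tri, 3L)
    T_ <- matrix(blood_idx[tri, m + 1L], n_tri, 3L)
    add(.split_prisms(B, T_, m * KB + tri_key, (m + 1L) * KB + tri_key),
        "blood")
  }
  wall_pos <- integer(n_dir); wall_pos[wall_dir] <- seq_len(n_wl)
  lat_tri <- tri[tri_band == 2L, , drop = FALSE]
  lat_tri_loc <- matrix(wall_pos[lat_tri], nrow(lat_tri), 3L)
  lat_key <- matrix(dir_key[lat_tri], nrow(lat_tri), 3L)
  for (l in seq_len(n_layer)) {
    B <- matrix(solid_idx[lat_tri_loc, l], nrow(lat_tri), 3L)
    T_ <- matrix(solid_idx[lat_tri_loc, l + 1L], nrow(lat_tri), 3L)
    add(.split_prisms(B, T_, l * KB + lat_key, (l + 1L) * KB + lat_key),
        layer_region[l])
  }
  # gas: center fan to shell 1 (triangles flipped: normal toward center node)
  fan_tri <- matrix(gas_idx[tri, 2L], n_tri, 3L)
  add(cbind(gas_center, fan_tri), "gas")
  if (n_gas > 1L) for (m in 2L:n_gas) {
    B <- matrix(gas_idx[tri, m], n_tri, 3L)
    T_ <- matrix(gas_idx[tri, m + 1L], n_tri, 3L)
    add(.split_prisms(B, T_, m * KB + tri_key, (m + 1L) * KB + tri_key),
        "gas")
  }
  tets <- do.call(rbind, tets[seq_len(tk)])
  region <- unlist(regs[seq_len(tk)])

  # orientation fix: make all volumes positive
  v6 <- .tet_volumes(verts, tets)
  flip <- v6 < 0
  if (any(flip)) tets[flip, 2:3] <- tets[flip, c(3L, 2L)]

  mesh <- structure(list(
    vertices = verts, tets = tets, region = region,
    spec = spec, geometry = geo, params = p,
    maps = list(blood_idx = blood_idx, gas_idx = gas_idx,
                solid_idx = solid_idx, dirs = dirs, t_exit = t_exit,
                g = g, wall_dir = wall_dir, on_lateral = on_lateral,
                on_end = on_end, tri = tri, tri_band = tri_band,
                bubble_center = b0, n_dir = n_dir,
                layer_region = layer_region)),
    class = "vc_mesh")
  mesh$facets <- .tag_facets(mesh)
  q <- mesh_quality(mesh)
  if (q$inverted_count > 0L)
    stop("generate_mesh: inverted elements produced")
  if (q$min_dihedral_angle < quality_floor)
    stop(sprintf("generate_mesh: min dihedral %.2f deg below quality floor %g",
                 q$min_dihedral_angle, quality_floor))
  mesh$quality <- q
  mesh
}

# Conforming prism-to-tet split.  B, T: n x 3 bottom/top vertex ids, bottom
# oriented toward the top.  Face diagonals pass through the smallest-KEY
# vertex of each quad face, which makes the split agree between
# neighbours; with structural (shell, row, column) keys the pattern is
# invariant under azimuth-column shifts, so the discretization treats the
# nine wall stations identically.  Keys default to the vertex ids.
.split_prisms <- function(B, T_, keyB = B, keyT = T_) {
  n <- nrow(B)
  V <- cbind(B, T_)
  K <- cbind(keyB, keyT)
  # flip so the overall smallest key lies on the bottom (mirror keeps
  # orientation)
  flip <- apply(K[, 4:6, drop = FALSE], 1L, min) <
    apply(K[, 1:3, drop = FALSE], 1L, min)
  if (any(flip)) {
    perm <- c(4L, 6L, 5L, 1L, 3L, 2L)
    V[flip, ] <- V[flip, perm, drop = FALSE]
    K[flip, ] <- K[flip, perm, drop = FALSE]
  }
  # rotate bottom so its smallest key is first
  k <- max.col(-matrix(K[, 1:3], n, 3L), ties.method = "first")
  rot <- function(idx, k) V[cbind(seq_len(n), ((k - 1L + idx - 1L) %% 3L) + 1L)]
  rotT <- function(idx, k) V[cbind(seq_len(n), ((k - 1L + idx - 1L) %% 3L) + 4L)]
  rotK <- function(idx, k) K[cbind(seq_len(n), ((k - 1L + idx - 1L) %% 3L) + 1L)]
  rotKT <- function(idx, k) K[cbind(seq_len(n), ((k - 1L + idx - 1L) %% 3L) + 4L)]
  v1 <- rot(1L, k); v2 <- rot(2L, k); v3 <- rot(3L, k)
  v4 <- rotT(1L, k); v5 <- rotT(2L, k); v6 <- rotT(3L, k)
  k2 <- rotK(2L, k); k3 <- rotK(3L, k)
  k5 <- rotKT(2L, k); k6 <- rotKT(3L, k)
  caseA <- pmin(k2, k6) < pmin(k3, k5)
  out <- matrix(0L, 3L * n, 4L)
  ia <- which(caseA); ib <- which(!caseA)
  if (length(ia)) {
    out[3 * (ia - 1) + 1, ] <- cbind(v1[ia], v2[ia], v3[ia], v6[ia])
    out[3 * (ia - 1) + 2, ] <- cbind(v1[ia], v2[ia], v6[ia], v5[ia])
    out[3 * (ia - 1) + 3, ] <- cbind(v1[ia], v5[ia], v6[ia], v4[ia])
  }
  if (length(ib)) {
    out[3 * (ib - 1) + 1, ] <- cbind(v1[ib], v2[ib], v3[ib], v5[ib])
    out[3 * (ib - 1) + 2, ] <- cbind(v1[ib], v5[ib], v3[ib], v6[ib])
    out[3 * (ib - 1) + 3, ] <- cbind(v1[ib], v5[ib], v6[ib], v4[ib])
  }
  out
}

.tet_volumes <- function(verts, tets) {
  a <- verts[tets[, 2L], ] - verts[tets[, 1L], ]
  b <- verts[tets[, 3L], ] - verts[tets[, 1L], ]
  cc <- verts[tets[, 4L], ] - verts[tets[, 1L], ]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
     a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
     a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# Extract and tag boundary/interface facets (vectorized).
.tag_facets <- function(mesh) {
  tets <- mesh$tets; region <- mesh$region; v <- mesh$vertices
  faces <- rbind(tets[, c(2L, 3L, 4L)], tets[, c(1L, 4L, 3L)],
                 tets[, c(1L, 2L, 4L)], tets[, c(1L, 3L, 2L)])
  owner <- rep(seq_len(nrow(tets)), 4L)
  fa <- pmin(faces[, 1L], faces[, 2L], faces[, 3L])
  fc <- pmax(faces[, 1L], faces[, 2L], faces[, 3L])
  fb <- faces[, 1L] + faces[, 2L] + faces[, 3L] - fa - fc
  nv <- nrow(v)
  key <- (as.numeric(fa) * nv + fb) * nv + fc
  uk <- unique(key); idx <- match(key, uk); cnt <- tabulate(idx, length(uk))
  spec <- mesh$spec; geo <- mesh$geometry
  r_p <- geo$r_pml_outer; L <- spec$axial_half_length
  tol <- 1e-6 * spec$vessel_inner_radius

  geom_tag <- function(f) {
    x1 <- abs(v[f[, 1L], 1L]); x2 <- abs(v[f[, 2L], 1L]); x3 <- abs(v[f[, 3L], 1L])
    z1 <- abs(abs(v[f[, 1L], 3L]) - L); z2 <- abs(abs(v[f[, 2L], 3L]) - L)
    z3 <- abs(abs(v[f[, 3L], 3L]) - L)
    r1 <- abs(sqrt(v[f[, 1L], 1L]^2 + v[f[, 1L], 2L]^2) - r_p)
    r2 <- abs(sqrt(v[f[, 2L], 1L]^2 + v[f[, 2L], 2L]^2) - r_p)
    r3 <- abs(sqrt(v[f[, 3L], 1L]^2 + v[f[, 3L], 2L]^2) - r_p)
    tag <- rep(NA_character_, nrow(f))
    tag[x1 < tol & x2 < tol & x3 < tol] <- "symmetry_plane"
    nat <- is.na(tag)
    tag[nat & z1 < tol & z2 < tol & z3 < tol] <- "axial_ends"
    nat <- is.na(tag)
    tag[nat & r1 < tol & r2 < tol & r3 < tol] <- "pml_outer"
    tag
  }

  # boundary facets (owned by exactly one tet)
  bd <- which(cnt[idx] == 1L)
  bd_tag <- geom_tag(faces[bd, , drop = FALSE])
  keep <- !is.na(bd_tag)
  out_f <- faces[bd[keep], , drop = FALSE]
  out_tag <- bd_tag[keep]
  out_owner <- owner[bd[keep]]

  # interface facets between different regions
  ii <- which(cnt[idx] == 2L)
  o <- ii[order(key[ii])]
  first <- o[seq(1L, length(o), by = 2L)]
  second <- o[seq(2L, length(o), by = 2L)]
  r1 <- region[owner[first]]; r2 <- region[owner[second]]
  dif <- r1 != r2
  first <- first[dif]; second <- second[dif]
  r1 <- r1[dif]; r2 <- r2[dif]
  plo <- pmin(r1, r2); phi <- pmax(r1, r2)
  itag <- rep(NA_character_, length(first))
  itag[plo == "blood" & phi == "gas"] <- "bubble_interface"
  itag[plo == "blood" & phi == "vessel"] <- "vessel_inner_wall"
  itag[plo == "tissue" & phi == "vessel"] <- "vessel_outer_wall"
  keep <- !is.na(itag)
  # store with the fluid-side (blood) or inner-side owner
  fo <- ifelse(region[owner[first]] %in% c("blood", "vessel"),
               first, second)[keep]
  # orient stored interface facets outward from the fluid-side owner tet
  of <- faces[fo, , drop = FALSE]
  list(facets = rbind(out_f, of),
       tag = c(out_tag, itag[keep]),
       owner = c(out_owner, owner[fo]))
}

#' Mesh quality report
#'
#' @param mesh a `vc_mesh`
#' @return object of class `mesh_quality_report` with element counts, minimum
#'   dihedral angle, bubble-surface facet count, meshed vs analytic half
#'   bubble volume and the volume deficit in percent
#' @export
mesh_quality <- function(mesh) {
  v6 <- .tet_volumes(mesh$vertices, mesh$tets)
  dih <- .min_dihedral(mesh$vertices, mesh$tets)
  gas <- mesh$region == "gas"
  vol_gas <- sum(v6[gas])
  vol_true <- 2 / 3 * pi * mesh$spec$bubble_radius^3
  n_bub <- sum(mesh$facets$tag == "bubble_interface")
  structure(list(
    element_count = nrow(mesh$tets),
    inverted_count = sum(v6 <= 0),
    min_dihedral_angle = dih,
    bubble_surface_facet_count = n_bub,
    meshed_bubble_volume = vol_gas,
    analytic_bubble_volume = vol_true,
    volume_deficit = 100 * (vol_true - vol_gas) / vol_true,
    region_volumes = tapply(v6, mesh$region, sum)),
    class = "mesh_quality_report")
}

# minimum dihedral angle (degrees) over all tets, vectorized
.min_dihedral <- function(verts, tets) {
  p1 <- verts[tets[, 1L], , drop = FALSE]
  p2 <- verts[tets[, 2L], , drop = FALSE]
  p3 <- verts[tets[, 3L], , drop = FALSE]
  p4 <- verts[tets[, 4L], , drop = FALSE]
  crossp <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  nrm <- function(a) sqrt(rowSums(a^2))
  # inward face normals opposite each vertex
  n1 <- crossp(p3 - p2, p4 - p2)  # face (2,3,4)
  n2 <- crossp(p4 - p1, p3 - p1)  # face (1,4,3)
  n3 <- crossp(p2 - p1, p4 - p1)  # face (1,2,4)
  n4 <- crossp(p3 - p1, p2 - p1)  # face (1,3,2)
  ang <- function(a, b) {
    cth <- -rowSums(a * b) / (nrm(a) * nrm(b))
    acos(pmin(1, pmax(-1, cth))) * 180 / pi
  }
  m <- pmin(ang(n1, n2), ang(n1, n3), ang(n1, n4),
            ang(n2, n3), ang(n2, n4), ang(n3, n4))
  min(m)
}

#' @export
print.mesh_quality_report <- function(x, ...) {
  cat("<mesh_quality_report>",
      sprintf("%d tets (%d inverted), min dihedral %.2f deg",
              x$element_count, x$inverted_count, x$min_dihedral_angle),
      sprintf("bubble surface: %d facets, volume deficit %.3f%%",
              x$bubble_surface_facet_count, x$volume_deficit),
      sep = "\n")
  invisible(x)
}

#' @export
print.vc_mesh <- function(x, ...) {
  cat(sprintf("<vc_mesh> %d vertices, %d tets\n", nrow(x$vertices),
              nrow(x$tets)))
  print(table(x$region))
  invisible(x)
}
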