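#' Interior mesh smoothing under prescribed boundary motion
#'
#' Propagates boundary displacements into the interior of a region by
#' stiffened harmonic smoothing: each displacement component solves a
#' scalar diffusion problem whose element coefficient is the inverse
#' element volume, so small elements (boundary layers, near-interface
#' shells) move almost rigidly while large elements absorb the deformation.
#' Raises `"remesh required"` if the update would invert elements or drop
#' the minimum dihedral angle below `quality_floor`.
#'
#' During time stepping the solver uses the structured transfinite ray
#' update instead (exact for the layered topology and cheaper); this
#' general smoother backs arbitrary boundary motion on any region.
#'
#' @param mesh a `vc_mesh`
#' @param displacements matrix (n_constrained x 3) of boundary
#'   displacements [m]
#' @param nodes vertex indices (into `mesh$vertices`) carrying the
#'   prescribed displacements; all other boundary-tagged vertices of the
#'   region are held fixed
#' @param region which region's interior to smooth (default `"blood"`)
#' @param quality_floor minimum admissible dihedral angle [deg] after the
#'   update
#' @return the mesh with updated `vertices`
#' @export
#' @examples
#' m <- generate_mesh(geometry_spec(), "coarse")
#' bub <- sort(unique(as.vector(m$facets$facets[m$facets$tag == "bubble_interface", ])))
#' disp <- 0.1 * (m$vertices[bub, ] - rep(c(0, 0, 0), each = length(bub)))
#' m2 <- smooth_mesh(m, disp, bub)     # 10 % bubble expansion
smooth_mesh <- function(mesh, displacements, nodes, region = "blood",
                        quality_floor = 0.1) {
  stopifnot(inherits(mesh, "vc_mesh"))
  tets_g <- mesh$tets[mesh$region == region, , drop = FALSE]
  rnodes <- sort(unique(as.vector(tets_g)))
  l2g <- rnodes
  g2l <- integer(nrow(mesh$vertices)); g2l[rnodes] <- seq_along(rnodes)
  tets <- matrix(g2l[tets_g], ncol = 4L)
  verts <- mesh$vertices[rnodes, , drop = FALSE]
  geom <- fem_tet_geom(verts, tets)
  K <- fem_sparse(fem_asm_scalar_stiff(tets, geom, 1 / geom$vol),
                  length(rnodes), length(rnodes))
  # Dirichlet sets: prescribed nodes + all other tagged boundary vertices
  presc <- g2l[nodes]
  if (any(presc == 0L)) stop("smooth_mesh: some nodes are not in the region")
  tagged <- sort(unique(as.vector(mesh$facets$facets)))
  fixed <- setdiff(g2l[intersect(tagged, rnodes)], presc)
  dir_nodes <- c(presc, fixed)
  dir_val <- rbind(as.matrix(displacements),
                   matrix(0, length(fixed), 3L))
  free <- setdiff(seq_along(rnodes), dir_nodes)
  disp <- matrix(0, length(rnodes), 3L)
  disp[dir_nodes, ] <- dir_val
  if (length(free)) {
    Kff <- K[free, free, drop = FALSE]
    Kfd <- K[free, dir_nodes, drop = FALSE]
    for (ci in 1:3) {
      rhs <- -as.numeric(Kfd %*% dir_val[, ci])
      disp[free, ci] <- as.numeric(Matrix::solve(Kff, rhs))
    }
  }
  new_verts <- mesh$vertices
  new_verts[l2g, ] <- verts + disp
  vol_new <- .tet_volumes(new_verts, tets_g)
  if (any(vol_new <= 0)) stop("smooth_mesh: remesh required (inverted elements)")
  if (.min_dihedral(new_verts, tets_g) < quality_floor)
    stop("smooth_mesh: remesh required (quality below floor)")
  mesh$vertices <- new_verts
  mesh
}
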