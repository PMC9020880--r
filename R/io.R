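# Plain-text mesh and field export: Gmsh MSH 2.2 and legacy VTK ASCII.

.region_codes <- c(gas = 1L, blood = 2L, vessel = 3L, tissue = 4L, pml = 5L)
.facet_codes <- c(bubble_interface = 11L, vessel_inner_wall = 12L,
                  vessel_outer_wall = 13L, symmetry_plane = 14L,
                  axial_ends = 15L, pml_outer = 16L)

#' Write a mesh in Gmsh MSH 2.2 ASCII format
#'
#' Region tags become tetrahedron physical tags (gas = 1, blood = 2,
#' vessel = 3, tissue = 4, pml = 5); tagged boundary/interface facets are
#' written as triangles with physical tags 11-16.
#'
#' @param mesh a `vc_mesh`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(mesh$vertices))), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(mesh$vertices)),
                     mesh$vertices[, 1L], mesh$vertices[, 2L],
                     mesh$vertices[, 3L]), con)
  writeLines("$EndNodes", con)
  nf <- nrow(mesh$facets$facets); nt <- nrow(mesh$tets)
  writeLines(c("$Elements", as.character(nf + nt)), con)
  fc <- .facet_codes[mesh$facets$tag]
  writeLines(sprintf("%d 2 2 %d %d %d %d %d", seq_len(nf), fc, fc,
                     mesh$facets$facets[, 1L], mesh$facets$facets[, 2L],
                     mesh$facets$facets[, 3L]), con)
  rc <- .region_codes[mesh$region]
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", nf + seq_len(nt), rc, rc,
                     mesh$tets[, 1L], mesh$tets[, 2L], mesh$tets[, 3L],
                     mesh$tets[, 4L]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh MSH 2.2 ASCII mesh written by [write_msh()]
#'
#' @param path file path
#' @return list with `vertices`, `tets`, `region`, `facets`, `facet_tag`
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  i_n <- which(lines == "$Nodes")
  n_nodes <- as.integer(lines[i_n + 1L])
  nd <- utils::read.table(text = lines[(i_n + 2L):(i_n + 1L + n_nodes)])
  i_e <- which(lines == "$Elements")
  n_el <- as.integer(lines[i_e + 1L])
  el_lines <- lines[(i_e + 2L):(i_e + 1L + n_el)]
  parts <- strsplit(el_lines, " ", fixed = TRUE)
  typ <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
  tri <- t(vapply(parts[typ == 2L],
                  function(p) as.integer(p[c(4L, 6L, 7L, 8L)]), integer(4)))
  tet <- t(vapply(parts[typ == 4L],
                  function(p) as.integer(p[c(4L, 6L, 7L, 8L, 9L)]), integer(5)))
  rc_inv <- names(.region_codes)[order(.region_codes)]
  fc_names <- names(.facet_codes)
  list(vertices = as.matrix(nd[, 2:4]),
       tets = tet[, 2:5, drop = FALSE],
       region = names(.region_codes)[match(tet[, 1L], .region_codes)],
       facets = tri[, 2:4, drop = FALSE],
       facet_tag = fc_names[match(tri[, 1L], .facet_codes)])
}

#' Write a mesh (with optional nodal fields) as legacy ASCII VTK
#'
#' @param mesh a `vc_mesh`, or a list with `vertices` and `tets`
#' @param path output `.vtk` path
#' @param point_data named list of nodal fields (vectors or n x 3 matrices
#'   indexed like `vertices`)
#' @param vertices optional replacement coordinates (deformed geometry)
#' @return `path`, invisibly
#' @export
write_vtk <- function(mesh, path, point_data = list(), vertices = NULL) {
  v <- if (is.null(vertices)) mesh$vertices else vertices
  tt <- mesh$tets
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vescav export", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.17g %.17g %.17g", v[, 1L], v[, 2L], v[, 3L]), con)
  writeLines(sprintf("CELLS %d %d", nrow(tt), 5L * nrow(tt)), con)
  writeLines(sprintf("4 %d %d %d %d", tt[, 1L] - 1L, tt[, 2L] - 1L,
                     tt[, 3L] - 1L, tt[, 4L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(tt)), con)
  writeLines(rep("10", nrow(tt)), con)
  if (!is.null(mesh$region)) {
    writeLines(sprintf("CELL_DATA %d", nrow(tt)), con)
    writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(.region_codes[mesh$region]), con)
  }
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(point_data)) {
      f <- point_data[[nm]]
      if (is.matrix(f) && ncol(f) == 3L) {
        writeLines(sprintf("VECTORS %s double", nm), con)
        writeLines(sprintf("%.10g %.10g %.10g", f[, 1L], f[, 2L], f[, 3L]),
                   con)
      } else {
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(sprintf("%.10g", f), con)
      }
    }
  }
  invisible(path)
}

#' Export a microstreaming snapshot as VTK on the deformed blood mesh
#'
#' @param run an `fsi_result`
#' @param t snapshot time [s]
#' @param path output `.vtk` path
#' @return `path`, invisibly
#' @export
write_snapshot_vtk <- function(run, t, path) {
  sn <- microstreaming_snapshot(run, t)
  sys <- run$system
  sub <- list(vertices = sn$X, tets = sys$bl_tets, region = NULL)
  write_vtk(sub, path, point_data = list(velocity = sn$v, pressure = sn$p))
}
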