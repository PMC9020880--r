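# Vectorized P1 tetrahedral finite-element kernels.
#
# All assembly routines return triplet lists (i, j, x) that the caller
# concatenates and turns into one sparse matrix; scalar DOFs are node
# indices, vector DOFs interleave components as (node - 1) * 3 + comp.

.crossp <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# per-tet volume and shape-function gradients
fem_tet_geom <- function(verts, tets) {
  p1 <- verts[tets[, 1L], , drop = FALSE]
  c1 <- verts[tets[, 2L], , drop = FALSE] - p1
  c2 <- verts[tets[, 3L], , drop = FALSE] - p1
  c3 <- verts[tets[, 4L], , drop = FALSE] - p1
  cr23 <- .crossp(c2, c3)
  det <- rowSums(c1 * cr23)           # 6 V
  g2 <- cr23 / det
  g3 <- .crossp(c3, c1) / det
  g4 <- .crossp(c1, c2) / det
  g1 <- -(g2 + g3 + g4)
  list(vol = det / 6, g = list(g1, g2, g3, g4))
}

# scalar stiffness sum_K coef_K int grad Na . grad Nb
fem_asm_scalar_stiff <- function(tets, geom, coef) {
  m <- nrow(tets)
  i <- integer(16L * m); j <- integer(16L * m); x <- numeric(16L * m)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    idx <- k * m + seq_len(m); k <- k + 1L
    i[idx] <- tets[, a]; j[idx] <- tets[, b]
    x[idx] <- coef * geom$vol * rowSums(geom$g[[a]] * geom$g[[b]])
  }
  list(i = i, j = j, x = x)
}

# consistent scalar mass int rho Na Nb (per-element rho allowed)
fem_asm_scalar_mass <- function(tets, geom, rho) {
  m <- nrow(tets)
  i <- integer(16L * m); j <- integer(16L * m); x <- numeric(16L * m)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    idx <- k * m + seq_len(m); k <- k + 1L
    i[idx] <- tets[, a]; j[idx] <- tets[, b]
    x[idx] <- rho * geom$vol / 20 * (1 + (a == b))
  }
  list(i = i, j = j, x = x)
}

# expand a scalar triplet list to identical blocks on all 3 components
fem_vectorize <- function(tr) {
  list(i = c(3L * (tr$i - 1L) + 1L, 3L * (tr$i - 1L) + 2L, 3L * tr$i),
       j = c(3L * (tr$j - 1L) + 1L, 3L * (tr$j - 1L) + 2L, 3L * tr$j),
       x = rep(tr$x, 3L))
}

# viscous/deviatoric stiffness int mu (grad v + grad v^T) : grad phi,
# i.e. blocks mu V (d_ij ga.gb + ga_j gb_i)
fem_asm_visc <- function(tets, geom, mu) {
  m <- nrow(tets)
  n_ent <- 144L * m
  i <- integer(n_ent); j <- integer(n_ent); x <- numeric(n_ent)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    gab <- rowSums(geom$g[[a]] * geom$g[[b]])
    for (ci in 1:3) for (cj in 1:3) {
      idx <- k * m + seq_len(m); k <- k + 1L
      i[idx] <- 3L * (tets[, a] - 1L) + ci
      j[idx] <- 3L * (tets[, b] - 1L) + cj
      v <- mu * geom$vol * geom$g[[a]][, cj] * geom$g[[b]][, ci]
      if (ci == cj) v <- v + mu * geom$vol * gab
      x[idx] <- v
    }
  }
  list(i = i, j = j, x = x)
}

# convection int rho Na (abar . grad Nb) (centroid-sampled advecting field)
fem_asm_conv <- function(tets, geom, afield, rho) {
  m <- nrow(tets)
  am <- (afield[tets[, 1L], , drop = FALSE] + afield[tets[, 2L], , drop = FALSE] +
           afield[tets[, 3L], , drop = FALSE] + afield[tets[, 4L], , drop = FALSE]) / 4
  i <- integer(16L * m); j <- integer(16L * m); x <- numeric(16L * m)
  k <- 0L
  for (a in 1:4) for (b in 1:4) {
    idx <- k * m + seq_len(m); k <- k + 1L
    i[idx] <- tets[, a]; j[idx] <- tets[, b]
    x[idx] <- rho * geom$vol / 4 * rowSums(am * geom$g[[b]])
  }
  fem_vectorize(list(i = i[seq_len(16L * m)], j = j, x = x))
}

# divergence coupling B[q, vdof] = int Nq d_i Nb
fem_asm_div <- function(tets, geom) {
  m <- nrow(tets)
  n_ent <- 48L * m
  i <- integer(n_ent); j <- integer(n_ent); x <- numeric(n_ent)
  k <- 0L
  for (a in 1:4) for (b in 1:4) for (ci in 1:3) {
    idx <- k * m + seq_len(m); k <- k + 1L
    i[idx] <- tets[, a]
    j[idx] <- 3L * (tets[, b] - 1L) + ci
    x[idx] <- geom$vol / 4 * geom$g[[b]][, ci]
  }
  list(i = i, j = j, x = x)
}

# P1 surface (Laplace-Beltrami, cotan) stiffness on a 3D triangulation,
# scalar.  Applied per coordinate component, K x is the exact gradient of
# the triangulated surface area, which makes the surface-tension force
# variational (the capillary energy sigma*A is a Lyapunov function of the
# coupled scheme)
fem_asm_surface_stiff <- function(tris, verts) {
  q1 <- verts[tris[, 1L], , drop = FALSE]
  q2 <- verts[tris[, 2L], , drop = FALSE]
  q3 <- verts[tris[, 3L], , drop = FALSE]
  e1 <- q3 - q2; e2 <- q1 - q3; e3 <- q2 - q1   # edges opposite vertices
  A <- sqrt(rowSums(.crossp(e3, -e2)^2)) / 2
  ee <- list(e1, e2, e3)
  m <- nrow(tris)
  i <- integer(9L * m); j <- integer(9L * m); x <- numeric(9L * m)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- k * m + seq_len(m); k <- k + 1L
    i[idx] <- tris[, a]; j[idx] <- tris[, b]
    x[idx] <- rowSums(ee[[a]] * ee[[b]]) / (4 * A)
  }
  list(i = i, j = j, x = x)
}

# exact gradient of the enclosed (gas-side) volume of an oriented closed
# triangulated surface with respect to vertex positions; `tris` oriented
# with normals pointing INTO the enclosed region (the blood-outward
# convention of the stored interface facets), `origin` any point in the
# plane of the open symmetry cap so the cap contributes nothing
fem_volume_grad <- function(tris, verts, n_nodes, origin = c(0, 0, 0)) {
  sh <- function(a) verts[tris[, a], , drop = FALSE] -
    matrix(origin, nrow(tris), 3L, byrow = TRUE)
  y1 <- sh(1L); y2 <- sh(2L); y3 <- sh(3L)
  # enclosed volume with outward orientation is (1/6) sum y1.(y2 x y3)
  # on the reversed triangles (1,3,2)
  g1 <- .crossp(y3, y2) / 6
  g2 <- .crossp(y1, y3) / 6
  g3 <- .crossp(y2, y1) / 6
  out <- matrix(0, n_nodes, 3L)
  for (a in 1:3) {
    g <- list(g1, g2, g3)[[a]]
    for (ci in 1:3) {
      s <- rowsum(g[, ci], tris[, a])
      out[as.integer(rownames(s)), ci] <- out[as.integer(rownames(s)), ci] + s
    }
  }
  out
}

# P1 surface mass matrix int Na Nb dGamma on a 3D triangulation, scalar
fem_asm_surface_mass <- function(tris, verts, coef = 1) {
  q1 <- verts[tris[, 1L], , drop = FALSE]
  q2 <- verts[tris[, 2L], , drop = FALSE]
  q3 <- verts[tris[, 3L], , drop = FALSE]
  A <- sqrt(rowSums(.crossp(q2 - q1, q3 - q1)^2)) / 2
  m <- nrow(tris)
  i <- integer(9L * m); j <- integer(9L * m); x <- numeric(9L * m)
  k <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- k * m + seq_len(m); k <- k + 1L
    i[idx] <- tris[, a]; j[idx] <- tris[, b]
    x[idx] <- coef * A / 12 * (1 + (a == b))
  }
  list(i = i, j = j, x = x)
}

# nodal area-weighted normal integrals int Na n dGamma over oriented facets
fem_facet_normal_int <- function(tris, verts, n_nodes) {
  q1 <- verts[tris[, 1L], , drop = FALSE]
  q2 <- verts[tris[, 2L], , drop = FALSE]
  q3 <- verts[tris[, 3L], , drop = FALSE]
  an <- .crossp(q2 - q1, q3 - q1) / 2   # area-weighted facet normal
  out <- matrix(0, n_nodes, 3L)
  for (a in 1:3) {
    for (ci in 1:3) {
      acc <- rowsum(an[, ci] / 3, tris[, a])
      ids <- as.integer(rownames(acc))
      out[ids, ci] <- out[ids, ci] + acc
    }
  }
  out
}

# sparse matrix from concatenated triplets
fem_sparse <- function(tr, nrow, ncol) {
  Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(nrow, ncol))
}

fem_cat_triplets <- function(..., row_off = 0L, col_off = 0L) {
  trs <- list(...)
  list(i = unlist(lapply(trs, `[[`, "i")) + row_off,
       j = unlist(lapply(trs, `[[`, "j")) + col_off,
       x = unlist(lapply(trs, `[[`, "x")))
}
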