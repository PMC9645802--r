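#' Geometric measures of a tetrahedral mesh
#'
#' Computes, deterministically for a fixed mesh: tetrahedron volumes and
#' barycenters; for every interior face, the shared-triangle area and the
#' barycenter-to-barycenter distance between the two adjacent tetrahedra
#' (symmetric: both directions use the same area and distance); areas of the
#' tagged surface triangles; and per-vertex lumped membrane areas (one third
#' of each adjacent tagged triangle's area).  These are the geometric inputs
#' of the diffusion rate formula and of the membrane-potential assembly.
#'
#' @param mesh a [tet_mesh()].
#' @return An object of class `mesh_measures` with fields:
#'   `volumes` (m^3), `barycenters` (m), `total_volume`;
#'   neighbour tables as [flat_multimap()]s keyed by 0-based tetrahedron
#'   index: `nb_tet` (neighbour index), `nb_area` (m^2), `nb_dist` (m);
#'   `tri_areas` (m^2, per tagged triangle); `vertex_memb_area` (m^2 per
#'   vertex, unscaled by any patch surface correction).
#' @export
compute_measures <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  vol <- tet_volumes_signed(mesh$vertices, mesh$tets)
  vol <- abs(vol)
  if (any(vol <= 0 | !is.finite(vol))) {
    bad <- which(vol <= 0 | !is.finite(vol))[1]
    stop(sprintf("degenerate tetrahedron %d has zero volume", bad), call. = FALSE)
  }
  m <- nrow(mesh$tets)
  bary <- (mesh$vertices[mesh$tets[, 1], , drop = FALSE] +
           mesh$vertices[mesh$tets[, 2], , drop = FALSE] +
           mesh$vertices[mesh$tets[, 3], , drop = FALSE] +
           mesh$vertices[mesh$tets[, 4], , drop = FALSE]) / 4

  fi <- mesh$faces$interior
  if (nrow(fi)) {
    areas <- triangle_areas(mesh$vertices, mesh$faces$interior_verts)
    dvec <- bary[fi[, 1], , drop = FALSE] - bary[fi[, 2], , drop = FALSE]
    dist <- sqrt(rowSums(dvec^2))
    if (any(areas <= 0) || any(dist <= 0)) {
      stop("degenerate interior face (zero area or coincident barycenters)",
           call. = FALSE)
    }
    keys <- c(unname(fi[, 1]), unname(fi[, 2])) - 1L  # both directions, 0-based
    nb   <- c(unname(fi[, 2]), unname(fi[, 1]))
    nb_tet  <- flat_multimap(keys, nb, n_keys = m)
    nb_area <- flat_multimap(keys, c(areas, areas), n_keys = m)
    nb_dist <- flat_multimap(keys, c(dist, dist), n_keys = m)
  } else {
    nb_tet  <- flat_multimap(integer(0), integer(0), n_keys = m)
    nb_area <- flat_multimap(integer(0), numeric(0), n_keys = m)
    nb_dist <- flat_multimap(integer(0), numeric(0), n_keys = m)
  }

  tri_areas <- triangle_areas(mesh$vertices, mesh$tris)
  vma <- numeric(nrow(mesh$vertices))
  if (nrow(mesh$tris)) {
    third <- rep(tri_areas / 3, 3L)
    idx <- c(mesh$tris[, 1], mesh$tris[, 2], mesh$tris[, 3])
    acc <- rowsum(third, idx)
    vma[as.integer(rownames(acc))] <- acc[, 1]
  }

  structure(list(
    volumes = vol, barycenters = bary, total_volume = sum(vol),
    nb_tet = nb_tet, nb_area = nb_area, nb_dist = nb_dist,
    tri_areas = tri_areas, vertex_memb_area = vma
  ), class = "mesh_measures")
}

#' @export
print.mesh_measures <- function(x, ...) {
  cat(sprintf("<mesh_measures> %d tets, total volume %.6g m^3, %d tri areas\n",
              length(x$volumes), x$total_volume, length(x$tri_areas)))
  invisible(x)
}
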