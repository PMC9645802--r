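#' Tetrahedral mesh container
#'
#' A `tet_mesh` holds vertices (SI metres), tetrahedra (4 vertex indices
#' each), an optional list of tagged surface triangles, and physical tags:
#' every tetrahedron carries exactly one compartment tag and every tagged
#' triangle exactly one patch tag.  Compartments host volume chemistry,
#' patches host surface chemistry and membranes.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z (m).
#' @param tets integer matrix, one row per tetrahedron, 4 vertex indices
#'   (1-based).
#' @param tris integer matrix (possibly 0-row), tagged surface triangles,
#'   3 vertex indices per row.
#' @param tet_tags character vector of compartment tags, one per tetrahedron.
#' @param tri_tags character vector of patch tags, one per triangle in `tris`.
#' @param surface_scale named numeric: per-patch multiplier applied to all
#'   membrane surface densities (capacitance, leak, channel densities).  Used
#'   by the cable generator to correct a polygonal cross-section to the ideal
#'   cylinder (see [generate_cable_mesh()]); defaults to 1 for every patch.
#' @return An object of class `tet_mesh`.  Triangle ownership
#'   (`tri_tet`: up to two adjacent tetrahedra per tagged triangle) is
#'   resolved at construction.
#' @export
tet_mesh <- function(vertices, tets, tris = NULL, tet_tags = NULL,
                     tri_tags = NULL, surface_scale = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  stopifnot(ncol(vertices) == 3)
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  stopifnot(ncol(tets) == 4)
  if (is.null(tris)) tris <- matrix(integer(), 0, 3)
  tris <- as.matrix(tris)
  storage.mode(tris) <- "integer"
  if (nrow(tris)) stopifnot(ncol(tris) == 3)
  if (is.null(tet_tags)) tet_tags <- rep("comp", nrow(tets))
  if (is.null(tri_tags)) tri_tags <- rep("patch", nrow(tris))
  stopifnot(length(tet_tags) == nrow(tets), length(tri_tags) == nrow(tris))
  if (max(tets) > nrow(vertices) || min(tets) < 1L) {
    stop("tetrahedron refers to a vertex outside the vertex table", call. = FALSE)
  }

  mesh <- structure(list(
    vertices = vertices, tets = tets, tris = tris,
    tet_tags = as.character(tet_tags), tri_tags = as.character(tri_tags),
    surface_scale = surface_scale %||% numeric(0)
  ), class = "tet_mesh")
  mesh$faces <- mesh_face_table(tets)
  mesh$tri_tet <- resolve_tri_owners(mesh)
  # default surface scale 1 for any patch not mentioned
  for (p in unique(mesh$tri_tags)) {
    if (is.null(mesh$surface_scale[p]) || is.na(mesh$surface_scale[p])) {
      mesh$surface_scale[p] <- 1
    }
  }
  mesh
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Enumerate the 4 faces of every tetrahedron, match shared faces.
# Returns a list: key (sorted-vertex face key), tet/opp of each face row,
# plus interior pairing (face -> the two adjacent tets) and boundary faces.
mesh_face_table <- function(tets) {
  m <- nrow(tets)
  # face i of a tet omits vertex i; orientation irrelevant here
  fidx <- rbind(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  fv <- rbind(tets[, fidx[1, ], drop = FALSE], tets[, fidx[2, ], drop = FALSE],
              tets[, fidx[3, ], drop = FALSE], tets[, fidx[4, ], drop = FALSE])
  tet_of <- rep.int(seq_len(m), 4L)
  fs <- t(apply(fv, 1L, sort.int))
  key <- paste(fs[, 1], fs[, 2], fs[, 3])
  first <- match(key, key)
  dup <- first != seq_along(key)
  n_owners <- tabulate(first, nbins = length(key))
  if (any(n_owners > 2L)) {
    stop("non-manifold mesh: a triangle is shared by more than 2 tetrahedra",
         call. = FALSE)
  }
  pair_a <- tet_of[first[dup]]
  pair_b <- tet_of[dup]
  interior_key <- key[first[dup]]
  boundary <- which(n_owners == 1L)
  list(
    verts = fs, tet_of = tet_of, key = key,
    interior = cbind(tet_a = pair_a, tet_b = pair_b),
    interior_verts = fs[first[dup], , drop = FALSE],
    boundary_verts = fs[boundary, , drop = FALSE],
    boundary_tet = tet_of[boundary]
  )
}

# For each tagged triangle, find the 1 or 2 adjacent tetrahedra.
resolve_tri_owners <- function(mesh) {
  nt <- nrow(mesh$tris)
  out <- matrix(NA_integer_, nt, 2)
  if (!nt) return(out)
  ts <- t(apply(mesh$tris, 1L, sort.int))
  tkey <- paste(ts[, 1], ts[, 2], ts[, 3])
  f <- mesh$faces
  hit <- match(tkey, f$key)
  if (anyNA(hit)) {
    stop("tagged triangle is not a face of any tetrahedron", call. = FALSE)
  }
  out[, 1] <- f$tet_of[hit]
  dup_pos <- which(duplicated(f$key))          # second occurrence of each face
  hit2 <- match(tkey, f$key[dup_pos])
  has2 <- !is.na(hit2)
  out[has2, 2] <- f$tet_of[dup_pos[hit2[has2]]]
  out
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d vertices, %d tetrahedra, %d tagged triangles\n",
              nrow(x$vertices), nrow(x$tets), nrow(x$tris)))
  cat("  compartments:", paste(unique(x$tet_tags), collapse = ", "), "\n")
  if (nrow(x$tris)) cat("  patches:", paste(unique(x$tri_tags), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a structured box mesh
#'
#' Axis-aligned cuboid of dimensions `dims` (m), subdivided into
#' `resolution` hexahedral cells per axis, each split into 6 tetrahedra by
#' the Kuhn (Freudenthal) decomposition: deterministic, conforming across
#' cells, all volumes positive.
#'
#' @param dims numeric length 3, edge lengths (m).
#' @param resolution integer length 3, cells per axis.
#' @param comp_tag compartment tag for all tetrahedra.
#' @param memb_tag if non-`NULL`, every boundary triangle is tagged with this
#'   patch name.
#' @return A [tet_mesh()].
#' @export
generate_box_mesh <- function(dims, resolution, comp_tag = "comp",
                              memb_tag = NULL) {
  stopifnot(length(dims) == 3, length(resolution) == 3)
  if (any(dims <= 0)) stop("box dimensions must be positive", call. = FALSE)
  resolution <- as.integer(resolution)
  if (any(resolution < 1L)) stop("resolution must be >= 1 per axis", call. = FALSE)
  n <- resolution
  nv <- n + 1L
  xs <- seq(0, dims[1], length.out = nv[1])
  ys <- seq(0, dims[2], length.out = nv[2])
  zs <- seq(0, dims[3], length.out = nv[3])
  vid <- function(i, j, k) i + nv[1] * ((j - 1L) + nv[2] * (k - 1L))
  verts <- cbind(rep(xs, times = nv[2] * nv[3]),
                 rep(rep(ys, each = nv[1]), times = nv[3]),
                 rep(zs, each = nv[1] * nv[2]))
  # Kuhn: each cell split along permutations of unit steps from corner 000
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  ci <- rep(seq_len(n[1]), times = n[2] * n[3])
  cj <- rep(rep(seq_len(n[2]), each = n[1]), times = n[3])
  ck <- rep(seq_len(n[3]), each = n[1] * n[2])
  ncell <- length(ci)
  tets <- matrix(0L, 6L * ncell, 4L)
  step <- diag(3L)
  for (p in seq_len(6L)) {
    s1 <- step[perms[p, 1], ]; s2 <- s1 + step[perms[p, 2], ]
    v0 <- vid(ci, cj, ck)
    v1 <- vid(ci + s1[1], cj + s1[2], ck + s1[3])
    v2 <- vid(ci + s2[1], cj + s2[2], ck + s2[3])
    v3 <- vid(ci + 1L, cj + 1L, ck + 1L)
    tets[seq.int(p, by = 6L, length.out = ncell), ] <- cbind(v0, v1, v2, v3)
  }
  tris <- NULL; tri_tags <- NULL
  ft <- mesh_face_table(tets)
  if (!is.null(memb_tag)) {
    tris <- ft$boundary_verts
    tri_tags <- rep(memb_tag, nrow(tris))
  }
  tet_mesh(verts, tets, tris = tris,
           tet_tags = rep(comp_tag, nrow(tets)), tri_tags = tri_tags)
}

#' Generate a cable (prism) mesh for cylindrical-cable benchmarks
#'
#' A straight prism along z of length `length` whose square cross-section is
#' area-matched to a cylinder of nominal diameter `diameter`: side
#' `sqrt(pi)/2 * diameter`, cross-section area `pi (d/2)^2`.  The whole
#' surface (lateral plus the two end caps) is tagged as the membrane patch
#' and the volume as the compartment.  Because the analytic cable solution
#' assumes a cylindrical membrane, the ratio
#' `rho = (ideal cylinder area pi*d*L + 2 end caps) / (actual mesh surface
#' area)` is recorded as the patch's `surface_scale`; binding multiplies all
#' membrane surface densities by it so total membrane conductance and
#' capacitance per unit length match the ideal cylinder.
#'
#' @param length cable length (m).
#' @param diameter nominal cylinder diameter (m).
#' @param axial_segments number of subdivisions along z.
#' @param cross_segments subdivisions across each lateral axis (default 1).
#' @param comp_tag,memb_tag tags for the volume and the surface.
#' @return A [tet_mesh()] whose `surface_scale[memb_tag]` holds rho.
#' @export
generate_cable_mesh <- function(length, diameter, axial_segments,
                                cross_segments = 1L, comp_tag = "cyto",
                                memb_tag = "memb") {
  stopifnot(length > 0, diameter > 0, axial_segments >= 1)
  side <- sqrt(pi) * diameter / 2
  mesh <- generate_box_mesh(c(side, side, length),
                            c(cross_segments, cross_segments, axial_segments),
                            comp_tag = comp_tag, memb_tag = memb_tag)
  actual_area <- sum(triangle_areas(mesh$vertices, mesh$tris))
  ideal_area <- pi * diameter * length + 2 * pi * (diameter / 2)^2
  mesh$surface_scale[memb_tag] <- ideal_area / actual_area
  mesh
}

triangle_areas <- function(vertices, tris) {
  if (!nrow(tris)) return(numeric(0))
  a <- vertices[tris[, 1], , drop = FALSE]
  b <- vertices[tris[, 2], , drop = FALSE]
  c_ <- vertices[tris[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

tet_volumes_signed <- function(vertices, tets) {
  a <- vertices[tets[, 1], , drop = FALSE]
  b <- vertices[tets[, 2], , drop = FALSE] - a
  c_ <- vertices[tets[, 3], , drop = FALSE] - a
  d <- vertices[tets[, 4], , drop = FALSE] - a
  (b[, 1] * (c_[, 2] * d[, 3] - c_[, 3] * d[, 2]) -
   b[, 2] * (c_[, 1] * d[, 3] - c_[, 3] * d[, 1]) +
   b[, 3] * (c_[, 1] * d[, 2] - c_[, 2] * d[, 1])) / 6
}
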