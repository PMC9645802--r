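#' Read a Gmsh MSH (ASCII v2.2) mesh
#'
#' Parses the `$MeshFormat`, `$PhysicalNames`, `$Nodes` and `$Elements`
#' sections of the MSH 2.2 ASCII format.  Element types 4 (tetrahedron) and
#' 2 (triangle) are imported; the first element tag (the physical group) is
#' resolved to its physical name when a `$PhysicalNames` section is present,
#' otherwise the numeric tag is used verbatim and, if no tags are present at
#' all, a tagless mesh is returned with a warning.  MSH node/element
#' numbering is 1-based and kept; coordinates are multiplied by
#' `unit_scale` (metres per file unit).
#'
#' @param path path to an ASCII `.msh` file.
#' @param unit_scale multiplicative factor converting file coordinates to
#'   metres (default 1: file already in metres).
#' @return A [tet_mesh()].
#' @export
read_msh <- function(path, unit_scale = 1.0) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  sec <- function(name) {
    beg <- match(paste0("$", name), lines)
    end <- match(paste0("$End", name), lines)
    if (is.na(beg) || is.na(end)) return(NULL)
    lines[(beg + 1L):(end - 1L)]
  }
  fmt <- sec("MeshFormat")
  if (is.null(fmt)) stop("not an MSH file (missing $MeshFormat): ", path,
                         call. = FALSE)
  ver <- strsplit(trimws(fmt[1]), "\\s+")[[1]]
  if (!(ver[1] %in% c("2.2")) || ver[2] != "0") {
    stop(sprintf("unsupported MSH version/format '%s %s' (ASCII v2.2 supported)",
                 ver[1], ver[2]), call. = FALSE)
  }

  phys <- sec("PhysicalNames")
  phys_names <- character(0)
  if (!is.null(phys)) {
    n <- as.integer(phys[1])
    if (n > 0) {
      pn <- do.call(rbind, strsplit(phys[1 + seq_len(n)], "\\s+"))
      phys_names <- gsub("\"", "", pn[, 3])
      names(phys_names) <- pn[, 2]            # keyed by physical tag number
    }
  }

  nd <- sec("Nodes")
  if (is.null(nd)) stop("MSH file has no $Nodes section", call. = FALSE)
  nn <- as.integer(nd[1])
  ntab <- matrix(scan(text = nd[1 + seq_len(nn)], quiet = TRUE), ncol = 4,
                 byrow = TRUE)
  verts <- matrix(0, nn, 3)
  verts[ntab[, 1], ] <- ntab[, 2:4] * unit_scale

  el <- sec("Elements")
  if (is.null(el)) stop("MSH file has no $Elements section", call. = FALSE)
  ne <- as.integer(el[1])
  tets <- list(); tet_tags <- list(); tris <- list(); tri_tags <- list()
  other3d <- 0L
  for (ln in el[1 + seq_len(ne)]) {
    v <- scan(text = ln, quiet = TRUE)
    type <- v[2]; ntag <- v[3]
    tags <- if (ntag > 0) v[3 + seq_len(ntag)] else numeric(0)
    nodes <- v[(4 + ntag):length(v)]
    ptag <- if (length(tags)) as.character(tags[1]) else NA_character_
    if (type == 4) {
      tets[[length(tets) + 1L]] <- nodes
      tet_tags[[length(tet_tags) + 1L]] <- ptag
    } else if (type == 2) {
      tris[[length(tris) + 1L]] <- nodes
      tri_tags[[length(tri_tags) + 1L]] <- ptag
    } else if (type %in% c(5, 6, 7)) {       # hexa/prism/pyramid
      other3d <- other3d + 1L
    }
  }
  if (other3d > 0L) {
    stop(sprintf("mesh contains %d non-tetrahedral 3D elements; only tetrahedra are supported",
                 other3d), call. = FALSE)
  }
  if (!length(tets)) stop("MSH file contains no tetrahedra", call. = FALSE)
  resolve <- function(tags) {
    tags <- unlist(tags)
    if (all(is.na(tags))) return(NULL)
    out <- phys_names[tags]
    out[is.na(out)] <- tags[is.na(out)]      # unnamed group: numeric tag as name
    unname(out)
  }
  tet_tags <- resolve(tet_tags)
  if (is.null(tet_tags)) {
    warning("MSH file has no physical groups; returning tagless mesh")
  }
  tri_tags <- if (length(tris)) resolve(tri_tags) else NULL
  tet_mesh(verts,
           do.call(rbind, tets),
           tris = if (length(tris)) do.call(rbind, tris) else NULL,
           tet_tags = tet_tags, tri_tags = tri_tags)
}

#' Write a mesh as Gmsh MSH ASCII v2.2
#'
#' Inverse of [read_msh()]: physical names are emitted for every distinct
#' compartment (dimension 3) and patch (dimension 2) tag, and element
#' numbering is 1-based per the format.
#'
#' @param mesh a [tet_mesh()].
#' @param path output path.
#' @param unit_scale metres per file unit (coordinates are divided by it).
#' @return `path`, invisibly.
#' @export
write_msh <- function(mesh, path, unit_scale = 1.0) {
  comp <- unique(mesh$tet_tags)
  patch <- unique(mesh$tri_tags)
  tag_no <- seq_along(c(patch, comp))
  names(tag_no) <- c(patch, comp)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("$MeshFormat"); w("2.2 0 8"); w("$EndMeshFormat")
  w("$PhysicalNames"); w("%d", length(tag_no))
  for (p in patch) w("2 %d \"%s\"", tag_no[p], p)
  for (p in comp)  w("3 %d \"%s\"", tag_no[p], p)
  w("$EndPhysicalNames")
  w("$Nodes"); w("%d", nrow(mesh$vertices))
  writeLines(paste(seq_len(nrow(mesh$vertices)),
                   mesh$vertices[, 1] / unit_scale,
                   mesh$vertices[, 2] / unit_scale,
                   mesh$vertices[, 3] / unit_scale), con)
  w("$EndNodes")
  ntr <- nrow(mesh$tris); nte <- nrow(mesh$tets)
  w("$Elements"); w("%d", ntr + nte)
  if (ntr) {
    writeLines(paste(seq_len(ntr), 2, 2,
                     tag_no[mesh$tri_tags], tag_no[mesh$tri_tags],
                     mesh$tris[, 1], mesh$tris[, 2], mesh$tris[, 3]), con)
  }
  writeLines(paste(ntr + seq_len(nte), 4, 2,
                   tag_no[mesh$tet_tags], tag_no[mesh$tet_tags],
                   mesh$tets[, 1], mesh$tets[, 2], mesh$tets[, 3],
                   mesh$tets[, 4]), con)
  w("$EndElements")
  invisible(path)
}
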