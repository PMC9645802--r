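#' Partition a mesh across emulated ranks
#'
#' Recursive coordinate bisection on tetrahedron barycenters: at each level
#' the current block is split at the median along its longest axis, so
#' ownership is spatially contiguous and balanced.  `ranks` must be a power
#' of 2 (mirroring the usual power-of-2 core counts of distributed runs);
#' other values are rejected.  Ghost layers are derived from face adjacency:
#' rank r ghosts every non-owned tetrahedron sharing a face with one it owns.
#'
#' The partition emulates a distributed run in a single process: the SSA and
#' diffusion operators loop over ranks, cross-rank diffusion is staged in a
#' delta state and applied only at the synchronization step.
#'
#' @param mesh a [tet_mesh()].
#' @param ranks number of emulated ranks (power of 2, `<=` number of tets).
#' @param measures optional precomputed [compute_measures()] (barycenters).
#' @return An object of class `mesh_partition`: `n_ranks`; `owner` (integer
#'   per tet, ranks numbered 1..R); `ghosts` (list per rank of ghosted tet
#'   indices).
#' @export
partition_mesh <- function(mesh, ranks, measures = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  ranks <- as.integer(ranks)
  if (ranks < 1L) stop("ranks must be >= 1", call. = FALSE)
  m <- nrow(mesh$tets)
  if (ranks > m) stop("more ranks than tetrahedra", call. = FALSE)
  if (bitwAnd(ranks, ranks - 1L) != 0L) {
    stop(sprintf("ranks must be a power of 2 (got %d)", ranks), call. = FALSE)
  }
  if (is.null(measures)) measures <- compute_measures(mesh)
  bary <- measures$barycenters
  owner <- integer(m)
  rcb <- function(idx, lo, hi) {
    if (hi == lo) { owner[idx] <<- lo; return(invisible()) }
    spans <- apply(bary[idx, , drop = FALSE], 2, function(v) diff(range(v)))
    ax <- which.max(spans)
    ord <- idx[order(bary[idx, ax], idx)]    # id tiebreak: deterministic
    half <- length(ord) %/% 2L
    mid <- (lo + hi - 1L) %/% 2L
    rcb(ord[seq_len(half)], lo, mid)
    rcb(ord[(half + 1L):length(ord)], mid + 1L, hi)
  }
  rcb(seq_len(m), 1L, ranks)

  ghosts <- vector("list", ranks)
  fi <- mesh$faces$interior
  for (r in seq_len(ranks)) {
    a_own <- owner[fi[, 1]] == r
    b_own <- owner[fi[, 2]] == r
    g <- c(fi[a_own & !b_own, 2], fi[b_own & !a_own, 1])
    ghosts[[r]] <- sort(unique(g))
  }
  structure(list(n_ranks = ranks, owner = owner, ghosts = ghosts),
            class = "mesh_partition")
}

#' @export
print.mesh_partition <- function(x, ...) {
  cat(sprintf("<mesh_partition> %d ranks, owned: %s\n", x$n_ranks,
              paste(tabulate(x$owner, x$n_ranks), collapse = "/")))
  invisible(x)
}
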