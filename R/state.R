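#' Molecule state
#'
#' Integer molecule counts per (owned tetrahedron, volume species) and per
#' (patch triangle, surface species / channel state), stored as one
#' contiguous vector (doubles holding exact integers; R has no native 64-bit
#' integer, and doubles are exact far beyond the in-scope count range).
#' Counts are nonnegative at every observable point of the core loop.
#'
#' @param bound a [bind_model()] result.
#' @return An environment of class `molecule_state` with field `counts`.
#' @export
molecule_state <- function(bound) {
  M <- new.env(parent = emptyenv())
  M$counts <- numeric(bound$n_state)
  for (blk in bound$init_surf) M$counts[blk[, 1]] <- M$counts[blk[, 1]] + blk[, 2]
  class(M) <- "molecule_state"
  M
}

#' Read a molecule count
#'
#' @param M a [molecule_state()].
#' @param bound the bound model that defined the state layout.
#' @param element an [entity_id()] of kind `"tet"` or `"tri"`.
#' @param species species name (volume species for tets, surface
#'   species/channel state for triangles).
#' @export
mol_count <- function(M, bound, element, species) {
  kind <- id_kind(element)
  if (kind == "tet") {
    idx <- bound$vidx(assert_id(element, "tet"), species)
  } else {
    idx <- bound$sidx(assert_id(element, "tri"), species)
  }
  M$counts[idx]
}

#' Per-species global totals
#'
#' @inheritParams mol_count
#' @return Named numeric: total count per volume and surface species.
#' @export
species_totals <- function(M, bound) {
  n_tet <- bound$n_tet; n_tri <- bound$n_tri
  nv <- length(bound$vol_species); ns <- length(bound$surf_species)
  tv <- if (nv) colSums(matrix(M$counts[seq_len(n_tet * nv)], n_tet, nv)) else numeric(0)
  ts <- if (ns) colSums(matrix(M$counts[n_tet * nv + seq_len(n_tri * ns)],
                               n_tri, ns)) else numeric(0)
  stats::setNames(c(tv, ts), c(bound$vol_species, bound$surf_species))
}

#' Delta molecule state
#'
#' Staged signed count changes, keyed by destination rank: the single-process
#' emulation of the cross-rank exchange.  Diffusion writes destinations here;
#' [apply_delta()] flushes all buffers into the molecule state in one
#' synchronization step, so no cross-rank mutation happens mid-window.
#'
#' @param n_state state-vector length.
#' @param n_ranks number of emulated ranks.
#' @return An environment of class `delta_state`: per-rank dense buffers
#'   `buf` and touched-index lists `touched`.
#' @export
delta_state <- function(n_state, n_ranks) {
  dM <- new.env(parent = emptyenv())
  dM$buf <- lapply(seq_len(n_ranks), function(i) numeric(n_state))
  dM$touched <- lapply(seq_len(n_ranks), function(i) integer(0))
  class(dM) <- "delta_state"
  dM
}

# Stage deltas destined for rank r (internal hot path).  Duplicate indices
# in one call are aggregated before accumulation.
delta_stage <- function(dM, r, idx, d) {
  if (anyDuplicated(idx)) {
    agg <- rowsum(as.numeric(d), idx)
    idx <- as.integer(rownames(agg))
    d <- agg[, 1]
  }
  dM$buf[[r]][idx] <- dM$buf[[r]][idx] + d
  dM$touched[[r]] <- c(dM$touched[[r]], idx)
}

#' Apply a delta state to a molecule state (synchronization step)
#'
#' Flushes all per-rank buffers into `M`.  When the deltas sum to zero per
#' species (as diffusion deltas do: diffusion moves molecules, never creates
#' them) per-species global totals are unchanged.  A count that would go
#' negative is an operator bug and raises an error naming the state index.
#'
#' @param M a [molecule_state()].
#' @param dM a [delta_state()].
#' @return Integer vector of distinct touched state indices, invisibly.
#' @export
apply_delta <- function(M, dM) {
  all_touched <- integer(0)
  for (r in seq_along(dM$buf)) {
    tch <- dM$touched[[r]]
    if (!length(tch)) next
    tch <- unique(tch)
    M$counts[tch] <- M$counts[tch] + dM$buf[[r]][tch]
    dM$buf[[r]][tch] <- 0
    dM$touched[[r]] <- integer(0)
    all_touched <- c(all_touched, tch)
  }
  all_touched <- unique(all_touched)
  if (length(all_touched) && any(M$counts[all_touched] < 0)) {
    bad <- all_touched[which(M$counts[all_touched] < 0)[1]]
    stop(sprintf("molecule count went negative at state index %d (operator bug)",
                 bad), call. = FALSE)
  }
  invisible(all_touched)
}

#' Snapshot a molecule state to a plain data frame
#'
#' Debug/inspection dump: one row per nonzero (element, species) count.
#'
#' @inheritParams mol_count
#' @return A tibble with columns `element_kind`, `element`, `species`,
#'   `count`.
#' @export
state_snapshot <- function(M, bound) {
  nz <- which(M$counts != 0)
  n_vol <- bound$n_tet * length(bound$vol_species)
  is_vol <- nz <= n_vol
  elem <- ifelse(is_vol, (nz - 1L) %% bound$n_tet + 1L,
                 (nz - n_vol - 1L) %% bound$n_tri + 1L)
  spi <- ifelse(is_vol, (nz - 1L) %/% bound$n_tet + 1L,
                (nz - n_vol - 1L) %/% bound$n_tri + 1L)
  spn <- ifelse(is_vol, bound$vol_species[spi], bound$surf_species[spi])
  tibble::tibble(element_kind = ifelse(is_vol, "tet", "tri"),
                 element = as.integer(elem), species = spn,
                 count = M$counts[nz])
}
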