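#' Per-tetrahedron diffusion rates
#'
#' For each diffusive species and tetrahedron i with neighbour k across a
#' shared face of area `A_k` at barycenter distance `h_k`:
#' `d_k = D A_k / (V_i h_k)` (s^-1), and `d_tot = sum(d_k)`.  Construction
#' is symmetric (both directions use the same `A_k`, `h_k`); boundary faces
#' contribute nothing (sealed, reflective boundaries); flux is restricted to
#' neighbour pairs inside the rule's compartment.
#'
#' @param measures a [compute_measures()] result.
#' @param rules list of [diffusion_rule()]s.
#' @param bound a [bind_model()] result (tag and state layout resolution).
#' @return An object of class `diffusion_rates`: per diffusive species a
#'   slot table for vectorized redistribution, plus `d_tot` per (tet,
#'   species) and the global maximum total rate.
#' @export
compute_diffusion_rates <- function(measures, rules, bound) {
  mesh <- bound$mesh
  n_tet <- bound$n_tet
  species <- list()
  max_dtot <- 0
  for (rule in rules) {
    if (rule$D <= 0) next
    tets_in <- mesh$tet_tags == rule$compartment
    # gather neighbour arrays from the measures multimaps
    lo <- measures$nb_tet$a2ab[seq_len(n_tet)]
    hi <- measures$nb_tet$a2ab[seq_len(n_tet) + 1L]
    deg <- hi - lo
    src <- rep.int(seq_len(n_tet), deg)
    nb  <- measures$nb_tet$ab2c
    ar  <- measures$nb_area$ab2c
    di  <- measures$nb_dist$ab2c
    keep <- tets_in[src] & tets_in[nb]
    src <- src[keep]; nb <- nb[keep]; ar <- ar[keep]; di <- di[keep]
    d_k <- rule$D * ar / (measures$volumes[src] * di)
    d_tot <- numeric(n_tet)
    if (length(src)) {
      acc <- rowsum(d_k, src)
      d_tot[as.integer(rownames(acc))] <- acc[, 1]
    }
    max_dtot <- max(max_dtot, d_tot)
    # slot tables: k-th neighbour of each source tet, for sequential
    # binomial splitting of the leavers
    ord <- order(src)
    src <- src[ord]; nb <- nb[ord]; d_k <- d_k[ord]
    pos_in_src <- sequence(rle(src)$lengths)
    slots <- list()
    if (length(src)) {
      degs <- tabulate(src, n_tet)
      for (k in seq_len(max(pos_in_src))) {
        sel <- pos_in_src == k
        slots[[k]] <- list(
          src = src[sel],
          src_idx = bound$vidx(src[sel], rule$species),
          dst_idx = bound$vidx(nb[sel], rule$species),
          dst_tet = nb[sel],
          d_k = d_k[sel],
          is_last = degs[src[sel]] == k
        )
      }
    }
    species[[rule$species]] <- list(
      species = rule$species, D = rule$D, compartment = rule$compartment,
      d_tot = d_tot, slots = slots,
      state_idx = bound$vidx(seq_len(n_tet), rule$species)
    )
  }
  structure(list(species = species, max_dtot = max_dtot),
            class = "diffusion_rates")
}

#' Choose the reaction-diffusion window length
#'
#' `dt_rd = min(efield_dt, alpha / max d_tot)` over all (tetrahedron,
#' species); with no diffusive species the window equals the EField window.
#' `alpha` is a dimensionless safety factor (default 1).
#'
#' @param rates a [compute_diffusion_rates()] result.
#' @param efield_dt EField window (s); also the window with no diffusion.
#' @param alpha safety factor.
#' @return The window length `dt_rd` (s).
#' @export
select_rd_dt <- function(rates, efield_dt, alpha = 1.0) {
  stopifnot(efield_dt > 0, alpha > 0)
  if (!length(rates$species) || rates$max_dtot <= 0) return(efield_dt)
  min(efield_dt, alpha / rates$max_dtot)
}

# One diffusion window over all ranks: sample leavers per (owned tet,
# species) from Binomial(n, 1 - exp(-d_tot dt)), split them multinomially
# over the neighbours with probabilities d_k/d_tot (sequential binomial
# splitting), stage destination increments in the delta state keyed by the
# destination's owner, then synchronize and reprice affected processes.
# Exactly conservative: leavers removed from sources equal additions staged.
diffuse_window <- function(sim, dt) {
  rates <- sim$diff_rates
  if (!length(rates$species)) return(invisible(integer(0)))
  bound <- sim$bound
  owner <- bound$partition$owner
  M <- sim$M
  dM <- sim$dM
  touched_src <- integer(0)
  for (r in seq_len(bound$partition$n_ranks)) {
    with_stream(sim, r, {
      for (sp in rates$species) {
        n <- M$counts[sp$state_idx]
        p_leave <- 1 - exp(-sp$d_tot * dt)
        cand <- which(n > 0 & p_leave > 0 & owner == r)
        if (!length(cand)) next
        leav <- stats::rbinom(length(cand), n[cand], p_leave[cand])
        act <- leav > 0
        if (!any(act)) next
        cand <- cand[act]; leav <- leav[act]
        M$counts[sp$state_idx[cand]] <- M$counts[sp$state_idx[cand]] - leav
        touched_src <- c(touched_src, sp$state_idx[cand])
        remaining <- leav
        rem_rate <- sp$d_tot[cand]
        for (slot in sp$slots) {
          m <- match(slot$src, cand)
          sl <- which(!is.na(m))
          if (!length(sl)) next
          pos <- m[sl]
          nk <- integer(length(sl))
          live <- which(remaining[pos] > 0)
          if (length(live)) {
            sll <- sl[live]; posl <- pos[live]
            rem <- remaining[posl]
            pk <- pmin(pmax(slot$d_k[sll] / rem_rate[posl], 0), 1)
            draw <- integer(length(sll))
            lastm <- slot$is_last[sll]
            draw[lastm] <- rem[lastm]
            if (any(!lastm)) {
              draw[!lastm] <- stats::rbinom(sum(!lastm), rem[!lastm],
                                            pk[!lastm])
            }
            nk[live] <- draw
            dst_rank <- owner[slot$dst_tet[sll]]
            nz <- draw > 0
            for (rr in unique(dst_rank[nz])) {
              ii <- nz & dst_rank == rr
              delta_stage(dM, rr, slot$dst_idx[sll[ii]], draw[ii])
            }
          }
          remaining[pos] <- remaining[pos] - nk
          rem_rate[pos] <- rem_rate[pos] - slot$d_k[sl]
        }
        if (any(remaining != 0)) {
          stop("diffusion split left unassigned molecules (internal error)",
               call. = FALSE)
        }
      }
    })
  }
  # synchronization step: apply all staged deltas at once
  touched_dst <- apply_delta(M, dM)
  changed <- unique(c(touched_src, touched_dst))
  # update propensities affected by the moved molecules
  if (length(changed) && sim$bound$n_proc) {
    rm <- sim$dep$reac_map
    lo <- rm$a2ab[changed]; hi <- rm$a2ab[changed + 1L]
    aff <- unique(rm$ab2c[sequence(hi - lo, from = lo + 1L)])
    if (length(aff)) {
      by_rank <- sim$rank_of_proc[aff]
      for (r in unique(by_rank)) {
        with_stream(sim, r, ssa_reprice(sim, aff[by_rank == r], sim$t))
      }
    }
  }
  invisible(changed)
}
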