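#' Create a simulation
#'
#' Instantiates state (molecule counts, kinetic-process queues, voltage) for
#' a bound model, ready for [run()].  One RNG stream is kept per emulated
#' rank, seeded `seed + rank - 1`; initial molecule placement draws from the
#' first stream.  Initial volume counts are distributed over each
#' compartment's tetrahedra by a volume-weighted multinomial (spatially
#' uniform placement).
#'
#' @param bound a [bind_model()] result.
#' @param seed integer seed.
#' @param efield_dt EField window length (s); required when the model has a
#'   membrane and no `fixed_voltage`.
#' @param alpha_rd safety factor for the reaction-diffusion window (the
#'   window is `min(efield_dt, alpha_rd / max total diffusion rate)`).
#' @param use_components independent-component optimization: schedule each
#'   weakly connected dependency-graph component with its own queue
#'   (default off).
#' @param operator `"nrm"` (Gibson-Bruck next-reaction method, default) or
#'   `"direct"` (direct-method reference operator).
#' @param v_init initial potential (V); defaults to the membrane leak
#'   reversal.
#' @return An environment of class `tet_simulation`.
#' @export
simulation <- function(bound, seed = 1L, efield_dt = NULL, alpha_rd = 1.0,
                       use_components = FALSE,
                       operator = c("nrm", "direct"), v_init = NULL) {
  stopifnot(inherits(bound, "bound_model"))
  operator <- match.arg(operator)
  sim <- new.env(parent = emptyenv())
  sim$bound <- bound
  sim$t <- 0
  sim$ef_index <- 0L
  sim$rd_index <- 0L
  sim$event_count <- 0L
  sim$window_count <- 0L
  sim$seed <- as.integer(seed)
  sim$operator <- operator
  sim$hook <- NULL
  sim$event_log <- NULL

  n_ranks <- bound$partition$n_ranks
  sim$rngs <- vector("list", n_ranks)
  for (r in seq_len(n_ranks)) {
    set.seed(sim$seed + r - 1L)
    sim$rngs[[r]] <- .Random.seed
  }

  # --- molecule state ----------------------------------------------------
  sim$M <- molecule_state(bound)
  with_stream(sim, 1L, {
    for (tag in names(bound$model$initial)) {
      tets <- which(bound$mesh$tet_tags == tag)
      w <- bound$measures$volumes[tets]
      for (sp in names(bound$model$initial[[tag]])) {
        n <- bound$model$initial[[tag]][[sp]]
        if (n <= 0) next
        alloc <- as.numeric(stats::rmultinom(1, n, w / sum(w)))
        idx <- bound$vidx(tets, sp)
        sim$M$counts[idx] <- sim$M$counts[idx] + alloc
      }
    }
  })
  sim$dM <- delta_state(bound$n_state, n_ranks)

  # --- diffusion ---------------------------------------------------------
  sim$diff_rates <- compute_diffusion_rates(bound$measures,
                                            bound$model$diffusion, bound)

  # --- voltage -----------------------------------------------------------
  sim$has_efield <- length(bound$membranes) > 0 &&
    is.null(bound$model$fixed_voltage)
  if (sim$has_efield) {
    if (is.null(efield_dt)) {
      stop("efield_dt is required for a model with a membrane potential solve",
           call. = FALSE)
    }
    sim$V <- assemble_efield_system(bound)
    if (!is.null(v_init)) sim$V$v[] <- v_init
  } else {
    sim$V <- NULL
  }
  sim$efield_dt <- efield_dt
  # the RD window: min(efield_dt, alpha / max total diffusion rate); with
  # no EField the window is bounded by the diffusion limit alone (and a
  # run span with no diffusion either is a single window)
  sim$dt_rd <- if (!is.null(efield_dt)) {
    select_rd_dt(sim$diff_rates, efield_dt, alpha_rd)
  } else if (length(sim$diff_rates$species) && sim$diff_rates$max_dtot > 0) {
    alpha_rd / sim$diff_rates$max_dtot
  } else {
    NULL
  }
  sim$alpha_rd <- alpha_rd

  # --- kinetic-process state --------------------------------------------
  sim$ccur <- bound$procs$cbase
  sim$a <- numeric(bound$n_proc)
  sim$tnext <- rep(Inf, bound$n_proc)
  sim$hpos <- integer(bound$n_proc)
  if (bound$n_proc > 0L) {
    sim$dep <- build_dependency_graph(bound)
    # rank of a process: owner of its tetrahedron (inner tetrahedron for
    # surface-located processes)
    elem_tet <- bound$procs$elem
    tri_sel <- which(bound$procs$is_tri)
    if (length(tri_sel)) {
      elem_tet[tri_sel] <- bound$mesh$tri_tet[bound$procs$elem[tri_sel], 1]
    }
    sim$rank_of_proc <- bound$partition$owner[elem_tet]
    if (use_components) {
      comp <- split_components(sim$dep)
      gkey <- paste(sim$rank_of_proc, comp)
    } else {
      gkey <- as.character(sim$rank_of_proc)
    }
    ug <- unique(gkey)
    sim$group_of <- match(gkey, ug)
    sim$groups <- lapply(seq_along(ug), function(g)
      new_group(which(sim$group_of == g),
                sim$rank_of_proc[which(sim$group_of == g)[1]]))
    # voltage-dependent coefficient groups, one per shared rate function
    vd <- which(bound$procs$vdep)
    sim$vdep_groups <- list()
    if (length(vd)) {
      lab <- bound$procs$label[vd]
      for (l in unique(lab)) {
        sel <- vd[lab == l]
        sim$vdep_groups[[l]] <- list(procs = sel,
                                     fn = bound$procs$fn[[sel[1]]],
                                     vtri = bound$procs$vtri[sel])
      }
      refresh_vdep(sim, reprice = FALSE)
    }
    # initial propensities and next-fire times, per rank stream
    sim$a <- compute_propensity(bound, sim$M$counts, sim$ccur)
    for (r in seq_len(n_ranks)) {
      mine <- which(sim$rank_of_proc == r)
      with_stream(sim, r, {
        pos <- sim$a[mine] > 0
        sim$tnext[mine[pos]] <- stats::rexp(sum(pos)) / sim$a[mine[pos]]
        sim$tnext[mine[!pos]] <- Inf
      })
    }
    for (h in sim$groups) heap_build(sim, h)
  } else {
    sim$dep <- NULL
    sim$groups <- list()
    sim$group_of <- integer(0)
    sim$rank_of_proc <- integer(0)
    sim$vdep_groups <- list()
  }
  sim$use_components <- use_components
  class(sim) <- "tet_simulation"
  sim
}

# Swap in rank r's RNG stream, evaluate, swap out.
with_stream <- function(sim, r, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", sim$rngs[[r]], globalenv())
  on.exit({
    sim$rngs[[r]] <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  eval.parent(substitute(expr))
}

# Refresh voltage-dependent per-event coefficients at the current voltage
# (start of each EField window; voltage is frozen in between).
refresh_vdep <- function(sim, reprice = TRUE) {
  if (!length(sim$vdep_groups)) return(invisible())
  vtri_all <- if (!is.null(sim$V)) tri_voltage(sim$V)
              else rep(sim$bound$model$fixed_voltage %||% 0,
                       sim$bound$n_tri)
  touched <- integer(0)
  for (g in sim$vdep_groups) {
    sim$ccur[g$procs] <- sim$bound$procs$cbase[g$procs] * g$fn(vtri_all[g$vtri])
    touched <- c(touched, g$procs)
  }
  if (reprice) {
    by_rank <- sim$rank_of_proc[touched]
    for (r in unique(by_rank)) {
      with_stream(sim, r, ssa_reprice(sim, touched[by_rank == r], sim$t))
    }
  }
  invisible()
}

#' Advance a simulation to a target time
#'
#' The nested window loop: the span up to `t_end` is divided into EField
#' windows (`efield_dt`), each subdivided into reaction-diffusion windows
#' (`dt_rd`).  Within each RD window the SSA operator applies kinetic events
#' until the window end, then the diffusion operator stages, synchronizes
#' and applies molecule movements; at each EField window end the voltage
#' state advances by one implicit step.  Voltage-dependent propensities are
#' refreshed at the start of every EField window.  Window edges are computed
#' from integer window indices (no floating-point drift); trailing partial
#' windows are truncated so the state time lands exactly on `t_end`, and
#' control returns to the caller for data inquiry.
#'
#' @param sim a [simulation()].
#' @param t_end target time (s), `>=` current state time.
#' @return `sim`, invisibly (state advanced in place).
#' @export
run <- function(sim, t_end) {
  stopifnot(inherits(sim, "tet_simulation"))
  eps <- 1e-12 * max(1, abs(t_end))
  if (t_end < sim$t - eps) {
    stop(sprintf("t_end (%g) is before current state time (%g)", t_end, sim$t),
         call. = FALSE)
  }
  efdt <- if (sim$has_efield) sim$efield_dt else NULL
  repeat {
    if (sim$t >= t_end - eps) break
    if (is.null(efdt)) {
      # no EField: the EField window equals the whole requested span
      run_rd_span(sim, t_end)
      sim$t <- t_end
      break
    }
    ef_end <- (sim$ef_index + 1L) * efdt
    t_stop <- min(ef_end, t_end)
    run_rd_span(sim, t_stop)
    sim$t <- t_stop
    if (t_stop >= ef_end - eps) {
      if (!is.null(sim$hook)) sim$hook("efield", sim$t)
      efield_step(sim$V, sim$M$counts, efdt)
      sim$ef_index <- sim$ef_index + 1L
      sim$rd_index <- 0L
      if (length(sim$vdep_groups)) refresh_vdep(sim)
    }
  }
  invisible(sim)
}

# Run the RD windows of the current EField window up to t_stop.
run_rd_span <- function(sim, t_stop) {
  eps <- 1e-12 * max(1, abs(t_stop))
  efdt <- if (sim$has_efield) sim$efield_dt else NULL
  ef_start <- if (is.null(efdt)) 0 else sim$ef_index * efdt
  dt_rd <- sim$dt_rd
  if (sim$rd_index == 0L && sim$t <= ef_start + eps &&
      length(sim$vdep_groups) && is.null(sim$V)) {
    refresh_vdep(sim)     # fixed-voltage models: coefficients set once
  }
  repeat {
    if (sim$t >= t_stop - eps) break
    rd_end <- if (is.null(dt_rd)) t_stop
              else min(ef_start + (sim$rd_index + 1L) * dt_rd, t_stop)
    # SSA phase, per scheduling group, each rank on its own stream
    if (!is.null(sim$hook)) sim$hook("ssa", sim$t)
    for (h in sim$groups) {
      with_stream(sim, h$rank, {
        if (sim$operator == "direct") {
          ssa_run_group_direct(sim, h, sim$t, rd_end)
        } else {
          ssa_run_group(sim, h, rd_end)
        }
      })
    }
    # diffusion phase + synchronization
    if (length(sim$diff_rates$species)) {
      if (!is.null(sim$hook)) sim$hook("diffusion", sim$t)
      diffuse_window(sim, rd_end - sim$t)
      if (!is.null(sim$hook)) sim$hook("sync", rd_end)
    }
    sim$t <- rd_end
    sim$window_count <- sim$window_count + 1L
    if (!is.null(dt_rd) &&
        rd_end >= ef_start + (sim$rd_index + 1L) * dt_rd - eps) {
      sim$rd_index <- sim$rd_index + 1L
    }
  }
  invisible(sim)
}

#' Run with periodic recording
#'
#' Loops [run()] over recording intervals (recording happens only between
#' run calls, when the caller holds control), collecting voltage probes
#' and/or per-species totals.
#'
#' @param sim a [simulation()].
#' @param t_end end time (s).
#' @param record_dt recording interval (s).
#' @param probes named list of coordinates (each length 3, m) or
#'   vertex [entity_id()]s whose potential is recorded.
#' @param species character vector of species whose global totals are
#'   recorded.
#' @return A tibble with `time_s`, one column per probe (volts), one per
#'   species (counts).
#' @export
run_record <- function(sim, t_end, record_dt, probes = list(),
                       species = character(0)) {
  pverts <- vapply(probes, function(p) {
    if (inherits(p, "entity_id")) assert_id(p, "vertex")
    else id_value(resolve_vertex(sim$bound$mesh, p))
  }, integer(1))
  nrec <- floor((t_end - sim$t) / record_dt + 1e-9) + 1L
  times <- sim$t + (seq_len(nrec) - 1L) * record_dt
  out <- matrix(NA_real_, nrec, length(probes) + length(species))
  colnames(out) <- c(names(probes), species)
  tot_names <- c(sim$bound$vol_species, sim$bound$surf_species)
  for (i in seq_len(nrec)) {
    run(sim, times[i])
    if (length(probes)) out[i, seq_along(probes)] <- sim$V$v[pverts]
    if (length(species)) {
      tots <- species_totals(sim$M, sim$bound)
      out[i, length(probes) + seq_along(species)] <- tots[species]
    }
  }
  tibble::as_tibble(cbind(data.frame(time_s = times), as.data.frame(out)))
}

#' @export
print.tet_simulation <- function(x, ...) {
  cat(sprintf("<tet_simulation> t = %g s, %d kinetic processes, %d events applied\n",
              x$t, x$bound$n_proc, x$event_count))
  cat(sprintf("  ranks: %d, operator: %s, efield: %s\n",
              x$bound$partition$n_ranks, x$operator,
              if (x$has_efield) sprintf("dt = %g s", x$efield_dt) else "off"))
  invisible(x)
}
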