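#' Mass-action propensity of kinetic processes
#'
#' `a = c n` for first order, `a = c n_A n_B` for two distinct reactants,
#' `a = c n (n - 1) / 2` for a symmetric pair, `a = c` for zero-order
#' (outer-driven GHK influx).  Zero counts give `a = 0`.
#'
#' @param bound a [bind_model()] result.
#' @param counts molecule-count vector.
#' @param ccur current per-event coefficient vector (voltage-dependent
#'   coefficients refreshed elsewhere).
#' @param procs integer vector of process ids (default all).
#' @return Propensities (s^-1), parallel to `procs`.
#' @export
compute_propensity <- function(bound, counts, ccur = bound$procs$cbase,
                               procs = seq_len(bound$n_proc)) {
  r1 <- bound$procs$r1[procs]
  a <- ccur[procs]
  has1 <- r1 > 0L
  if (any(has1)) {
    n1 <- counts[r1[has1]]
    s1 <- bound$procs$s1[procs][has1]
    f <- ifelse(s1 == 2L, n1 * (n1 - 1) / 2, n1)
    a[has1] <- a[has1] * f
  }
  r2 <- bound$procs$r2[procs]
  has2 <- r2 > 0L
  if (any(has2)) a[has2] <- a[has2] * counts[r2[has2]]
  pmax(a, 0)
}

#' Build the kinetic-process dependency graph
#'
#' Directed edge p -> q whenever an occurrence of p changes a molecule count
#' entering q's propensity, i.e. the state indices p writes intersect q's
#' reactant indices.  Includes p -> p when p changes its own reactants.
#'
#' @param bound a [bind_model()] result.
#' @return An object of class `dependency_graph`: a [flat_multimap()]
#'   `edges` (0-based process key -> dependent process ids) plus the
#'   reverse reactant map and the edge count.
#' @export
build_dependency_graph <- function(bound) {
  n <- bound$n_proc
  # reverse map: state index -> processes with that index as a reactant
  reac <- bound$procs$reactants
  lens <- lengths(reac)
  rvals <- rep.int(seq_len(n), lens)
  rkeys <- unlist(reac, use.names = FALSE)
  reac_map <- flat_multimap(if (length(rkeys)) rkeys - 1L else integer(0),
                            rvals, n_keys = bound$n_state)
  deps <- vector("list", n)
  for (p in seq_len(n)) {
    ch <- bound$procs$eff[[p]][, 1]
    lo <- reac_map$a2ab[ch]; hi <- reac_map$a2ab[ch + 1L]
    qs <- unique(reac_map$ab2c[sequence(hi - lo, from = lo + 1L)])
    deps[[p]] <- sort(qs)
  }
  lens <- lengths(deps)
  edges <- flat_multimap(rep.int(seq_len(n) - 1L, lens),
                         unlist(deps, use.names = FALSE), n_keys = n)
  structure(list(edges = edges, n_proc = n, reac_map = reac_map,
                 n_edges = sum(lens)),
            class = "dependency_graph")
}

#' @export
print.dependency_graph <- function(x, ...) {
  cat(sprintf("<dependency_graph> %d processes, %d edges\n", x$n_proc,
              x$n_edges))
  invisible(x)
}

#' Split a dependency graph into independent components
#'
#' Weakly connected components; each process belongs to exactly one.  Within
#' a reaction-diffusion window, components do not interact and can each be
#' exhausted by an independent SSA pass.
#'
#' @param graph a [build_dependency_graph()] result.
#' @return Integer vector: component id (1-based) per process.
#' @export
split_components <- function(graph) {
  n <- graph$n_proc
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (p in seq_len(n)) {
    lo <- graph$edges$a2ab[p]; hi <- graph$edges$a2ab[p + 1L]
    if (hi == lo) next
    for (q in graph$edges$ab2c[(lo + 1L):hi]) {
      rp <- find(p); rq <- find(q)
      if (rp != rq) parent[max(rp, rq)] <- min(rp, rq)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# ---------------------------------------------------------------------------
# Indexed binary min-heap over (absolute next-fire time, process id): the
# next-reaction-method priority queue.  One heap per scheduling group (per
# rank by default, or per rank x dependency component when the
# independent-component optimization is on).  Heap arrays live in the group
# environment; the position of each process inside its group's heap lives in
# sim$hpos.  All mutation is via environment bindings so vectors are updated
# in place.  Ties are broken by process id for determinism.

heap_less <- function(h, i, j) {
  (h$ht[i] < h$ht[j]) || (h$ht[i] == h$ht[j] && h$hp[i] < h$hp[j])
}

heap_swap <- function(sim, h, i, j) {
  tp <- h$hp[i]; h$hp[i] <- h$hp[j]; h$hp[j] <- tp
  tt <- h$ht[i]; h$ht[i] <- h$ht[j]; h$ht[j] <- tt
  sim$hpos[h$hp[i]] <- i
  sim$hpos[h$hp[j]] <- j
}

heap_sift_up <- function(sim, h, i) {
  while (i > 1L) {
    par <- i %/% 2L
    if (heap_less(h, i, par)) { heap_swap(sim, h, i, par); i <- par }
    else break
  }
}

heap_sift_down <- function(sim, h, i) {
  n <- h$n
  repeat {
    l <- 2L * i
    if (l > n) break
    sm <- if (l < n && heap_less(h, l + 1L, l)) l + 1L else l
    if (heap_less(h, sm, i)) { heap_swap(sim, h, i, sm); i <- sm }
    else break
  }
}

heap_update <- function(sim, h, p, tnew) {
  i <- sim$hpos[p]
  told <- h$ht[i]
  h$ht[i] <- tnew
  if (tnew < told) heap_sift_up(sim, h, i) else heap_sift_down(sim, h, i)
}

# Rebuild a group's heap from the global next-time vector.  A sorted array
# satisfies the heap invariant, so a single order() call suffices.
heap_build <- function(sim, h) {
  procs <- h$procs
  ord <- order(sim$tnext[procs], procs)
  h$hp <- procs[ord]
  h$ht <- sim$tnext[procs][ord]
  h$n <- length(procs)
  sim$hpos[h$hp] <- seq_len(h$n)
}

new_group <- function(procs, rank) {
  h <- new.env(parent = emptyenv())
  h$procs <- as.integer(procs)
  h$rank <- rank
  h$hp <- integer(0); h$ht <- numeric(0); h$n <- 0L
  h
}

# ---------------------------------------------------------------------------
# SSA window: exhaust one scheduling group up to t_end under NRM semantics.
# Events with occurrence time <= t_end are applied in nondecreasing order;
# times already drawn beyond t_end persist in the queue (valid under
# absolute-time NRM; no rejection-redraw).  Returns applied event count.
#
# Hot path: all state vectors are extracted to locals and written back at
# the end (single-element writes on environment bindings copy the whole
# vector each time; locals are modified in place).  This is sound because
# dependency edges never leave the element (or its inner tetrahedron), so
# every dependent process belongs to this same scheduling group.
ssa_run_group <- function(sim, h, t_end) {
  bound <- sim$bound
  M <- sim$M
  eff_all <- bound$procs$eff
  dep_a2ab <- sim$dep$edges$a2ab
  dep_ab2c <- sim$dep$edges$ab2c
  r1v <- bound$procs$r1; s1v <- bound$procs$s1; r2v <- bound$procs$r2
  ccur <- sim$ccur
  labels <- bound$procs$label
  log_events <- !is.null(sim$event_log)
  rexp <- stats::rexp

  counts <- M$counts
  a <- sim$a
  tnext <- sim$tnext
  hpos <- sim$hpos
  ht <- h$ht; hp <- h$hp; hn <- h$n
  n_events <- 0L

  # inline scalar propensity
  prop1 <- function(q) {
    aa <- ccur[q]
    r1 <- r1v[q]
    if (r1 > 0L) {
      n1 <- counts[r1]
      aa <- if (s1v[q] == 2L) aa * n1 * (n1 - 1) / 2 else aa * n1
    }
    r2 <- r2v[q]
    if (r2 > 0L) aa <- aa * counts[r2]
    if (aa > 0) aa else 0
  }

  repeat {
    if (hn == 0L) break
    t_ev <- ht[1]
    if (t_ev > t_end) break
    p <- hp[1]
    eff <- eff_all[[p]]
    ix <- eff[, 1]
    newc <- counts[ix] + eff[, 2]
    if (any(newc < 0)) {
      stop(sprintf("negative count after event of process %d (%s)", p,
                   labels[p]), call. = FALSE)
    }
    counts[ix] <- newc
    n_events <- n_events + 1L
    lo <- dep_a2ab[p]; hi <- dep_a2ab[p + 1L]
    k <- lo
    while (k < hi) {
      k <- k + 1L
      q <- dep_ab2c[k]
      ao <- a[q]
      an <- prop1(q)
      if (q == p) { a[q] <- an; next }       # fired proc handled below
      if (an == ao) next
      a[q] <- an
      tq <- if (an <= 0) Inf
            else if (ao <= 0 || tnext[q] == Inf) t_ev + rexp(1L) / an
            else t_ev + (ao / an) * (tnext[q] - t_ev)
      tnext[q] <- tq
      # heap position update (sift up or down from current position)
      i <- hpos[q]
      ht[i] <- tq
      repeat {   # sift up
        if (i <= 1L) break
        par <- i %/% 2L
        if (ht[i] < ht[par] || (ht[i] == ht[par] && hp[i] < hp[par])) {
          tt <- ht[i]; ht[i] <- ht[par]; ht[par] <- tt
          tp2 <- hp[i]; hp[i] <- hp[par]; hp[par] <- tp2
          hpos[hp[i]] <- i; hpos[hp[par]] <- par
          i <- par
        } else break
      }
      repeat {   # sift down
        l <- 2L * i
        if (l > hn) break
        sm <- if (l < hn && (ht[l + 1L] < ht[l] ||
                             (ht[l + 1L] == ht[l] && hp[l + 1L] < hp[l])))
          l + 1L else l
        if (ht[sm] < ht[i] || (ht[sm] == ht[i] && hp[sm] < hp[i])) {
          tt <- ht[i]; ht[i] <- ht[sm]; ht[sm] <- tt
          tp2 <- hp[i]; hp[i] <- hp[sm]; hp[sm] <- tp2
          hpos[hp[i]] <- i; hpos[hp[sm]] <- sm
          i <- sm
        } else break
      }
    }
    # fired process: a[p] was refreshed above if p depends on itself;
    # recompute if not, then redraw a fresh exponential
    ap <- prop1(p)
    a[p] <- ap
    tp <- if (ap > 0) t_ev + rexp(1L) / ap else Inf
    tnext[p] <- tp
    i <- hpos[p]
    ht[i] <- tp
    repeat {   # sift up (tp can only move up after ties-by-id)
      if (i <= 1L) break
      par <- i %/% 2L
      if (ht[i] < ht[par] || (ht[i] == ht[par] && hp[i] < hp[par])) {
        tt <- ht[i]; ht[i] <- ht[par]; ht[par] <- tt
        tp2 <- hp[i]; hp[i] <- hp[par]; hp[par] <- tp2
        hpos[hp[i]] <- i; hpos[hp[par]] <- par
        i <- par
      } else break
    }
    repeat {   # sift down
      l <- 2L * i
      if (l > hn) break
      sm <- if (l < hn && (ht[l + 1L] < ht[l] ||
                           (ht[l + 1L] == ht[l] && hp[l + 1L] < hp[l])))
        l + 1L else l
      if (ht[sm] < ht[i] || (ht[sm] == ht[i] && hp[sm] < hp[i])) {
        tt <- ht[i]; ht[i] <- ht[sm]; ht[sm] <- tt
        tp2 <- hp[i]; hp[i] <- hp[sm]; hp[sm] <- tp2
        hpos[hp[i]] <- i; hpos[hp[sm]] <- sm
        i <- sm
      } else break
    }
    if (log_events) {
      sim$event_log[[length(sim$event_log) + 1L]] <-
        c(t_ev, p, bound$procs$elem[p])
    }
  }

  M$counts <- counts
  sim$a <- a
  sim$tnext <- tnext
  sim$hpos <- hpos
  h$ht <- ht; h$hp <- hp
  sim$event_count <- sim$event_count + n_events
  n_events
}

# Direct-method SSA over one group (reference operator for distributional
# cross-checks): cumulative-propensity selection, exponential waiting times.
# The operator interface is pluggable; this is the alternative operator.
ssa_run_group_direct <- function(sim, h, t_start, t_end) {
  bound <- sim$bound
  M <- sim$M
  procs <- h$procs
  a <- compute_propensity(bound, M$counts, sim$ccur, procs)
  t <- t_start
  n_events <- 0L
  repeat {
    atot <- sum(a)
    if (atot <= 0) break
    t <- t + stats::rexp(1) / atot
    if (t > t_end) break
    u <- stats::runif(1) * atot
    k <- findInterval(u, cumsum(a), left.open = TRUE) + 1L
    k <- min(k, length(procs))
    p <- procs[k]
    eff <- bound$procs$eff[[p]]
    M$counts[eff[, 1]] <- M$counts[eff[, 1]] + eff[, 2]
    n_events <- n_events + 1L
    lo <- sim$dep$edges$a2ab[p]; hi <- sim$dep$edges$a2ab[p + 1L]
    deps <- if (hi > lo) sim$dep$edges$ab2c[(lo + 1L):hi] else integer(0)
    upd <- match(unique(c(deps, p)), procs)
    upd <- upd[!is.na(upd)]
    a[upd] <- compute_propensity(bound, M$counts, sim$ccur, procs[upd])
  }
  # keep NRM bookkeeping consistent for subsequent windows
  sim$a[procs] <- a
  sim$event_count <- sim$event_count + n_events
  n_events
}

# Reprice a set of processes after their propensities changed outside an
# event (diffusion sync, voltage refresh): non-firing rescale
# t' = t + (a_old/a_new)(t_old - t); resuscitation from zero draws a fresh
# exponential; a_new = 0 parks the process at +Inf.  Heaps of affected
# groups are rebuilt wholesale (a single vectorized sort each).  Fresh
# exponentials come from whatever RNG stream is current: callers invoke this
# per rank inside with_stream().
ssa_reprice <- function(sim, procs, t_now) {
  if (!length(procs)) return(invisible())
  bound <- sim$bound
  a_old <- sim$a[procs]
  a_new <- compute_propensity(bound, sim$M$counts, sim$ccur, procs)
  chg <- which(a_new != a_old)
  if (!length(chg)) return(invisible())
  procs <- procs[chg]; a_old <- a_old[chg]; a_new <- a_new[chg]
  dead <- a_new <= 0
  resus <- !dead & (a_old <= 0 | !is.finite(sim$tnext[procs]))
  resc <- !dead & !resus
  if (any(dead)) sim$tnext[procs[dead]] <- Inf
  if (any(resus)) {
    sim$tnext[procs[resus]] <- t_now + stats::rexp(sum(resus)) / a_new[resus]
  }
  if (any(resc)) {
    pr <- procs[resc]
    sim$tnext[pr] <- t_now + (a_old[resc] / a_new[resc]) * (sim$tnext[pr] - t_now)
  }
  sim$a[procs] <- a_new
  for (g in unique(sim$group_of[procs])) {
    heap_build(sim, sim$groups[[g]])
  }
  invisible()
}
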