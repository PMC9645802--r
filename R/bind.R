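#' Bind a model to a tagged mesh
#'
#' Resolves a [sim_model()] against a [tet_mesh()]: every kinetic process
#' (volume reaction instance per tetrahedron, surface reaction / channel
#' transition / GHK flux instance per patch triangle) is enumerated, rate
#' constants are converted to stochastic per-event coefficients, and channel
#' densities are converted to integer per-triangle channel counts by
#' largest-remainder rounding (so each patch total equals
#' `round(density * patch area * surface_scale)`).  Binding is deterministic
#' and idempotent: no random numbers are drawn.
#'
#' State layout: molecule counts are a single vector indexed first by
#' (tetrahedron, volume species), then by (patch triangle, surface species),
#' where surface species are triangle-side reaction species and channel
#' states (named `channel.state`).
#'
#' @param model a [sim_model()].
#' @param mesh a [tet_mesh()].
#' @param partition a [partition_mesh()] result; default single rank.
#' @param measures optional precomputed [compute_measures()].
#' @return An object of class `bound_model`.
#' @export
bind_model <- function(model, mesh, partition = NULL, measures = NULL) {
  stopifnot(inherits(model, "sim_model"), inherits(mesh, "tet_mesh"))
  if (is.null(measures)) measures <- compute_measures(mesh)
  if (is.null(partition)) partition <- partition_mesh(mesh, 1L, measures)

  sp_names <- model$species$name
  n_sp <- length(sp_names)
  n_tet <- nrow(mesh$tets)
  n_tri <- nrow(mesh$tris)

  comp_tags <- unique(mesh$tet_tags)
  patch_tags <- unique(mesh$tri_tags)
  need_tag <- function(tag, where, kindname) {
    if (!tag %in% where) {
      stop(sprintf("unknown %s tag '%s' (mesh has: %s)", kindname, tag,
                   paste(where, collapse = ", ")), call. = FALSE)
    }
  }
  need_species <- function(nm) {
    bad <- setdiff(nm, sp_names)
    if (length(bad)) {
      stop("undeclared species: ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }

  # ---- surface species enumeration -------------------------------------
  surf_sp <- character(0)
  for (r in model$reactions) {
    if (r$kind == "surface") {
      surf_sp <- c(surf_sp, names(r$lhs_tri), names(r$rhs_tri))
    }
  }
  chan_by_name <- list()
  for (ch in model$channels) chan_by_name[[ch$name]] <- ch
  for (mb in model$membranes) {
    for (cn in names(mb$channel_densities)) {
      ch <- chan_by_name[[cn]]
      if (is.null(ch)) stop("membrane references undeclared channel: ", cn,
                            call. = FALSE)
      surf_sp <- c(surf_sp, paste(ch$name, ch$states, sep = "."))
    }
  }
  surf_sp <- unique(surf_sp)
  need_species(setdiff(surf_sp, unlist(lapply(chan_by_name, function(ch)
    paste(ch$name, ch$states, sep = ".")))))
  n_ssp <- length(surf_sp)

  n_state <- n_tet * n_sp + n_tri * n_ssp
  vidx <- function(tet, sp) (match(sp, sp_names) - 1L) * n_tet + as.integer(tet)
  sidx <- function(tri, ss) n_tet * n_sp +
    (match(ss, surf_sp) - 1L) * n_tri + as.integer(tri)

  # ---- kinetic process accumulation ------------------------------------
  acc <- new.env(parent = emptyenv())
  acc$elem <- integer(0); acc$is_tri <- logical(0); acc$vtri <- integer(0)
  acc$r1 <- integer(0); acc$s1 <- integer(0); acc$r2 <- integer(0)
  acc$cbase <- numeric(0); acc$fn <- list(); acc$label <- character(0)
  acc$eff <- list(); acc$reactants <- list()
  add_procs <- function(elem, is_tri, vtri, r1, s1, r2, cbase, fn, eff,
                        reactants, label) {
    n <- length(elem)
    acc$elem <- c(acc$elem, as.integer(elem))
    acc$is_tri <- c(acc$is_tri, rep_len(is_tri, n))
    acc$vtri <- c(acc$vtri, as.integer(rep_len(vtri, n)))
    acc$r1 <- c(acc$r1, as.integer(r1)); acc$s1 <- c(acc$s1, as.integer(rep_len(s1, n)))
    acc$r2 <- c(acc$r2, as.integer(rep_len(r2, n)))
    acc$cbase <- c(acc$cbase, rep_len(cbase, n))
    acc$fn <- c(acc$fn, rep_len(list(fn), n))
    acc$eff <- c(acc$eff, eff)
    acc$reactants <- c(acc$reactants, reactants)
    acc$label <- c(acc$label, rep_len(label, n))
  }

  net_effect <- function(lhs, rhs) {
    all_sp <- union(names(lhs), names(rhs))
    d <- stats::setNames(numeric(length(all_sp)), all_sp)
    d[names(lhs)] <- d[names(lhs)] - lhs
    d[names(rhs)] <- d[names(rhs)] + rhs
    d[d != 0]
  }

  inner_tet_of_tri <- mesh$tri_tet[, 1]

  for (r in model$reactions) {
    if (r$kind == "volume") {
      need_tag(r$compartment, comp_tags, "compartment")
      need_species(c(names(r$lhs), names(r$rhs)))
      tets <- which(mesh$tet_tags == r$compartment)
      order <- sum(r$lhs)
      cvec <- if (order == 1) rep(stochastic_rate_constant(r$rate, 1, unit = r$unit),
                                  length(tets))
              else vapply(measures$volumes[tets], function(v)
                stochastic_rate_constant(r$rate, 2, v, r$unit), numeric(1))
      rs <- names(r$lhs)[r$lhs > 0]
      if (order == 1 || (length(rs) == 1 && r$lhs[rs] == 2)) {
        r1 <- vidx(tets, rs[1]); r2 <- 0L
        s1 <- if (order == 2) 2L else 1L
      } else {
        r1 <- vidx(tets, rs[1]); r2 <- vidx(tets, rs[2]); s1 <- 1L
      }
      net <- net_effect(r$lhs, r$rhs)
      eff <- lapply(tets, function(tt)
        cbind(idx = vidx(rep(tt, length(net)), names(net)),
              delta = unname(net)))
      reac <- if (length(rs) == 2)
        lapply(seq_along(tets), function(i) c(r1[i], r2[i]))
      else as.list(r1)
      add_procs(tets, FALSE, NA_integer_, r1, s1, r2, cvec, NULL, eff, reac,
                paste0("rxn:", paste(names(r$lhs), collapse = "+"), ">",
                       paste(names(r$rhs), collapse = "+")))
    } else if (r$kind == "surface") {
      need_tag(r$patch, patch_tags, "patch")
      need_species(names(r$lhs_tet))
      need_species(names(r$rhs_tet))
      tris <- which(mesh$tri_tags == r$patch)
      if (!length(tris)) next
      tets <- inner_tet_of_tri[tris]
      order <- sum(r$lhs_tet) + sum(r$lhs_tri)
      cvec <- if (order == 1) rep(stochastic_rate_constant(r$rate, 1, unit = r$unit),
                                  length(tris))
              else vapply(measures$volumes[tets], function(v)
                stochastic_rate_constant(r$rate, 2, v, r$unit), numeric(1))
      mk_idx <- function(tri, tt, tet_side, tri_side) {
        c(if (length(tet_side)) vidx(rep(tt, length(tet_side)), names(tet_side)),
          if (length(tri_side)) sidx(rep(tri, length(tri_side)), names(tri_side)))
      }
      lhs_all <- c(r$lhs_tet, r$lhs_tri)
      eff <- vector("list", length(tris)); reac <- vector("list", length(tris))
      r1 <- integer(length(tris)); r2 <- integer(length(tris)); s1v <- 1L
      for (i in seq_along(tris)) {
        tri <- tris[i]; tt <- tets[i]
        li <- mk_idx(tri, tt, r$lhs_tet, r$lhs_tri)
        ri <- mk_idx(tri, tt, r$rhs_tet, r$rhs_tri)
        d <- c(-unname(lhs_all), unname(c(r$rhs_tet, r$rhs_tri)))
        idxs <- c(li, ri)
        agg <- rowsum(d, idxs)
        keep <- agg[, 1] != 0
        eff[[i]] <- cbind(idx = as.integer(rownames(agg))[keep],
                          delta = unname(agg[keep, 1]))
        rlist <- rep(li, unname(lhs_all))
        reac[[i]] <- unique(rlist)
        if (length(unique(rlist)) == 1L) {
          r1[i] <- rlist[1]; r2[i] <- 0L
          s1v <- if (length(rlist) == 2L) 2L else 1L
        } else {
          r1[i] <- unique(rlist)[1]; r2[i] <- unique(rlist)[2]
        }
      }
      add_procs(tris, TRUE, tris, r1, s1v, r2, cvec, NULL, eff, reac,
                paste0("srxn:", r$patch))
    } else if (r$kind == "ghk") {
      need_tag(r$patch, patch_tags, "patch")
      need_species(r$species)
      z <- model$species$valence[match(r$species, sp_names)]
      if (z == 0) stop("GHK flux needs a species with nonzero valence",
                       call. = FALSE)
      tris <- which(mesh$tri_tags == r$patch)
      tets <- inner_tet_of_tri[tris]
      rt_f <- GAS_R * model$temperature / FARADAY
      P <- r$permeability; nch <- r$channels; cout <- r$outer_conc
      fn_eff <- make_ghk_ratefun(P, z, rt_f, "efflux")
      fn_in  <- make_ghk_ratefun(P, z, rt_f, "influx")
      ridx <- vidx(tets, r$species)
      eff_out <- lapply(ridx, function(ix) cbind(idx = ix, delta = -1))
      eff_in  <- lapply(ridx, function(ix) cbind(idx = ix, delta = +1))
      add_procs(tris, TRUE, tris, ridx, 1L, 0L,
                nch / measures$volumes[tets], fn_eff, eff_out,
                as.list(ridx), paste0("ghk_out:", r$species))
      add_procs(tris, TRUE, tris, 0L, 1L, 0L,
                rep(nch * AVOGADRO * cout, length(tris)), fn_in, eff_in,
                rep(list(integer(0)), length(tris)),
                paste0("ghk_in:", r$species))
    }
  }

  # ---- membranes: channel populations and transitions ------------------
  membranes <- list()
  init_surf <- list()   # list of (idx, count)
  for (mb in model$membranes) {
    need_tag(mb$patch, patch_tags, "patch")
    tris <- which(mesh$tri_tags == mb$patch)
    scale <- unname(mesh$surface_scale[mb$patch])
    if (is.na(scale)) scale <- 1
    areas <- measures$tri_areas[tris] * scale
    chans <- list()
    for (cn in names(mb$channel_densities)) {
      ch <- chan_by_name[[cn]]
      dens <- mb$channel_densities[[cn]]
      counts <- largest_remainder_round(dens * areas)
      # split each triangle's channels over states by initial fractions
      for (s in ch$states) {
        frac <- ch$initial[s]
        if (is.na(frac)) frac <- 0
        scounts <- largest_remainder_round(counts * frac)
        init_surf[[length(init_surf) + 1L]] <-
          cbind(idx = sidx(tris, paste(ch$name, s, sep = ".")),
                count = scounts)
      }
      # transitions: one process per (triangle, transition)
      for (tr in ch$transitions) {
        from_i <- sidx(tris, paste(ch$name, tr$from, sep = "."))
        to_i   <- sidx(tris, paste(ch$name, tr$to, sep = "."))
        eff <- lapply(seq_along(tris), function(i)
          cbind(idx = c(from_i[i], to_i[i]), delta = c(-1, 1)))
        if (is.function(tr$rate)) {
          add_procs(tris, TRUE, tris, from_i, 1L, 0L, 1.0, tr$rate, eff,
                    as.list(from_i),
                    paste0("chan:", ch$name, ":", tr$from, ">", tr$to))
        } else {
          add_procs(tris, TRUE, tris, from_i, 1L, 0L, tr$rate, NULL, eff,
                    as.list(from_i),
                    paste0("chan:", ch$name, ":", tr$from, ">", tr$to))
        }
      }
      open_idx <- if (length(ch$open_states))
        vapply(ch$open_states, function(s)
          (match(paste(ch$name, s, sep = "."), surf_sp) - 1L), integer(1))
      else integer(0)
      chans[[cn]] <- list(channel = ch, counts = counts,
                          open_surf_sp0 = open_idx)
    }
    membranes[[mb$patch]] <- list(
      patch = mb$patch, tris = tris, scale = scale,
      capacitance = mb$capacitance * scale, leak = mb$leak * scale,
      leak_reversal = mb$leak_reversal, channels = chans
    )
  }

  # ---- initial volume counts -------------------------------------------
  for (tag in names(model$initial)) need_tag(tag, comp_tags, "compartment")
  need_species(unlist(lapply(model$initial, names)))

  # ---- diffusion rules --------------------------------------------------
  for (d in model$diffusion) {
    need_tag(d$compartment, comp_tags, "compartment")
    need_species(d$species)
  }

  n_proc <- length(acc$elem)
  vdep <- !vapply(acc$fn, is.null, logical(1))
  structure(list(
    model = model, mesh = mesh, measures = measures, partition = partition,
    vol_species = sp_names, surf_species = surf_sp,
    n_tet = n_tet, n_tri = n_tri, n_state = n_state, n_proc = n_proc,
    procs = list(elem = acc$elem, is_tri = acc$is_tri, vtri = acc$vtri,
                 r1 = acc$r1, s1 = acc$s1, r2 = acc$r2, cbase = acc$cbase,
                 fn = acc$fn, vdep = vdep, eff = acc$eff,
                 reactants = acc$reactants, label = acc$label),
    membranes = membranes, init_surf = init_surf,
    vidx = vidx, sidx = sidx
  ), class = "bound_model")
}

# GHK one-way rate factors as functions of voltage.  u = zFV/RT.
# efflux factor:  P * u / (1 - exp(-u))          (times n/V_tet in cbase)
# influx factor:  P * u * exp(-u) / (1 - exp(-u)) (times N_A*c_out in cbase)
# Removable singularity at u = 0 handled by series (u/(1-e^-u) ~ 1 + u/2).
make_ghk_ratefun <- function(P, z, rt_f, side) {
  force(P); force(z); force(rt_f); force(side)
  function(V) {
    u <- z * V / rt_f
    small <- abs(u) < 1e-8
    base <- ifelse(small, 1 + u / 2, u / (1 - exp(-u)))
    if (side == "efflux") P * base else P * base * exp(-u)
  }
}

#' @export
print.bound_model <- function(x, ...) {
  cat(sprintf("<bound_model> %d kinetic processes on %d tets / %d tris; %d volume + %d surface species\n",
              x$n_proc, x$n_tet, x$n_tri, length(x$vol_species),
              length(x$surf_species)))
  invisible(x)
}
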