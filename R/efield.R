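#' Goldman-Hodgkin-Katz current per open channel
#'
#' Constant-field flux equation
#' `I = P z^2 F^2 V / (RT) * (c_in - c_out exp(-zFV/RT)) / (1 - exp(-zFV/RT))`
#' with the removable singularity at `V = 0` handled via `expm1` and a series
#' limit `I -> P z F (c_in - c_out)`.  Outward (efflux) current is positive.
#'
#' @param P single-channel permeability (m^3/s).
#' @param z ionic valence.
#' @param V membrane potential (V), vectorized.
#' @param c_in,c_out inner/outer concentrations (mol/m^3).
#' @param temperature temperature (K).
#' @return Current per open channel (A), parallel to `V`.
#' @export
ghk_current <- function(P, z, V, c_in, c_out,
                        temperature = DEFAULT_TEMPERATURE) {
  stopifnot(all(c_in >= 0), all(c_out >= 0))
  u <- z * FARADAY * V / (GAS_R * temperature)
  small <- abs(u) < 1e-12
  out <- numeric(length(u))
  if (any(!small)) {
    us <- u[!small]
    out[!small] <- P * z * FARADAY * us *
      (c_in - c_out * exp(-us)) / (-expm1(-us))
  }
  if (any(small)) out[small] <- P * z * FARADAY * (c_in - c_out)
  out
}

#' Assemble the membrane-potential linear system
#'
#' Linear (P1) finite elements on the tetrahedral mesh: the volume
#' conductance matrix is the standard stiffness matrix with conductivity
#' `1/Ra` (Ra the intracellular resistivity), symmetric positive
#' semi-definite with the constant vector in its null space.  Membrane
#' capacitance and leak are lumped to vertices with one third of each
#' membrane triangle's (surface-scaled) area.  Vertex ordering follows the
#' partition's tetrahedron ownership (owned blocks contiguous), mirroring
#' the locality contract of a distributed assembly in a single process.
#'
#' @param bound a [bind_model()] result with at least one membrane.
#' @return An environment of class `voltage_state`: `v` (potential per
#'   vertex, V), `Kvol` (sparse stiffness, S), `Cvec` (lumped capacitance
#'   per vertex, F), `Gleak` (S per vertex), `b_leak` (A per vertex),
#'   `inj` (A per vertex), plus channel/GHK current source tables.
#' @export
assemble_efield_system <- function(bound) {
  mesh <- bound$mesh
  measures <- bound$measures
  if (!length(bound$membranes)) {
    stop("model declares no membrane; nothing to assemble", call. = FALSE)
  }
  n_vert <- nrow(mesh$vertices)
  sigma <- 1 / bound$model$resistivity

  # --- stiffness: per-tet gradients via cofactors, 16 triplets per tet ---
  tets <- mesh$tets
  p1 <- mesh$vertices[tets[, 1], , drop = FALSE]
  u <- mesh$vertices[tets[, 2], , drop = FALSE] - p1
  v <- mesh$vertices[tets[, 3], , drop = FALSE] - p1
  w <- mesh$vertices[tets[, 4], , drop = FALSE] - p1
  cross3 <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  vxw <- cross3(v, w); wxu <- cross3(w, u); uxv <- cross3(u, v)
  det <- rowSums(u * vxw)                  # 6 * signed volume
  g2 <- vxw / det; g3 <- wxu / det; g4 <- uxv / det
  g1 <- -(g2 + g3 + g4)
  grads <- list(g1, g2, g3, g4)
  vol <- abs(det) / 6
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  trip_i <- vector("list", 16); trip_j <- vector("list", 16)
  trip_x <- vector("list", 16); k <- 0
  for (a in 1:4) for (b in 1:4) {
    k <- k + 1
    trip_i[[k]] <- tets[, a]
    trip_j[[k]] <- tets[, b]
    trip_x[[k]] <- sigma * vol * rowSums(grads[[a]] * grads[[b]])
  }
  Kvol <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                               x = unlist(trip_x), dims = c(n_vert, n_vert))

  # --- membrane lumping -------------------------------------------------
  Cvec <- numeric(n_vert)
  Gleak <- numeric(n_vert)
  b_leak <- numeric(n_vert)
  v_init <- 0
  chan_src <- list()
  for (mb in bound$membranes) {
    tris <- mb$tris
    third <- rep(measures$tri_areas[tris] * mb$scale / 3, 3L)
    vv <- c(mesh$tris[tris, 1], mesh$tris[tris, 2], mesh$tris[tris, 3])
    acc <- rowsum(third, vv)
    vids <- as.integer(rownames(acc))
    Cvec[vids] <- Cvec[vids] + acc[, 1] * mb$capacitance / mb$scale
    Gleak[vids] <- Gleak[vids] + acc[, 1] * mb$leak / mb$scale
    b_leak[vids] <- b_leak[vids] + acc[, 1] * (mb$leak / mb$scale) * mb$leak_reversal
    v_init <- mb$leak_reversal
    for (cn in names(mb$channels)) {
      ch <- mb$channels[[cn]]
      if (!length(ch$open_surf_sp0) || ch$channel$g_single <= 0) next
      # state indices of the open-state counts on this patch's triangles
      open_idx <- lapply(ch$open_surf_sp0, function(s0)
        bound$n_tet * length(bound$vol_species) + s0 * bound$n_tri + tris)
      chan_src[[length(chan_src) + 1L]] <- list(
        tris = tris, open_idx = open_idx,
        g_single = ch$channel$g_single, reversal = ch$channel$reversal
      )
    }
  }

  # --- constant injected currents --------------------------------------
  inj <- numeric(n_vert)
  for (j in bound$model$injections) {
    vids <- if (!is.null(j$vertices)) as.integer(j$vertices)
            else resolve_vertex(mesh, j$at)
    inj[vids] <- inj[vids] + j$current / length(vids)
  }

  # --- GHK current sources (from ghk_flux declarations) -----------------
  ghk_src <- list()
  for (r in bound$model$reactions) {
    if (!inherits(r, "sim_reaction") || r$kind != "ghk") next
    tris <- which(mesh$tri_tags == r$patch)
    tets_in <- mesh$tri_tet[tris, 1]
    z <- bound$model$species$valence[match(r$species, bound$model$species$name)]
    ghk_src[[length(ghk_src) + 1L]] <- list(
      tris = tris, state_idx = bound$vidx(tets_in, r$species),
      tet_vol = measures$volumes[tets_in], P = r$permeability, z = z,
      c_out = r$outer_conc, n_channels = r$channels
    )
  }

  V <- new.env(parent = emptyenv())
  V$v <- rep(v_init, n_vert)
  V$Kvol <- Matrix::forceSymmetric((Kvol + Matrix::t(Kvol)) / 2)
  V$Cvec <- Cvec; V$Gleak <- Gleak; V$b_leak <- b_leak; V$inj <- inj
  V$chan_src <- chan_src; V$ghk_src <- ghk_src
  V$temperature <- bound$model$temperature
  V$factor <- NULL; V$static <- length(chan_src) == 0L
  V$tri_verts <- mesh$tris
  class(V) <- "voltage_state"
  V
}

#' Nearest mesh vertex to a coordinate
#'
#' @param mesh a [tet_mesh()].
#' @param at numeric length 3 (m).
#' @return An [entity_id()] of kind `"vertex"`.
#' @export
resolve_vertex <- function(mesh, at) {
  d2 <- (mesh$vertices[, 1] - at[1])^2 + (mesh$vertices[, 2] - at[2])^2 +
        (mesh$vertices[, 3] - at[3])^2
  entity_id(which.min(d2), "vertex")
}

# Membrane potential per patch triangle: mean of its 3 vertex potentials.
tri_voltage <- function(V) {
  (V$v[V$tri_verts[, 1]] + V$v[V$tri_verts[, 2]] + V$v[V$tri_verts[, 3]]) / 3
}

#' One backward-Euler step of the membrane-potential solve
#'
#' Solves `(C/dt + K_vol + G_mem) v' = (C/dt) v + G_mem-weighted reversal
#' terms + I_inj + I_GHK(v)`.  Ohmic channel conductances (open-channel
#' count times single-channel conductance, frozen over the step) enter
#' implicitly; GHK currents are evaluated explicitly at the pre-step
#' voltage.  The factorization is a sparse Cholesky, computed once for
#' passive systems and refreshed every step when channel conductances
#' change.
#'
#' @param V a [assemble_efield_system()] voltage state.
#' @param counts molecule-count vector (open-channel and ion counts).
#' @param dt step length (s).
#' @return The voltage state, stepped in place (also returned invisibly).
#' @export
efield_step <- function(V, counts, dt) {
  stopifnot(dt > 0)
  n <- length(V$v)
  Gdiag <- V$Gleak
  rhs <- V$Cvec / dt * V$v + V$b_leak + V$inj

  for (cs in V$chan_src) {
    n_open <- numeric(length(cs$tris))
    for (oi in cs$open_idx) n_open <- n_open + counts[oi]
    g_tri <- n_open * cs$g_single
    gv <- rowsum(rep(g_tri / 3, 3L),
                 c(V$tri_verts[cs$tris, 1], V$tri_verts[cs$tris, 2],
                   V$tri_verts[cs$tris, 3]))
    vids <- as.integer(rownames(gv))
    Gdiag[vids] <- Gdiag[vids] + gv[, 1]
    rhs[vids] <- rhs[vids] + gv[, 1] * cs$reversal
  }

  if (length(V$ghk_src)) {
    vtri_all <- tri_voltage(V)
    for (gs in V$ghk_src) {
      c_in <- counts[gs$state_idx] / (AVOGADRO * gs$tet_vol)
      itri <- gs$n_channels *
        ghk_current(gs$P, gs$z, vtri_all[gs$tris], c_in, gs$c_out,
                    V$temperature)
      iv <- rowsum(rep(-itri / 3, 3L),           # outward positive
                   c(V$tri_verts[gs$tris, 1], V$tri_verts[gs$tris, 2],
                     V$tri_verts[gs$tris, 3]))
      vids <- as.integer(rownames(iv))
      rhs[vids] <- rhs[vids] + iv[, 1]
    }
  }

  A <- V$Kvol + Matrix::Diagonal(n, V$Cvec / dt + Gdiag)
  if (is.null(V$factor)) {
    V$factor <- tryCatch(
      Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE),
      error = function(e) {
        stop(paste0("membrane-potential system is singular (no capacitance ",
                    "or grounding); pin a reference vertex or declare a ",
                    "membrane: ", conditionMessage(e)), call. = FALSE)
      })
  } else if (!V$static) {
    V$factor <- Matrix::update(V$factor, Matrix::forceSymmetric(A))
  }
  V$v <- as.numeric(Matrix::solve(V$factor, rhs))
  invisible(V)
}
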