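#' Ten-species reaction-diffusion benchmark ("simple" model)
#'
#' Species A..J with diffusion coefficients 100, 90, ..., 10 um^2/s and
#' initial counts 1,000, 2,000, ..., 10,000, coupled by four reversible
#' reactions: A+B<->C (kf 1000 (uM s)^-1, kb 100 s^-1), C+D<->E (100, 10),
#' F+G<->H (10, 1), H+I<->J (1, 1).  Initial counts scale by `scale`
#' (0.01x .. 100x series).  The companion geometry is a cuboid; the default
#' builder approximates a ~13,000-tetrahedron box (10 x 10 x 100 um at
#' resolution 6 x 6 x 60 gives 12,960), and coarser resolutions scale the
#' same cuboid down for quick runs.
#'
#' @param scale initial-count scale factor, one of 0.01, 0.1, 1, 10, 100.
#' @param resolution box resolution (cells per axis) for the companion mesh.
#' @return A list: `model` (a [sim_model()]), `mesh_spec` (dims/resolution),
#'   `build_mesh()` (closure returning the [tet_mesh()]).
#' @export
fixture_simple_model <- function(scale = 1, resolution = c(6, 6, 60)) {
  stopifnot(scale %in% c(0.01, 0.1, 1, 10, 100))
  species <- LETTERS[1:10]
  D <- seq(100, 10, by = -10) * 1e-12              # um^2/s -> m^2/s
  counts <- round(seq(1000, 10000, by = 1000) * scale)
  rxn <- c(
    reversible_reaction(c(A = 1, B = 1), c(C = 1), 1000, 100),
    reversible_reaction(c(C = 1, D = 1), c(E = 1), 100, 10),
    reversible_reaction(c(F = 1, G = 1), c(H = 1), 10, 1),
    reversible_reaction(c(H = 1, I = 1), c(J = 1), 1, 1)
  )
  model <- sim_model(
    species = species,
    reactions = rxn,
    diffusion = lapply(seq_along(species), function(i)
      diffusion_rule(species[i], D[i], "comp")),
    initial = list(comp = stats::setNames(counts, species))
  )
  dims <- c(10e-6, 10e-6, 100e-6)
  list(model = model,
       mesh_spec = list(shape = "box", dims = dims, resolution = resolution),
       build_mesh = function() generate_box_mesh(dims, resolution))
}

#' Passive-cable benchmark fixture
#'
#' A leaking, sealed 1 mm cable with a 0.1 nA step current injected at the
#' z_min end and voltage taps at both extremities.  Parameters: leak
#' 0.25 S/m^2, reversal -65 mV, axial resistivity 1 Ohm m, membrane
#' capacitance 0.01 F/m^2, nominal diameter 1 um, voltage step 5 us.  The
#' leak membrane sits on every surface triangle of the generated cable
#' mesh; surface densities carry the cylinder-correction ratio recorded by
#' [generate_cable_mesh()].
#'
#' @param axial_segments axial subdivisions of the cable mesh (>= 10).
#' @param cross_segments cross-section subdivisions per axis.
#' @return A list: `model`, `mesh` (the generated [tet_mesh()]), `params`
#'   ([rallpack1_params()]), `efield_dt`, `probes` (z_min / z_max
#'   coordinates), `injection_vertices`.
#' @export
fixture_rallpack1 <- function(axial_segments = 200, cross_segments = 1) {
  stopifnot(axial_segments >= 10)
  p <- rallpack1_params()
  mesh <- generate_cable_mesh(p$length, p$diameter, axial_segments,
                              cross_segments)
  zmin_verts <- which(abs(mesh$vertices[, 3]) < 1e-12)
  model <- sim_model(
    species = character(0),
    membranes = list(membrane("memb", capacitance = p$capacitance,
                              leak = p$leak,
                              leak_reversal = p$leak_reversal)),
    injections = list(list(vertices = zmin_verts, current = p$current)),
    resistivity = p$resistivity
  )
  side <- sqrt(pi) * p$diameter / 2
  list(model = model, mesh = mesh, params = p, efield_dt = p$efield_dt,
       probes = list(zmin = c(side / 2, side / 2, 0),
                     zmax = c(side / 2, side / 2, p$length)),
       injection_vertices = zmin_verts)
}

#' Stochastic Hodgkin-Huxley cable fixture
#'
#' The passive cable fixture plus stochastic Hodgkin-Huxley sodium and
#' potassium channels on every membrane triangle.  Channel densities are
#' the standard squid-axon maximal conductances (1200 S/m^2 Na,
#' 360 S/m^2 K) divided by the single-channel conductance, converted to
#' integer per-triangle counts by largest-remainder rounding; the leak is
#' the passive fixture's.  The benchmark span is 250 ms.
#'
#' @param g_single single-channel conductance (S) of both channels
#'   (4 pS by default; 20 pS gives 5x fewer channels and visibly noisier
#'   spiking).
#' @param axial_segments,cross_segments mesh resolution.
#' @param g_na_density,g_k_density maximal conductance densities (S/m^2).
#' @return As [fixture_rallpack1()], plus `channels`, `t_span` (0.25 s).
#' @export
fixture_rallpack3 <- function(g_single = 4e-12, axial_segments = 200,
                              cross_segments = 1, g_na_density = 1200,
                              g_k_density = 360) {
  stopifnot(g_single > 0)
  fx <- fixture_rallpack1(axial_segments, cross_segments)
  ch <- hh_gating_model(g_single = g_single,
                        v_init = fx$params$leak_reversal)
  fx$model$channels <- unname(ch)
  fx$model$membranes[[1]]$channel_densities <-
    c(Na = g_na_density / g_single, K = g_k_density / g_single)
  fx$channels <- ch
  fx$t_span <- 0.25
  fx$g_single <- g_single
  fx
}

#' Two-tetrahedron surface/GHK toy fixture
#'
#' Two face-adjacent tetrahedra, each carrying the cyclic volume reactions
#' A -> B -> C -> A; one boundary triangle of the first tetrahedron is a
#' membrane patch with four surface processes: C transfer between the
#' tetrahedron and the triangle (both directions) and a GHK flux carrying C
#' across the membrane in both directions (the outer side is not modelled
#' as molecules).  All rates default to 1 per second and the membrane
#' potential is held fixed; the fixture exists to exercise surface
#' reactions, GHK kinetics and the dependency-graph decomposition (its
#' graph has exactly two components, of sizes 7 and 3).
#'
#' @param rate volume/surface reaction rate constant (s^-1).
#' @param permeability GHK single-channel permeability (m^3/s).
#' @param outer_conc fixed outer concentration of C (mol/m^3).
#' @param fixed_voltage held membrane potential (V).
#' @param n0 initial count of each of A, B, C.
#' @return A list: `model`, `mesh`.
#' @export
fixture_ghk_toy <- function(rate = 1, permeability = 1e-20,
                            outer_conc = 1e-3, fixed_voltage = -0.065,
                            n0 = 100) {
  s <- 1e-6
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 1)) * s
  tets <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  tris <- rbind(c(1, 2, 3))                        # boundary face of tet 1
  mesh <- tet_mesh(verts, tets, tris = tris,
                   tet_tags = c("comp", "comp"), tri_tags = "memb")
  model <- sim_model(
    species = data.frame(name = c("A", "B", "C"), valence = c(0, 0, 1)),
    reactions = list(
      reaction(c(A = 1), c(B = 1), rate),
      reaction(c(B = 1), c(C = 1), rate),
      reaction(c(C = 1), c(A = 1), rate),
      surface_reaction(lhs_tet = c(C = 1), rhs_tri = c(C = 1),
                       rate = rate, patch = "memb"),
      surface_reaction(lhs_tri = c(C = 1), rhs_tet = c(C = 1),
                       rate = rate, patch = "memb"),
      ghk_flux("C", "memb", permeability = permeability,
               outer_conc = outer_conc)
    ),
    initial = list(comp = c(A = n0, B = n0, C = n0)),
    fixed_voltage = fixed_voltage
  )
  list(model = model, mesh = mesh)
}

#' Export a fixture as MSH mesh + JSON model config
#'
#' Writes the fixture's mesh in MSH v2.2 ASCII and its model (plus an
#' optional run block) as the package's JSON config schema, so command-line
#' runs reproduce library-level setups.
#'
#' @param fixture a fixture list with `model` and `mesh` (or `build_mesh`).
#' @param dir output directory (created if missing).
#' @param run optional named list stored under `"run"` in the config.
#' @return Paths of the written files, invisibly.
#' @export
fixture_export <- function(fixture, dir, run = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mesh <- if (!is.null(fixture$mesh)) fixture$mesh else fixture$build_mesh()
  mesh_path <- file.path(dir, "mesh.msh")
  write_msh(mesh, mesh_path)
  cfg_path <- file.path(dir, "model.json")
  model_to_json(fixture$model, cfg_path, run = run)
  invisible(c(mesh = mesh_path, config = cfg_path))
}
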