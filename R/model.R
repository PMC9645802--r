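#' Declare a biochemical model
#'
#' A model is a pure declaration — species, reactions, diffusion rules,
#' channels, membranes, initial conditions — with no reference to a concrete
#' mesh.  [bind_model()] resolves it against a tagged mesh into an enumerated
#' set of kinetic processes.
#'
#' @param species character vector of species names, or a data frame with
#'   columns `name` and `valence` (ionic valence, used by GHK currents).
#' @param reactions list of [reaction()] / [surface_reaction()] /
#'   [ghk_flux()] declarations.
#' @param diffusion list of [diffusion_rule()]s.
#' @param channels list of [channel()] definitions.
#' @param membranes list of [membrane()] declarations.
#' @param initial named list: per compartment tag, a named vector of initial
#'   molecule counts (distributed uniformly in space — volume-weighted — at
#'   simulation initialization).
#' @param injections list of `list(at = c(x, y, z), current = amperes)`
#'   constant current injections at the vertex nearest `at`.
#' @param fixed_voltage if not `NULL`, no membrane-potential solve is
#'   performed and voltage-dependent rates see this constant potential (V).
#' @param resistivity intracellular (axial) resistivity, Ohm m.
#' @param temperature temperature (K) for GHK RT/F terms.
#' @return An object of class `sim_model`.
#' @export
sim_model <- function(species, reactions = list(), diffusion = list(),
                      channels = list(), membranes = list(), initial = list(),
                      injections = list(), fixed_voltage = NULL,
                      resistivity = 1.0, temperature = DEFAULT_TEMPERATURE) {
  if (is.character(species)) {
    species <- data.frame(name = species,
                          valence = numeric(length(species)))
  }
  stopifnot(is.data.frame(species), all(c("name") %in% names(species)))
  if (is.null(species$valence)) species$valence <- 0
  if (anyDuplicated(species$name)) {
    stop("species names must be unique", call. = FALSE)
  }
  structure(list(
    species = species, reactions = reactions, diffusion = diffusion,
    channels = channels, membranes = membranes, initial = initial,
    injections = injections, fixed_voltage = fixed_voltage,
    resistivity = resistivity, temperature = temperature
  ), class = "sim_model")
}

#' Declare a volume reaction
#'
#' Mass-action kinetics.  Rate units: `"per_s"` for first order,
#' `"per_M_s"` or `"per_uM_s"` for second order (converted to a stochastic
#' per-event coefficient at binding via [stochastic_rate_constant()]).
#' Total reactant order must be 1 or 2.
#'
#' @param lhs,rhs named integer vectors of stoichiometries (may be empty for
#'   `rhs`; `lhs` order must be >= 1).
#' @param rate rate constant in `unit`.
#' @param unit one of `"per_s"`, `"per_M_s"`, `"per_uM_s"`.
#' @param compartment compartment tag the reaction applies in.
#' @export
reaction <- function(lhs, rhs, rate, unit = "per_s", compartment = "comp") {
  order <- sum(lhs)
  if (order < 1) stop("reactant order must be >= 1", call. = FALSE)
  if (order > 2) stop("reactions above order 2 are not supported", call. = FALSE)
  if (any(lhs < 0) || (length(rhs) && any(rhs < 0))) {
    stop("stoichiometric counts must be >= 0", call. = FALSE)
  }
  structure(list(kind = "volume", lhs = lhs, rhs = rhs, rate = rate,
                 unit = unit, compartment = compartment), class = "sim_reaction")
}

#' Declare a reversible volume reaction (two unidirectional reactions)
#'
#' @inheritParams reaction
#' @param kf,kb forward/backward rate constants.
#' @param unit_f,unit_b their units.
#' @return A list of two [reaction()]s.
#' @export
reversible_reaction <- function(lhs, rhs, kf, kb, unit_f = "per_uM_s",
                                unit_b = "per_s", compartment = "comp") {
  list(reaction(lhs, rhs, kf, unit_f, compartment),
       reaction(rhs, lhs, kb, unit_b, compartment))
}

#' Declare a surface reaction
#'
#' A reaction linking a tetrahedron and an adjacent patch triangle: species
#' on the `tet` side live in the tetrahedron's volume, species on the `tri`
#' side on the triangle.  One process is enumerated per (patch triangle,
#' inner tetrahedron) pair.  Order-2 rates use the inner tetrahedron volume.
#'
#' @param lhs_tet,lhs_tri,rhs_tet,rhs_tri named stoichiometry vectors
#'   (empty vectors allowed).
#' @param rate,unit as in [reaction()].
#' @param patch patch tag.
#' @export
surface_reaction <- function(lhs_tet = c(), lhs_tri = c(), rhs_tet = c(),
                             rhs_tri = c(), rate, unit = "per_s",
                             patch = "patch") {
  order <- sum(lhs_tet) + sum(lhs_tri)
  if (order < 1) stop("reactant order must be >= 1", call. = FALSE)
  if (order > 2) stop("reactions above order 2 are not supported", call. = FALSE)
  structure(list(kind = "surface", lhs_tet = lhs_tet, lhs_tri = lhs_tri,
                 rhs_tet = rhs_tet, rhs_tri = rhs_tri, rate = rate,
                 unit = unit, patch = patch), class = "sim_reaction")
}

#' Declare a Goldman-Hodgkin-Katz flux across a patch
#'
#' The GHK constant-field flux of an ion across each triangle of a patch,
#' realized as two unidirectional kinetic processes per triangle (efflux,
#' first order in the inner count; influx, zero order, driven by the fixed
#' outer concentration), plus the corresponding electrical current.  The
#' inner concentration is the inner tetrahedron's `count / (N_A * volume)`;
#' the outer side is not modelled as molecules.
#'
#' @param species ion species name (must declare a nonzero valence).
#' @param patch patch tag.
#' @param permeability single-channel permeability (m^3/s).
#' @param outer_conc fixed outer concentration (mol/m^3).
#' @param channels number of channels per triangle (default 1), or a
#'   channel-state reference `list(channel =, state =)` to count open
#'   channels dynamically (not needed by the shipped fixtures).
#' @export
ghk_flux <- function(species, patch, permeability, outer_conc, channels = 1) {
  structure(list(kind = "ghk", species = species, patch = patch,
                 permeability = permeability, outer_conc = outer_conc,
                 channels = channels), class = "sim_reaction")
}

#' Declare a diffusion rule
#'
#' @param species species name.
#' @param D diffusion coefficient (m^2/s).
#' @param compartment compartment tag it applies in.
#' @export
diffusion_rule <- function(species, D, compartment = "comp") {
  if (D < 0) stop("diffusion coefficient must be >= 0", call. = FALSE)
  structure(list(species = species, D = D, compartment = compartment),
            class = "diffusion_rule")
}

#' Declare a multi-state membrane channel
#'
#' Channel states are surface populations on patch triangles; transitions
#' between states are first-order kinetic processes whose rates may depend
#' on the local membrane potential.  States listed in `open_states` conduct:
#' ohmically with single-channel conductance `g_single` (S) toward reversal
#' potential `reversal` (V).
#'
#' @param name channel name (state populations are named `name.state`).
#' @param states character vector of state names.
#' @param transitions list of `list(from =, to =, rate =)` where `rate` is
#'   either a constant (s^-1) or a function of voltage (V -> s^-1),
#'   vectorized over V and nonnegative on the physiological range.
#' @param open_states character vector of conducting states.
#' @param g_single single-channel conductance (S).
#' @param reversal reversal potential (V).
#' @param initial named fractions per state at initialization (defaults to
#'   all channels in the first state).
#' @export
channel <- function(name, states, transitions, open_states = character(0),
                    g_single = 0, reversal = 0, initial = NULL) {
  stopifnot(length(states) >= 1)
  for (tr in transitions) {
    if (!all(c(tr$from, tr$to) %in% states)) {
      stop(sprintf("channel '%s': transition connects undeclared state", name),
           call. = FALSE)
    }
  }
  if (!all(open_states %in% states)) {
    stop("open_states must be declared states", call. = FALSE)
  }
  if (is.null(initial)) initial <- stats::setNames(
    c(1, rep(0, length(states) - 1L)), states)
  structure(list(name = name, states = states, transitions = transitions,
                 open_states = open_states, g_single = g_single,
                 reversal = reversal, initial = initial), class = "sim_channel")
}

#' Declare a membrane on a patch
#'
#' Passive electrical properties plus channel populations.  All surface
#' densities are multiplied by the mesh's per-patch `surface_scale` at
#' binding (the cylinder-correction ratio for generated cable meshes).
#'
#' @param patch patch tag.
#' @param capacitance specific membrane capacitance (F/m^2).
#' @param leak leak conductance (S/m^2).
#' @param leak_reversal leak reversal potential (V).
#' @param channel_densities named numeric: channels per m^2, by channel name.
#' @export
membrane <- function(patch, capacitance, leak = 0, leak_reversal = 0,
                     channel_densities = c()) {
  if (capacitance <= 0) stop("membrane capacitance must be > 0", call. = FALSE)
  if (leak < 0) stop("leak conductance must be >= 0", call. = FALSE)
  structure(list(patch = patch, capacitance = capacitance, leak = leak,
                 leak_reversal = leak_reversal,
                 channel_densities = channel_densities), class = "sim_membrane")
}

#' Stochastic rate-constant conversion
#'
#' Converts a declared macroscopic rate constant to the per-event propensity
#' coefficient `c` of the stochastic kinetics.  Order 1: `c = k` (s^-1).
#' Order 2: `c = k_SI / (N_A * V_litres)` with `k_SI` in 1/(M s); for
#' symmetric reactants (A + A) the `n (n - 1) / 2` combination count is
#' applied in the propensity, not here.
#'
#' @param k rate constant in `unit`.
#' @param order total reactant order (1 or 2).
#' @param volume element volume in m^3 (required for order 2).
#' @param unit `"per_s"`, `"per_M_s"` or `"per_uM_s"`.
#' @return Propensity coefficient `c` (s^-1 per reactant combination).
#' @examples
#' stochastic_rate_constant(10, 1)                      # 10
#' stochastic_rate_constant(1000, 2, 1e-18, "per_uM_s") # ~1.66
#' @export
stochastic_rate_constant <- function(k, order, volume = NULL, unit = "per_s") {
  unit <- match.arg(unit, c("per_s", "per_M_s", "per_uM_s"))
  if (order == 1) {
    if (unit != "per_s") stop("first-order rates must be in per_s", call. = FALSE)
    return(k)
  }
  if (order != 2) stop("only orders 1 and 2 are supported", call. = FALSE)
  if (is.null(volume) || volume <= 0) {
    stop("order-2 conversion needs a positive volume", call. = FALSE)
  }
  k_si <- switch(unit, per_M_s = k, per_uM_s = k * 1e6,
                 stop("second-order rates must be per_M_s or per_uM_s",
                      call. = FALSE))
  k_si / (AVOGADRO * volume * 1e3)   # volume m^3 -> litres
}

#' Largest-remainder rounding of nonnegative reals to integers
#'
#' Returns integers summing to `round(sum(x))`, each within 1 of `x`:
#' floors first, then distributes the remaining units to the largest
#' fractional parts.  Used to convert channel density x area products to
#' per-triangle channel counts without systematic truncation bias.
#'
#' @param x nonnegative numeric vector.
#' @return Integer vector, `sum == round(sum(x))`.
#' @export
largest_remainder_round <- function(x) {
  stopifnot(all(x >= 0))
  fl <- floor(x)
  rem <- round(sum(x)) - sum(fl)
  out <- fl
  if (rem > 0) {
    frac <- x - fl
    give <- order(frac, seq_along(x), decreasing = TRUE)[seq_len(rem)]
    out[give] <- out[give] + 1
  }
  as.integer(out)
}
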