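---
title: "Methods: operator-splitting stochastic reaction-diffusion with a membrane-potential solver"
author: "tetsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: operator-splitting stochastic reaction-diffusion with a membrane-potential solver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model class

tetsim simulates reaction–diffusion systems in which discrete molecules
react inside the tetrahedra of an unstructured mesh, hop between
face-adjacent tetrahedra, bind to and unbind from membrane triangles,
gate ion channels, and drive (and are driven by) a transmembrane
potential defined on the mesh vertices.  The chemistry is sampled exactly
from the chemical master equation *within* short time windows; diffusion
and voltage are advanced *between* windows.  This operator splitting is
what makes the scheme practical: reactions need no communication between
spatial regions inside a window, diffusion is a single synchronized
exchange per window, and the voltage solve is a sparse linear system per
(longer) voltage window.

The nested schedule is:

* the requested span is cut into **EField windows** of length
  `efield_dt` (or a single window when no membrane potential is
  simulated);
* each EField window is cut into **reaction–diffusion (RD) windows** of
  length `dt_rd = min(efield_dt, alpha_rd / max_total_diffusion_rate)`;
* inside an RD window the SSA operator fires kinetic events in exact
  time order, then the diffusion operator moves molecules and
  synchronizes, then propensities affected by the moves are repriced;
* at each EField window end, one implicit voltage step is taken and all
  voltage-dependent rate coefficients are refreshed at the new (frozen)
  voltage.

Window edges are integer multiples of the window lengths (never
accumulated by repeated addition), so the state time lands exactly on
the requested end time and long runs do not drift.

## Kinetic processes and the next-reaction method

Binding a model to a tagged mesh enumerates every *kinetic process*: a
volume reaction instance per tetrahedron, a surface reaction / channel
transition / GHK flux instance per patch triangle.  Each process carries
a per-event coefficient `c` (the stochastic rate constant), reactant
state indices, and a sparse effect list.  Propensities follow
mass-action combinatorics: `a = c n` (first order), `c n_A n_B`
(distinct pair), `c n (n - 1) / 2` (symmetric pair).  Second-order
declared constants in 1/(M s) or 1/(uM s) convert as
`c = k_SI / (N_A V_litres)` with the element's own volume.

The default SSA operator is the Gibson–Bruck next-reaction method:
absolute next-firing times in an indexed binary min-heap, one heap per
scheduling group.  Standard details that the method's name does not pin
down are resolved as follows:

* the fired process always redraws a fresh exponential;
* a non-firing process whose propensity changes from `a` to `a'`
  rescales its pending time, `t' = t + (a/a')(t_pending - t)`;
* a process whose propensity drops to zero parks at `+Inf`; one that
  resuscitates from zero draws fresh;
* heap ties break by process id, so a fixed seed yields a bit-identical
  trajectory;
* times drawn beyond the window end are *kept* (absolute-time
  semantics make them valid pending times), not rejected and redrawn.

A direct-method operator (cumulative propensity selection) is included
as an alternative implementation of the same jump process; the test
suite verifies that the two operators produce distributionally
indistinguishable outcomes (two-sample Cramér–von Mises), which checks
the queue bookkeeping against an implementation with none.

The *dependency graph* has an edge p → q when firing p changes a count
that enters q's propensity.  Its weakly connected components cannot
interact within an RD window, so each component can optionally be
scheduled with its own queue (`use_components = TRUE`).  This is a
performance lever only: on/off equivalence is part of the test suite.
It is off by default because its benefit depends on how many drawn
events actually land inside a window, which varies strongly across
heterogeneous models.

## Diffusion operator

For tetrahedron i, diffusive species s with coefficient D, and
face-neighbour k with shared area `A_k` and barycenter distance `h_k`,
the hop rate is the standard voxel coupling `d_k = D A_k / (V_i h_k)`,
`d_tot = sum d_k`.  Per RD window of length `dt`, each (tetrahedron,
species) population loses `Binomial(n, 1 - exp(-d_tot dt))` molecules —
the exact law of first exit for independent molecules when return hops
within the window are ignored — split multinomially over neighbours with
probabilities `d_k/d_tot`.  Boundary faces are sealed (reflective),
which is also the geometry all shipped validation fixtures assume.

The windowed operator converges to the diffusion master equation as the
window shrinks.  At the default safety factor `alpha_rd = 1` (window =
inverse of the fastest total hop rate) the stationary occupancy of
strongly volume-heterogeneous neighbours is measurably biased, because
`1 - exp(-d dt)` compresses fast rates more than slow ones; statistical
validation against master-equation oracles therefore runs at
`alpha_rd = 0.05`, and `alpha_rd` is an explicit configuration knob with
units of "maximum expected exit fraction per window".

## Emulated distribution: partitions, ghosts, delta state, RNG streams

The mesh is partitioned by recursive coordinate bisection over
barycenters (longest axis, median split, id tie-break), for a power-of-2
rank count; each rank ghosts the face-adjacent tetrahedra it does not
own.  The single-process engine emulates the distributed loop exactly:
the SSA phase runs per rank on that rank's own RNG stream (streams are
seeded `seed + rank - 1` and swapped in and out around each phase);
diffusion removes molecules from owned tetrahedra immediately but stages
*all* destination increments in a delta state keyed by destination rank;
a distinct synchronization step then applies every staged delta at once.
No cross-rank state mutates mid-window, a property the scheduler's
instrumentation hooks let the tests assert, and per-species totals are
conserved to exact integer equality.  Rank-count invariance is tested
two ways: the deterministic passive-cable pipeline must agree between 1
and 4 ranks to 1e-10 V, and stochastic diffusion outcomes for 1 versus 4
ranks must pass the Cramér–von Mises equivalence check.

## Membrane potential

The potential lives on mesh vertices.  Volume conduction is a linear
(P1) finite-element stiffness matrix with conductivity `1/Ra`
(intracellular resistivity `Ra`); membrane capacitance and leak are
lumped to vertices with one third of each membrane triangle's area.  One
EField window advances the voltage by a single backward-Euler step

```
(C/dt + K_vol + G_mem) v' = (C/dt) v + G_mem-weighted reversals + I_inj + I_GHK(v)
```

Ohmic channel currents (open-channel count × single-channel conductance,
frozen over the step) enter implicitly through `G_mem` — this keeps the
step unconditionally stable — while GHK currents are evaluated
explicitly at the pre-step voltage, a linearization that the test suite
bounds against small-step references.  The factorization is a sparse
Cholesky; for passive systems it is computed once, for active systems
the (pattern-preserving) matrix is refactored every step.  A
conjugate-gradient path was considered and rejected at this scale: the
refactor cost is negligible against the per-step assembly.  The
singular case (no capacitance anywhere) raises an error that suggests
grounding a reference vertex rather than returning garbage.

Channel state populations are ordinary surface species, so channel
gating is simulated by the same exact SSA machinery as the chemistry,
with voltage-dependent coefficients refreshed at EField window starts.
The refresh point is a documented convention: voltage is a constant
between voltage steps, so the window start is the only physically
distinguished choice.

Temperature enters only the GHK `RT/F` factors (default 293.15 K,
configurable per model).

## The benchmark fixtures and the study conditions

**Passive cable.**  A 1 mm cable of nominal diameter 1 um, leak
0.25 S/m^2 toward −65 mV, axial resistivity 1 Ohm m, specific
capacitance 0.01 F/m^2, 0.1 nA injected at one end, voltage step 5 us,
250 ms span.  The generated mesh is a square-section prism whose
cross-section area equals the cylinder's (`side = sqrt(pi) d / 2`), and
all membrane surface densities are multiplied by the recorded ratio
`rho = (cylinder lateral + cap area) / (mesh surface area)` so that
total membrane conductance and capacitance per unit length match the
ideal cylinder the analytic solution assumes.  The analytic reference is
the sealed-end cable solution: a `cosh` steady state plus a cosine
eigenfunction series, truncated when the next term's amplitude bound
falls below 1e-9 V, and cross-checked in the tests against an
independent Crank–Nicolson finite-difference solver to under 1 uV.  The
default fixture resolution is 200 axial segments (1,200 tetrahedra,
at and above the reference resolution of this benchmark); the end caps
carry membrane leak that the analytic solution lacks, which sets the
observed error floor (about −0.07 mV at steady state) well inside the
benchmark's published error.

**Stochastic Hodgkin–Huxley cable.**  The passive fixture plus Na
(8-state, m^3 h) and K (5-state, n^4) channels with the classic
squid-axon alpha/beta rate forms shifted to a −65 mV rest, reversal
potentials +50/−77 mV, and maximal conductance densities 1200 and
360 S/m^2.  Only the single-channel conductance is a free scale: channel
counts per triangle are `density x area / g_single`, largest-remainder
rounded so patch totals are exact.  The benchmark condition is 4 pS over
250 ms — about 10^6 channels, which is deliberately not a default run
here; the shipped checks use (a) the deterministic (infinite-channel)
limit of the same stepping scheme against a `deSolve` ODE integration
(within 1 mV over a spiking 25 ms trace at a 0.25 us step), and (b) a
scaled stochastic run — 10 axial segments, 400 pS, 25 ms, about 12,000
channels and 3x10^5 gating events — which must produce at least one
z_max spike above +40 mV with valleys near −65 mV.

**Ten-species benchmark.**  Species A..J, diffusion 100..10 um^2/s,
initial counts 1,000..10,000 scaled by 0.01–100, four reversible
reactions with the printed forward/backward constants.  The companion
cuboid is 10 x 10 x 100 um; at resolution 6 x 6 x 60 the generator
yields 12,960 tetrahedra, approximating the benchmark's ~13,000-element
mesh (the original mesh is not distributed with the benchmark, so the
dimensions are this package's choice of a biologically plausible
dendrite-sized cuboid at matching element count).

**Two-tetrahedron GHK toy.**  Two face-adjacent tetrahedra with the
cyclic volume chemistry A→B→C→A, C exchange between the first
tetrahedron and a membrane triangle, and a bidirectional GHK flux of C
(fixed outer concentration; the outer side is not modelled as
molecules).  Rates default to 1 s^-1 — the toy exists to exercise
surface kinetics, GHK propensities and the dependency-graph
decomposition (two components, sizes 7 and 3), not to reproduce numbers.

## Statistical validation framework

Stochastic simulators cannot be validated by comparing seeded
trajectories.  The framework here compares *distributions*:

* **Feature extraction**: peak heights and peak timestamps from voltage
  traces (local maxima filtered by prominence, default 10 mV, and
  separation, default 2 ms — spike trains in the active cable benchmark
  swing ~85 mV at ~69 Hz, so these defaults are far from both noise and
  spike spacing); spike frequency is `(n_peaks - 1) / (t_last -
  t_first)`.
* **Batched two-sample Cramér–von Mises testing**: each sample set is
  cut into batches (100 x 100 in the benchmark protocol) and every
  cross pair is tested, giving 10,000 p-values whose distribution under
  the null is uniform — the diagnostic is distributional, not a single
  accept/reject.  The null is rejected only when significantly more
  than 1% of p-values fall below 0.01 (three binomial sigma).  The
  statistic uses midranks (ties allowed); p-values come from the
  limiting distribution with Anderson's finite-sample moment
  normalization, evaluated through Bessel-K series, with a Monte-Carlo
  permutation null below 20 observations per sample where the
  asymptotic is poor.  "Exact" enumeration of permutations is
  deliberately not attempted: it is infeasible beyond toy sizes and the
  permutation null at 2,000 resamples already gives p-value resolution
  well below the decision levels used.
* **Confidence-band comparison** for smooth traces: pointwise
  mean ± t-quantile bands at 99%; an ensemble's mean must stay inside
  the other's band on all but a tolerated fraction of time points.
  The tolerance (default 15%) sits above the ~6% of exits expected
  under the null, because a pointwise band brackets the true mean while
  the compared quantity is itself a noisy ensemble mean.

## Containers and identifiers

All fixed-shape key→values tables (tetrahedron neighbourhoods,
dependency edges, reactant reverse maps) use the flat-multimap: an
offset array `a2ab` plus a contiguous value array `ab2c`, exactly two
allocations, shape fixed at construction.  A property suite checks it
against a nested-list reference on a thousand random multisets.  Public
interfaces take vocabulary-typed ids (`entity_id(v, "tet")` etc.);
mixing kinds is an immediate error.  Internally indices are 1-based (R's
native convention; mesh files' numbering is converted at the I/O
boundary), and molecule counts are doubles holding exact integers —
R has no native 64-bit integer and doubles are exact to 2^53, far above
the count scales any shipped model reaches (~10^6).

## Problem sizes used by the shipped checks

The package's own validation runs at desk scale by design: the passive
cable at 200 axial segments for the full 250 ms / 5 us protocol; the
null-distribution study with 2 x 10,000 single-tetrahedron runs of a
reversible isomerization (1,000 molecules, 50 ms); the scaled active
cable as above.  These sizes were chosen so that each check sharply
separates a correct implementation from a broken one; larger meshes and
the full 4 pS channel count change cost, not correctness, and the
fixtures expose the resolution and conductance scale as arguments for
anyone wanting the overnight-scale versions.

## Known limitations

* Surface (triangle-to-triangle) diffusion is not supported; membranes
  exchange with their inner tetrahedra only.
* Reactions above order two are rejected at declaration.
* The GHK explicit evaluation assumes ionic concentrations change slowly
  over one EField window; extremely permeable membranes with tiny
  compartments would need a shorter window.
* The windowed diffusion operator is first-order accurate in the window
  length; `alpha_rd` must be reduced for quantitatively unbiased
  stationary occupancies on strongly graded meshes (see above).
* One process emulates many ranks faithfully but serially; the
  partition machinery exists for semantic fidelity (ownership, ghosts,
  staged synchronization), not for speed.
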