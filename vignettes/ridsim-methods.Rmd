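---
title: "Brownian dynamics of reacting, interacting rigid bead molecules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brownian dynamics of reacting, interacting rigid bead molecules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ridsim` simulates coarse-grained molecular systems in which every molecule
is a rigid assembly of beads that diffuses, rotates, interacts through
short-ranged pair potentials, and undergoes stochastic reactions, optionally
confined by triangulated mesh compartments. This vignette is the package's
account of the underlying models, the numerical choices, and what the
validation suite does and does not establish.

## Units

Lengths are nm, times ns, energies kJ/mol. The Boltzmann constant is then
`KB = 0.008314462` kJ/(mol K) and thermal energy at the default 293.15 K is
kT = 2.437 kJ/mol. Dynamic viscosity carries the units kJ ns/(mol nm^3); the
default of 0.6022 is water near 20 C: 1 mPa s = 1e-3 J s/m^3, multiplied by
Avogadro's number and converted (1 m^3 = 1e27 nm^3, 1 s = 1e9 ns) gives
6.022e20 / 1e27 * 1e9 / 1e3 = 0.6022. A 1 nm radius sphere then gets
D = kT/(6 pi eta r) = 0.215 nm^2/ns, the textbook value.

## Rigid bead molecules and their diffusion tensors

A molecule type is an immutable body-frame geometry: beads with positions and
hydrodynamic radii, plus optional zero-radius "patch" particles that act as
interaction and reaction sites. `compute_diffusion_tensor()` derives the
6x6 rigid-body diffusion tensor from the bead geometry by the standard
bead-model supermatrix method:

1. the 3N x 3N pair mobility matrix with Rotne-Prager-Yamakawa blocks
   (the unequal-radii form, with the standard overlap corrections, so
   overlapping beads are permitted);
2. inversion to the friction supermatrix and contraction to the 6x6
   rigid-body friction tensor at the input origin;
3. the volume correction `6 eta V` on the rotational block, which restores
   the rotational friction a point-force model misses (exact for a single
   sphere: it alone yields the rotational Stokes friction `8 pi eta a^3`);
4. inversion to the diffusion tensor and a congruence shift to the center
   of diffusion -- the unique point where the translation-rotation coupling
   block is symmetric, found by solving the 3x3 linear system
   `skew(d) D_rr + D_rr skew(d) = D_tr - D_rt`.

All body-frame coordinates are recentred on the center of diffusion; it is
the reference point the integrator propagates and the point the molecular
virial uses. The test suite pins this machinery to closed forms: the
translational and rotational Stokes-Einstein relations for a single sphere
to better than six digits, and a hand-derived 2x2 block inversion for the
symmetric two-bead dumbbell (axial/transverse translation, tumbling and
spinning rotation), which exercises every stage of the supermatrix pipeline.
The coupling block `D_tr` is computed and stored but not used by the
propagator; for the symmetric bodies used in validation it is identically
zero, and for typical bead models its effect on short-time displacement
statistics is far below the sampling noise the validation operates at.

## Propagation

The integrator is first-order Euler-Maruyama for overdamped rigid-body
motion, evaluated in the body frame:

* translation: `dx_b = (D_tt F_b / kT) dt + xi`, `xi ~ N(0, 2 D_tt dt)`
  (Cholesky factor of `2 D_tt dt`), rotated to the world frame and added to
  the center-of-diffusion position;
* rotation: a body-frame rotation vector `dw_b = (D_rr T_b / kT) dt + xi_r`,
  `xi_r ~ N(0, 2 D_rr dt)`, applied by right quaternion multiplication and
  renormalized every step (norms stay unit to 1e-9 over arbitrarily long
  runs).

Rotational noise is sampled in the body frame, where `D_rr` is constant;
this is the natural frame for anisotropic rotors and makes the per-axis
displacement statistics directly testable: the per-axis variance of one step
from identity orientation equals `2 D_ii dt`, and the long-time MSD slope is
`6 Tr(D_tt)/3 t`. Isotropic point-like species skip the rotation update by
default (their orientation is dynamically irrelevant); it can be forced on
to measure rotational correlations, which for an isotropic rotor decay as
`exp(-6 D_r t)`.

Hydrodynamic coupling *between* molecules is out of scope: the pair mobility
enters only the per-type tensor computation, never the many-body dynamics.

## The step cycle

One `simulation_step()` performs, in this order:

1. position/orientation update for every molecule, including mesh collision
   response and the box boundary condition;
2. one sweep over all neighbor pairs that accumulates forces, torques and
   the scalar virial *and* collects the in-range bimolecular candidate
   events;
3. the Berendsen barostat, when active (it uses the virial pressure just
   computed);
4. expired unimolecular timers are added to the event list;
5. all events execute in uniformly random order drawn from the dense event
   index; an event whose educt was consumed earlier in the order is
   invalidated (removal of all events of one educt is an O(1)-per-event
   linked-chain operation).

Forces are *not* recomputed after reactions: products diffuse force-free in
their first step, and product placement does not resolve collisions. Both
approximations vanish as the time step shrinks; they bias dense,
fast-reacting systems, which is why the kinetics validation operates in the
reaction-limited regime where the per-step reaction probability is small.
Binding is the one exception: the bond's rest length is evaluated at
execution time, and the bond force enters from the next sweep on.

Propagation uses the forces of the *previous* sweep; the first sweep happens
at run start so the initial step is consistent.

## Pair potentials

Four built-in kinds (all C1 at their cutoff), plus a two-function custom
contract (`U(r)`, `dU/dr(r)`):

* harmonic repulsion `U = k/2 (r - sigma)^2` below contact -- the
  excluded-volume workhorse; a stiff `k` approximates a hard sphere;
* the weak piecewise harmonic well (harmonic core joined to a C1 piecewise
  parabolic well of given depth closing at the cutoff);
* the continuous square well `-eps/2 (1 - tanh((r - rw)/delta))`;
* the pseudo hard sphere (cut-shifted 50-49 Mie).

Energy-force consistency is enforced by central finite differences in the
tests, and the compiled sweep kernel is required to agree with the R
reference evaluator exactly on random configurations.

Bead-bead forces map onto the owning molecules as a net force plus a torque
about the center of diffusion. The virial pressure is
`P = (N kT + W/3)/V` with the *molecular* virial
`W = sum F_ij . (R_i - R_j)` referenced to centers of diffusion (minimum
image), the appropriate reference for rigid-body Brownian dynamics. Only
pair terms (including bonds) enter `W`; external/wall contributions are
excluded, so NPT runs with mesh walls are not meaningful and the barostat is
intended for fully periodic systems.

## Neighbor search

Particles are binned into a hierarchical cell grid: one level per distinct
interaction diameter (capped at 8 levels, geometric binning beyond), each
level's cell size equal to the largest cutoff it hosts. A pair (i, j) is a
neighbor when `r_ij < (cutoff_i + cutoff_j)/2`; per-particle cutoffs are the
maximum over the particle type's pair potentials and reaction radii, so the
mixing rule bounds every pair gate from above. The same-level sweep visits
nearest-neighbor cells with an i < j ordering; the cross-level sweep scans
only levels with smaller cells over the exact cell range covered by the
search radius, so each pair is produced once (Newton's third law). Grids are
rebuilt every step (no Verlet skin; simplicity over constant-factor speed).
Correctness is pinned by exact set equality with O(N^2) enumeration over
random monodisperse, bidisperse and fully polydisperse configurations, in
periodic and closed boxes.

## Reactions

*Unimolecular channels* use exact lifetime sampling: with total rate
`k_t = sum k_i` over a molecule's paths, the waiting time is
`tau = ln(1/U)/k_t`, drawn once and stored as an absolute timer; the path
fires with probability `k_i/k_t` when the timer expires. Timers are redrawn
whenever the molecule's channel set changes (type conversion, particle
retyping) -- and, harmlessly by memorylessness, at run start. Executions are
aligned to the step at which the timer expires, consistent with the hybrid
discrete/event-driven scheme; the recorded lifetimes remain exponential to
within the step quantization, which the suite verifies by Kolmogorov-Smirnov
at a time step far below the mean lifetime.

*Bimolecular channels* are keyed by particle-type pairs (molecule-level
reactions are linked to a particle pair for the distance test). A pair
within the reaction radius fires with probability
`p = 1 - exp(-sum_i k_i dt)` per step, paths weighted by rate among those
whose radius covers the observed distance. Execution semantics:

* fusion: educts removed, product at the midpoint of the reacting particle
  pair (minimum image), orientation inherited from the first educt;
* enzymatic: the substrate molecule converts in place (identity and
  position kept), the enzyme is untouched (its particle is still limited to
  one reaction per step);
* binding: a persistent harmonic bond between the two particles with rest
  length equal to their distance at execution; unbinding is an exponential
  timer on the bond;
* fission: educt replaced by two products placed symmetrically about its
  center, separated by the dissociation radius along a uniform direction;
* production: educt kept, products placed on the dissociation-radius shell;
* release (particle scope): the product appears at the particle position
  plus the dissociation radius along a uniform direction;
* conversion/decay on particles retype only the affected particle (decay
  retypes to the inert `void` type), leaving the parent molecule alive.

The microscopic-macroscopic rate bridge is
`k_macro = 4 pi (D_A + D_B) [R - sqrt((D_A+D_B)/k) tanh(R sqrt(k/(D_A+D_B)))]`,
with the Smoluchowski limit `4 pi (D_A+D_B) R` as `k -> infinity` and the
reaction-limited limit `(4/3) pi R^3 k` as `k -> 0`; `solve_k_micro()`
inverts it by bracketed root finding on a log scale to 1e-12 relative. The
radius should satisfy `R >= lambda_AB = sqrt(4 (D_A+D_B) dt)` or partners
can tunnel past each other between sweeps; `lambda_AB()` warns when
violated. For multi-path channels sharing one particle pair, the converted
total `k_macro(sum k_i)` is split proportionally to the microscopic rates
when building mass-action comparators; for paths on distinct particle pairs
the encounter volumes convolve independently, and the orientation-averaged
encounter volume of offset patches equals that of centered ones, so
mass-action comparisons stay valid in the reaction-limited regime even for
structured molecules.

## Boundary conditions

*Periodic*: positions wrap into `[-L/2, L/2)` (half-open; the minimum image
of a separation uses the same convention), with image counts tracked so
trajectories are recorded unwrapped.

*Repulsive*: specular reflection at the box walls.

*Fixed concentration*: molecules crossing the box are deleted (outflux); the
influx per face per step is Poisson with mean `A (l_n/2) C`, where
`l_n = sqrt(4 D dt / pi)` is the mean one-sided displacement normal to a
plane per step. Each inserted molecule sits at a uniform point of the face,
displaced inward by `sqrt(pi) l_n x` with the normalized depth `x` drawn
from `P(x) = 1 - exp(-x^2) + sqrt(pi) x erfc(x)`. That expression is the
unique reading of the influx depth law that is a valid CDF: `P(0) = 0`,
`P(infinity) = 1`, and `dP/dx = sqrt(pi) erfc(x) >= 0` (the cross terms of
differentiation cancel exactly); the suite checks the sampled depths against
it by Kolmogorov-Smirnov. Inversion uses a 4096-knot monotone interpolant of
the CDF. Known approximations, inherited by design: inserted molecules are
not collision-checked against meshes closer than `l_n`; molecules outside
the box do not interact with each other or with inside molecules, so inside
and outside concentrations only match for ideal diffusers (which is exactly
what the stationarity test asserts). The engine wires volume species on the
six box faces; for surface species the same law applies with the boundary
edge length in place of the area (`influx_rate()` accepts either measure),
but transparent-edge re-emission of surface molecules is not wired into the
step cycle.

## Mesh compartments

Meshes are closed orientable manifolds in a shared-vertex structure with
per-triangle edge lists and neighbor tables; construction verifies that
every directed edge appears exactly once and every undirected edge twice
(consistent counterclockwise winding, outward normals), reporting offending
edges otherwise. A voxel grid over the mesh bounding box (default cell: two
mean edge lengths) backs the ray queries.

*Volume molecules* of point-like types resolve collisions by ray tracing:
the displacement is walked through the voxel grid (Amanatides-Woo stepping;
the first-hit result is required to match an exhaustive all-triangle scan in
the tests), and at each hit the remaining displacement reflects about the
triangle plane -- a purely geometric rule independent of the time step.
Reflection counts are capped at 50 (stuck-geometry error). Large bead models
instead feel harmonic contact forces from nearby triangles through the
point-to-triangle distance (Eberly's region classification, pinned in the
tests to an independent closed-form oracle); the per-type choice is the
`mesh_collision` flag, defaulting to reflection for point-like species.

*Surface molecules* live on a triangle with their body z-axis along its
normal. A tangent-plane Gaussian displacement (plus the tangential force
drift) is transported by surface ray marching: the first crossed edge is
found from the barycentric line parameters, the position advances to the
edge, and the residual displacement and the molecule orientation rotate
about the shared edge by the dihedral angle into the neighbor's plane --
equivalent to unfolding the two faces into a common plane, so walkers
follow straight lines in the unfolded picture and geodesics on the surface,
with path length conserved exactly (the rotations are isometries; the cube
unfold test checks the final point to 1e-9). Displacements through a vertex
are measure-zero ties resolved by nudging 1e-9 toward the triangle interior.
Positions are re-projected onto the new triangle plane after each crossing
to stop floating-point drift.

Inside/outside classification uses ray parity with degenerate hits (near
triangle edges) re-tried under direction jitter.

## Barostat

Isotropic Berendsen coupling: `mu = (1 - (dt/tau_P)(P0 - P))^(1/3)`; box
lengths and molecule centers scale by `mu`, bead geometry stays rigid. The
sign convention is fixed by self-consistency: pressure below target gives
`mu < 1`, compression, rising pressure. The instantaneous virial pressure
enters directly (no smoothing window); `tau_P` must exceed `dt`, and the
validation uses `tau_P = 5 ns` at `dt = 0.1 ns`, reaching the target in a
few ns without overshoot. `mu^3 <= 0` raises an instability error advising a
smaller `dt/tau_P`. The barostat trades ensemble exactness for relaxation
speed -- pressure fluctuations are damped relative to a true NPT ensemble --
which is fine for its intended uses (equilibrating to a target density).

## Placement

*Poisson-disc sampling* (volumes): Bridson's active-list algorithm
generalized to polydisperse radii -- the pairwise minimum distance is
`r_i + r_j`, candidates are drawn uniformly from the annulus *volume*
`[r_a + r_new, 2(r_a + r_new)]` around a random active point, with k = 30
trials before an active point retires, and species drawn uniformly among
those below quota. Run to exhaustion it saturates monodisperse systems at a
volume fraction of about 30% -- the method's well-known density limit, which
the acceptance benchmark measures (the suite asserts the 25-32% band around
it).

*Dense packing*: uniform random insertion followed by pairwise projection --
steepest descent on the harmonic overlap energy with the per-pair exact step
(a 2% over-projection accelerates convergence) -- until the largest relative
overlap is below 1e-3; dense targets start in a box inflated by 25-30% that
anneals down by 0.15-0.2% per relaxed sweep. The two-component benchmark
(radii 10 and 2.5 nm, 75 nm box) packs to 53% overlap-free in a few hundred
sweeps.

*Surfaces*: area-weighted triangle selection with the square-root
barycentric transform for uniformity, optional dart-throwing thinning to a
minimum distance, and optional face-group restriction.

## Containers

Molecule state lives in tightly packed arrays with pop-and-swap deletion and
an id-to-index map (external ids are monotonically issued and never reused,
so trajectories can follow individuals across churn); slot-stable storage
uses the dynamic array with holes with a LIFO free list; both grow by
doubling. The per-step reaction list embeds four doubly linked chains (two
molecule educts, two particle educts) into a holey array with a dense index
for unbiased uniform random selection; clearing all events of one educt
walks only that educt's chain. All three containers are validated against
naive shadow models under random churn, and uniformity of the random pick is
chi-square tested.

## Reproducibility

A run seeds R's RNG once (`run_simulation()` uses the simulation's seed), so
equal seeds give bit-identical trajectories. This is a deliberate
simplification relative to per-molecule counter-based noise streams: under
reaction churn, deleting one molecule shifts the noise sequence of others
between seeds with different reaction outcomes, which is acceptable here
because no analysis in the package relies on cross-run noise alignment --
determinism of the *whole* run is what the contract (and the test) demands.

## Validation scale and scope

The suite and the acceptance script run at desk scale, chosen so every
stochastic assertion retains a comfortable error budget: fluids of ~600
particles (packing fraction 0.3, 8-10 nm boxes), reaction networks of
500-800 molecules over 2-4 us of simulated time, 1000 surface walkers for
250 steps, displacement ensembles of 1e5. Monte-Carlo tolerances are stated
as multiples of the relevant standard error (3-4 sigma), and kinetic
comparisons bound deviations by `4 sqrt(reactions so far)` -- the scale of
the accumulated birth-death noise.

The hard-sphere comparisons approximate the hard core by harmonic repulsion.
Stiffness and time step are chosen together a priori: stability of the
overdamped update requires `D k dt / kT` of order 0.3 or below, and fidelity
to the hard sphere is judged by the Barker-Henderson effective diameter
`d = integral of (1 - exp(-U/kT))`. The structural benchmarks use
`k = 1e4 kJ/(mol nm^2)` at `dt = 8e-4 ns` (d = 0.980 sigma), for which
structure and pressure sit within the 10% bands around the Percus-Yevick
contact value and the Carnahan-Starling equation of state at the nominal
packing fraction; the NPT benchmark follows the printed conditions
(`dt = 0.1 ns`, D = 0.0859 nm^2/ns), which force the soft `k = 100` -- fine
there, because the barostat target is a pressure, not a structure.

What passing these benchmarks shows: the diffusion tensors, propagator,
neighbor search, potentials, virial, barostat, reaction scheduling and
geometry kernels are mutually consistent and quantitatively correct against
closed-form physics at modest densities and reaction-limited rates. What it
does not show: fidelity for strongly diffusion-limited kinetics under dense
crowding (where the step-cycle approximations bite and only qualitative
behavior -- slower-than-mass-action association under excluded volume -- is
asserted), hydrodynamic coupling between molecules (not modeled), detailed
balance of reversible reactions (not enforced), or realistic biological
parameter regimes, which real applications must justify separately.

## Known limitations

* No angular or torsion potentials; pair potentials and rigid geometry only.
* No long-range electrostatics.
* Reactions between surface molecules use Euclidean, not geodesic,
  distances.
* The barostat does not sample the exact NPT ensemble and ignores meshes.
* Surface-species influx through transparent mesh elements is not wired
  into the step cycle (the influx law itself is exposed and tested).
* Trajectories persist to CSV/XYZ text containers; binary trajectory
  formats are out of scope.
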