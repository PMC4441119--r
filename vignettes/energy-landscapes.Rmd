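---
title: "Energy-landscape methods for intrinsically disordered peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-landscape methods for intrinsically disordered peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktnet)
```

## The problem this package addresses

Intrinsically disordered proteins (IDPs) have no single native fold: their
equilibrium ensemble is a set of very different, comparably low-lying
conformations separated by substantial barriers. On the potential energy
landscape this appears as a *multifunnel* organisation, and it has direct
kinetic consequences — for example, a BH3 peptide that is helical when bound
to its partner can be almost never helical in isolation because the helix
funnel is narrow, high-lying, and slow to enter. Characterising such a
landscape requires a chain of methods: global optimisation to find minima,
double-ended searches for the transition states between them, a database
(kinetic transition network, KTN) that organises the stationary points,
superposition thermodynamics and phenomenological rates over that network,
and projections (disconnectivity graphs, free-energy surfaces) that make the
organisation visible.

`ktnet` implements that chain end to end at desk scale. Every stage is
exercised on systems small enough that exact answers are available — analytic
two-dimensional surfaces, Lennard-Jones clusters, synthetic networks with
known master-equation kinetics, and a coarse-grained charged bead peptide
whose landscape is multifunnel by construction. The package's tests therefore
verify the *methodology* against independent oracles; they do not claim
quantitative agreement with any particular all-atom system.

## Model systems

### Analytic surfaces

`build_surface("muller_brown")` is the standard four-Gaussian two-dimensional
surface, with minima at energies $-146.700$, $-108.167$ and $-80.768$ and two
index-1 saddles at $-72.249$ and $-40.665$ (reduced units). It is the
canonical correctness fixture for minimisation, band searches and
eigenvector-following. `double_well_1d` ($V = x^4 - x^2$) supplies closed
forms for every stationary-point quantity. `lj_cluster` is the pairwise
$4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]$ cluster in reduced units
($\epsilon = \sigma = k_B = 1$); LJ$_7$ ($-16.505384\,\epsilon$) and LJ$_{13}$
($-44.326801\,\epsilon$) are the global-optimisation benchmarks.

### The charged bead peptide

The bead peptide is the package's stand-in for a disordered peptide with
mixed hydrophobic and charged residues. One bead per residue, four types
(`H` hydrophobic, `P` polar, `+`, `-`), and five energy terms:

| term | form | default |
|------|------|---------|
| bonds | $k_b (r - r_0)^2$ | $k_b = 100$ kcal/mol/Å², $r_0 = 3.8$ Å |
| angles | $k_a (\theta - \theta_0)^2$ | $k_a = 10$ kcal/mol/rad², $\theta_0 = 95^\circ$ |
| torsions | $k_t\,[1 - \cos(\phi - \phi_0)]$ | $k_t = 1$ kcal/mol, $\phi_0 = 50^\circ$ |
| van der Waals | LJ, $|i-j| \ge 3$ | $\epsilon_{HH} = 1$, $\epsilon$ other $= 0.2$ kcal/mol, $\sigma = 4.5$ Å |
| electrostatics | $332.06\, s\, q_i q_j e^{-r/\lambda}/r$ | $s = 1$, $\lambda = 10$ Å |

Units are kcal/mol, Å and K ($k_B = 0.0019872041$ kcal/mol/K). The default
13-bead sequence `H+HH-HH+H-HPH` mixes two positive and two negative charges
among hydrophobics. The torsional bias makes the ideal helix
(`helix_configuration()`) a genuine local minimum with 100% helicity; the
Debye-screened Coulomb term rewards collapse, so the global minimum is a
partially helical globule roughly 24 kcal/mol below the helix in which the
electrostatic term accounts for more than the whole relaxation (the
bonded/torsional terms oppose it and van der Waals changes are small). That
ordering — electrostatics driving helix unfolding, van der Waals nearly
neutral — is the qualitative behaviour the model is built to emulate, and the
default interaction strengths were chosen once to realise it: with much
weaker electrostatics (e.g. a dielectric scale of 0.25) the torsional bias
wins and the landscape degenerates to a single helix funnel, which defeats
the purpose of a multifunnel test system.

What the bead model does *not* emulate: backbone hydrogen bonding,
side-chain packing, solvent ordering, or any residue-specific chemistry.
Passing tests on it show that the landscape machinery is correct, not that a
real peptide has these energies.

### Synthetic transition networks

`generate_synthetic_ktn()` builds funnel-structured networks with prescribed
bottom energies, intra- and inter-funnel barriers, and seeded jitter on the
log frequency products. Because the network's harmonic TST rates define an
exact master-equation generator, every kinetic quantity downstream has a
linear-algebra ground truth. A high, narrow funnel (few minima, high bottom)
next to a deep, wide one reproduces the fold/unfold asymmetry of a helix
funnel competing with molten-globule funnels.

## Geometry optimisation

Minimisation is L-BFGS (memory 8, Armijo backtracking) converged on the RMS
gradient, default $10^{-4}$ kcal mol$^{-1}$Å$^{-1}$ (or reduced equivalent).
Built-in families run a compiled implementation; closure surfaces fall back
to `stats::optim`. Two numerical guards matter in practice: near float
precision the energy can no longer resolve the Armijo decrease, so a step
that lowers the gradient norm at (numerically) equal energy is accepted; and
if the RMS gradient stalls for 200 iterations the curvature memory is
dropped once before the run is declared unconverged — stale curvature pairs
were the dominant cause of spurious non-convergence on the 39-dimensional
bead peptide.

Basin-hopping perturbs the current minimum, re-minimises, and applies a
Metropolis test on minimised energies. Moves: uniform Cartesian displacement
(default half-width $0.4\sigma$-equivalent) and, for chains, pivot rotations
of the shorter arm about a random backbone bond (up to $\pm 60^\circ$).
Move type is chosen uniformly each step. The acceptance temperature and step
sizes are method parameters, not physical temperatures; defaults (reduced
temperature 1 for clusters) were fixed before any success-rate accounting.
An optional `target_energy` stops a run early once the target has been
reached, which changes wall time but not whether a given seed succeeds. The
acceptance fraction is reported over steps whose quench converged.

## Transition states and connections

Double-ended candidates come from a doubly-nudged elastic band: interior
images feel the perpendicular component of the true gradient, the parallel
spring force, and the retained perpendicular spring component that stabilises
the plain nudged band. The band is relaxed with FIRE rather than a
quasi-Newton scheme — the doubly-nudged force is not the gradient of any
scalar objective, and curvature-based steps on it proved unstable (images
ejected from the interaction region on stiff surfaces), while FIRE with a
trust-capped displacement is robust. Defaults: 11 interior images, spring
constant 10, band RMS-force tolerance $10^{-3}$.

Candidates (interior band maxima) are refined by eigenvector-following:
diagonalise the Hessian with the rigid-body zero modes projected out, take a
Newton (or trust-radius uphill) step along the lowest non-zero mode, then
minimise in the orthogonal complement; the trust radius doubles or halves on
the predicted-versus-actual energy-change ratio (thresholds 0.75/0.25,
initial radius $0.1\times$ the geometric scale). The full eigendecomposition
is used instead of a gradient-only Rayleigh–Ritz estimate: at $\le 40$
degrees of freedom the finite-difference Hessian is cheap, the index check
requires the spectrum anyway, and the explicit spectrum makes the
"exactly one negative non-zero eigenvalue" invariant verifiable at every
insertion. A converged saddle is connected to its two minima by displacing
$\pm 0.01\times$ scale along the negative mode and minimising.

`connect_minima()` grows the database until two endpoints are linked:
Dijkstra on a mixed graph (existing transition-state edges free, missing
pairs weighted by squared distance) proposes the gap to attack, a
DNEB/refine/descend cycle runs across it, and every converged stationary
point is inserted. Repeated attempts at the same gap escalate the image
count. The refinement drivers reuse this machinery: SHORTCUT BARRIER
reconnects the minima one step beyond the pair flanking the highest barrier
on the current fastest path (the leapfrog lets the band discover a direct
lower saddle that bypasses the barrier region), until successive
graph-transformation rates agree within a factor of 10; UNTRAP ranks minima
by (minimax barrier to the product set)/(energy above the product set) —
disconnected minima rank first, minima level with the product set rank by
barrier alone — and reconnects the worst offender to the nearest product
minimum.

## The database and its identity rule

Two minima are the same record iff their energies differ by less than
$10^{-6}$ and their superposition RMSD (Kabsch, proper rotations, no
permutations) is below $10^{-3}$ — both well inside optimiser precision.
Permutational isomers count separately, as appropriate for a peptide whose
beads are distinguishable. Frequencies (as $\sum \ln \nu$ over positive
normal modes, unit masses, $\nu = \sqrt{\lambda}/2\pi$) are computed once at
insertion. Persistence is plain text: `min.data`/`ts.data` rows (energy,
log-product, 1, connectivity, placeholders) at 17 significant digits plus an
extended-XYZ coordinate archive keyed by id, so a round trip is lossless.

## Thermodynamics and rates

Everything is classical harmonic. The statistical weight of minimum $i$ at
inverse temperature $\beta$ is $w_i = e^{-\beta E_i - \sum_j \ln \nu_{ij}}$
(the mode-count factor $\kappa \ln \beta$ is common to all minima and kept
only in free energies, with $h = 1$). Occupations follow by normalisation;
the heat capacity is $C_V = \kappa k_B + \mathrm{Var}_p(E)/k_B T^2$, which
the tests pin against finite differences of $\ln Z$ to $10^{-6}$ relative.

Harmonic TST gives
$k = (\prod \nu^{\min} / \prod \nu^{\ddagger})\, e^{-\beta \Delta E}$,
which satisfies detailed balance against the superposition weights exactly.
Free-energy regrouping merges, in simultaneous passes, every pair of groups
whose inter-group barrier — the lowest connecting transition-state free
energy minus the higher group free energy, clamped at zero — falls below the
threshold, recomputing
$F_G = -k_B T \ln \sum_{i \in G} e^{-F_i/k_B T}$ after each pass until no
merge occurs. Because merging only lowers group free energies and therefore
only raises the remaining barriers, the first simultaneous closure is
already self-consistent and the partition is independent of enumeration
order (the tests verify this by regrouping under random relabelings). The
clamp also makes threshold 0 the exact identity: a harmonic prefactor can
push a transition state's free energy below a minimum's, but a negative
barrier is a convention artefact, not kinetics.

Phenomenological two-state rates are committor-weighted equilibrium escape
fluxes,
$$k_{AB} = \sum_{b \in B} \frac{p_b}{p_B}\, \frac{P_{A \leftarrow b}}{\tau_b},$$
where $P_{A \leftarrow b}$ is the probability that the jump chain started in
$b$ reaches $A$ before returning to any $B$ state and $\tau_b$ is the
waiting time in $b$. Graph transformation computes $P_{A \leftarrow b}$ by
eliminating intermediate nodes in minimum-degree order (ties by id) with
$P'_{uv} = P_{uv} + P_{ux}P_{xv}/(1 - P_{xx})$; when $1 - P_{xx}$ underflows
the denominator is rebuilt from the surviving off-diagonal column. The
companion `exact_rate_oracle()` computes the same quantity from the
generator matrix by a direct committor solve and a null-space stationary
distribution — a fully independent route that the tests require to agree to
$10^{-8}$ relative. This flux definition obeys
$k_{AB} p_B = k_{BA} p_A$ identically (reactive-flux symmetry), so
fold/unfold ratios equal population ratios to round-off — the property the
rate-table analogue checks. Waiting-time–renormalised (mean-first-passage
flavoured) rates are reported alongside as `k_AB_mfpt` for completeness.
Rates are in reciprocal reduced time; absolute laboratory rates are outside
the model's claims and only ratios should be interpreted.

Fastest paths minimise $\sum -\ln P$ over discrete paths with
$P(v \leftarrow u) = k(v \leftarrow u) / \sum_w k(w \leftarrow u)$ at the
analysis temperature, with deterministic tie-breaks (fewer edges, then the
lexicographically smallest id sequence). Note one property that is *not*
true under this weighting: adding a transition state can raise the best
weight, because it competes in every escape denominator at its endpoints.

## Disconnectivity graphs

Superbasins at a threshold are connected components of the subgraph of
minima joined by transition states at or below it; the tree records merges
across a uniform grid of 50 levels by default (explicit levels can be
given). Layout is deterministic: children ordered by subtree leaf count,
then lowest id; horizontal positions by recursive proportional allocation.
Output is SVG (parsed by the tests) plus an indented text serialisation for
diffing. Leaf stems are coloured by any per-minimum order parameter,
typically the helicity percentage.

## Sampling and reweighting

The equilibrium stage is parallel-tempering Monte Carlo (not MD): the
analyses need Boltzmann ensembles, while kinetics come from the network
stages. Single-coordinate Metropolis moves ($n_{\rm dof}$ per sweep),
neighbour exchanges every few sweeps with the standard
$(\beta_i - \beta_j)(E_i - E_j)$ criterion on an alternating even/odd
schedule, a geometric ladder, and a 20% equilibration discard. MBAR is
solved by damped-free self-consistent iteration on the energies (states
differ only in temperature) with log-sum-exp stabilisation, the $f_1 = 0$
gauge, and optional within-state bootstrap errors. Reweighted heat
capacities use $C_V(T) = \mathrm{Var}_T(E)/k_B T^2$ with a bootstrap error
on the peak location.

## Conformational and sequence analyses

Helicity is the fraction of backbone dihedrals within $\pm 30^\circ$ of the
$50^\circ$ helical reference — the bead-model proxy for secondary-structure
assignment, since a one-bead-per-residue chain has no hydrogen-bond
geometry. Dihedral clustering is deterministic first-fit leader clustering
under the RMS minimum-image angular distance with a $40^\circ$ radius.
Contact maps exclude $|i-j| \le 2$; hydrogen-bond-like contacts use the
3 Å / $40^\circ$-from-linear criterion on user-assigned donor–hydrogen–
acceptor triples. The 2-D free-energy surface is
$-k_B T \ln(p/p_{\max})$ with empty bins `NA`, invariant under uniform
weight rescaling.

Charge patterning follows the Das–Pappu convention: window charge asymmetry
$\sigma = (f_+ - f_-)^2/(f_+ + f_-)$, blob sizes 5 and 6,
$\delta_g$ the mean squared deviation of windowed $\sigma$ from the
sequence value, and $\kappa = \overline{\delta} / \overline{\delta}_{\max}$
with $\delta_{\max}$ evaluated on the fully segregated arrangement of the
same composition (all negatives, neutrals, positives) rather than by
permutation search. Histidine and the termini are uncharged; K/R are $+1$,
D/E $-1$. The bundled BH3-region peptide (34 residues) gives
$\kappa = 0.197$ — a strong polyampholyte (FCR 0.44) with well-mixed
charges, the regime in which alternative electrostatic networks, rather
than one specific salt-bridge pattern, stabilise compact disordered states.

```{r kappa}
p <- charge_patterning(read_fasta_sequence(
  system.file("extdata", "puma_bh3.fasta", package = "ktnet")))
p
```

## Problem sizes and limitations

The shipped analyses and tests use deliberately small instances: clusters up
to LJ$_{13}$, a 13-bead peptide, synthetic networks of up to ~15 minima, 100
random $\le 12$-node networks for the rate cross-checks, $10^4$ samples per
state for MBAR, and 20-seed success statistics for global optimisation.
These sizes make every claim checkable against an exact oracle in seconds
while exercising the same code paths a larger study would use.

Known limitations: classical harmonic thermodynamics only (no anharmonic or
quantum corrections); point-group symmetry numbers are taken as 1; the
identity rule does not align permutational isomers; the band/EF machinery
assumes continuous analytic gradients; regrouped-network rates are evaluated
at the regrouping temperature; and nothing here claims quantitative accuracy
for any real peptide — the bead model is a methodological test bed, not a
force field.
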