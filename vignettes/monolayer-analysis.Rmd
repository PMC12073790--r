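---
title: "Models and methods behind goldsam"
author: "goldsam authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind goldsam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`goldsam` analyses how a monolayer of linker-conjugated peptides grafted on
a flat gold surface organises itself and presents binding surfaces to a
protein-sized probe.  The package has three layers: a **builder** that
constructs initial gold-slab + grafted-conjugate configurations and their
charge bookkeeping; a **synthetic trajectory generator** that produces
desk-scale Brownian-dynamics runs with controllable monolayer morphology;
and the **analyses** — density profiles, switching-function contact
scores, close contacts and persistence maps, dual-probe SASA, height-map
morphology, and a tensile deformability metric.  Everything internal uses
nm, ps, u and kg/m^3; unit conversions happen only at file-format
boundaries (PDB is Angstrom on disk).

The system this models: gold nanostructures functionalised with the
12-mer PD-L1-binding peptide CLP002 (or its scrambled control) through
either a long thiolated-PEG3000 linker with a cationic Lys3Gly2 spacer or
a short Ac-Cys-(O2oc)2 linker.  Experimentally only the long-linker,
correct-sequence system targets PD-L1 well; the mechanistic story is that
its peptides aggregate into a rough, deformable corona with pockets big
enough for the ~4 nm x 3 nm IgV-like binding domain, while the other
coatings form compact carpets.  The analyses here quantify exactly those
distinctions.

# The builder

`build_gold_layer()` places a single planar triangular lattice (one
hexagonally packed layer): rows `spacing * sqrt(3)/2` apart, alternate
rows offset by `spacing/2`.  The default spacing 0.288 nm is the bulk-gold
nearest-neighbour distance; the layer is a geometric stand-in for a
restrained Au slab, so a single layer suffices.

`graft_conjugates()` inserts conjugates long-axis parallel to Z with each
anchor sulfur exactly `s_au_distance` (default 0.294 nm, the Au-S bond
convention) above the gold plane, on a uniform anchor grid with a small
seeded jitter.  Chains are written in their extended (all-trans)
conformation — 0.28 nm rise per PEG monomer, 0.35 nm per amino acid — and
a user-supplied peptide head conformation can replace the extended head
(the relaxed head structure from solution simulations is not
reconstructible here, so extended is the documented default).  The
representation is deliberately coarse: one bead per linker unit, one
backbone bead (`CA`) plus one side-chain bead per amino acid, carrying
real residue masses so mass-density profiles are meaningful.  PEG3000 is
68 monomers of 44 u.  Counterions are scattered in the solvent region;
water is implicit everywhere and recorded only as metadata.

Formal charges use fixed neutral-pH rules — Arg/Lys +1 (spacer Lys
included), Asp/Glu −1, His neutral, Cys neutral whether thiol or
gold-bound, PEG/O2oc/acetyl neutral, amide C-terminus and blocked
N-terminus 0 — and `counterion_count()` is simply `n_peptides * charge`.
The three shipped system presets (45/45/90 chains, their printed boxes,
180/180/90 chloride) follow from these rules.

# The synthetic generator

`simulate_brush()` integrates overdamped (Brownian) position-update
dynamics:

    x <- x + mobility * dt * F + sqrt(2 * mobility * dt * kT) * N(0,1)

with `temperature_factor` playing kT in the reduced energy unit of the
force field.  No inertia, no solvent, no electrostatics: the goal is
trajectories with the *statistical structure* the analyses assume, not
physical kinetics.

The force field, per bead:

* harmonic bonds along each chain (`bond_stiffness`, rest length
  `bond_length` = 0.35 nm, one bead per residue);
* a bending term `k * (1 + cos theta)` over consecutive triplets
  (`bending_stiffness`, default 5) making chains semiflexible;
* a graft-alignment term `k * (1 - cos phi)` biasing the first bond of
  each grafted chain toward the surface normal (`graft_alignment`,
  default 20) — the orientational order a covalent surface anchor
  imposes;
* soft excluded volume between all bead pairs
  (`excluded_strength * (1 - r/r_ev)^2`, `r_ev` = 0.35 nm);
* a short-range attractive well `-eps * (1 - (r/rc)^2)^2` (range 0.6 nm)
  acting only between **peptide** beads of **different** chains — the
  linker phase is non-sticky, mirroring a PEG cushion that does not
  aggregate;
* optionally a constant force `mass * pull_acceleration` along −Z on
  every C-alpha-flagged bead (the tensile test; sign convention: toward
  the surface);
* a reflecting wall at Z = 0 standing in for the gold slab, periodic
  wrapping in X and Y.

The first bead of each chain is frozen at its graft site.  A rigid probe
body (`probe_spec()`: a cylinder, default 4 nm deep x 3 nm wide, the
IgV-domain proxy) can be added, either held at a fixed pose (default:
lowered to touch the monolayer's initial mean top) or performing a shared
vertical random walk; its surface beads carry residue labels by angular
sector, so the 12 PD-L1 active-spot names map onto probe patches for
persistence analyses.

Three of these terms (bending, graft alignment, peptide-only attraction)
exist because the minimal model fails without them: freely jointed chains
with attraction among all beads collapse into dense mats on the floor
regardless of attraction strength, and no morphology contrast survives.
With semiflexible, anchor-oriented chains and a non-sticky linker
cushion, the strong-attraction system de-mixes laterally into peptide
aggregates riding on the linker phase, with multi-nm voids between them,
while the weak-attraction system stays a uniform brush — the clustered
vs grid contrast the analyses are meant to detect.

Numerical choices:

* The deterministic part of each step is capped at `0.25 * bond_length`
  (the `nve/limit` idea from MD practice).  Cluster-collapse transients
  otherwise produce rare force spikes that would dictate a globally tiny
  timestep; the cap leaves equilibrium sampling untouched.  A hard
  stability error still fires if any total displacement exceeds the bond
  length — the advice then is a smaller `timestep`.
* Noise comes from R's RNG, so a run is bitwise-reproducible from
  `set.seed`-compatible `seed`; the per-run parameter set travels with
  the trajectory as an attribute and in pipeline manifests.
* Defaults (25 chains at 1.0 nm grafting, 12 peptide + 5 linker beads,
  dt = 0.004 ps, 10000 steps, kT = 1) were chosen once, as the smallest
  system in which aggregation, pocket formation and tensile response are
  all clearly expressed; `make_morphology_pair()` uses attraction 2
  (clustered) vs 0.2 (grid), identical seeds otherwise.

What the generator deliberately does not emulate: explicit solvent and
ions, residue-specific interactions (all peptide beads attract alike, so
sequence scrambling per se has no effect — the attraction knob stands in
for the sequence-dependent aggregation propensity), realistic kinetics or
time scales, and probe-monolayer binding specificity.  Tests passing on
these trajectories certify the *analysis pipeline* and the *qualitative
morphology logic*, not force-field realism.

# The analyses

**Density profiles.** Mass-weighted Z histograms in fixed slices (default
0.15 nm) from the gold plane (mean gold-atom Z per frame; Z = 0 for
gold-free brushes), averaged over a time window, in kg/m^3
(1 u/nm^3 = 1.66054 kg/m^3).  Atoms are binned by point position; at
0.15 nm slices, partial-volume smearing is ignored.  Mass is conserved to
1e-6 relative by construction and asserted in tests.  Beware knife-edge
artifacts when constructed coordinates sit exactly on slice boundaries
(the initial lattice does); generic offsets avoid them.

**Threshold distance.** The corona-extent proxy is the *outermost*
downward crossing of a threshold (default 200 kg/m^3), linearly
interpolated between slice centres.  Monolayer profiles can dip near the
surface, so inner crossings are ignored; the metric tracks outer extent
and is monotone as the threshold drops.

**Centroid shift.** "How far did the monolayer move along Z" is read as
the shift of the density-weighted mean Z between two profiles on the same
slice grid — the unique moment-based reading of an average density
position.  Negative = toward the surface.  This is the tensile
deformability metric.

**Tensile comparisons.** The tensile convention applies
0.01 nm/ps^2 to C-alpha beads.  In the generator's reduced units that
force fully flattens both desk-scale brushes, so the *contrast* between
morphologies is probed at 0.005 nm/ps^2, mid linear-response; the
monotonicity of shift magnitude with pull strength over {0, 0.005, 0.01}
is asserted separately.

**Switching-function score.** `switch_term()` is
`[1-(r/r0)^6]/[1-(r/r0)^14]` with the analytic limit 6/14 at `r = r0`
(removable singularity, handled within 1e-12 of r0).  `s_function()` sums
it over heavy-atom pairs of different peptides under the XY minimum image
via a cell-list kernel, truncated at `5 * r0` where a term is below 3e-6
(configurable, `Inf` disables); normalisation divides by `n(n-1)/2`.
Tests pin the kernel to an O(N^2) brute-force oracle at 1e-10 on random
frames, including pairs through the periodic boundary.

**Close contacts and persistence.** Strict inequality at the cutoff
(`< 0.5` nm) throughout, heavy atoms only by default (united-atom
topologies carry few hydrogens; a switch re-admits them).  Persistence
cell (i, j) counts window frames in which *any* heavy-atom pair between
peptide-residue position i (pooled over chains) and active spot j is in
contact, times the frame interval.  Because saved-frame spacing is an
explicit `frame_interval` field, persistence times are defined regardless
of the stride the producer used.  The 12-spot reference set follows the
protein's own residue numbering, with an offset argument for shifted
topologies.  The contact-potential score is a plain
`sum(matrix[type_a, type_b] * count)`; the residue-pair energy matrix is
a required input with no shipped default, and the result is a relative
score, never a binding free energy.

**SASA.** Shrake-Rupley with a deterministic Fibonacci sphere lattice
(default 960 points; 960 vs 3840 agrees within 1% on random crowded
fixtures, and two-sphere cases match the spherical-cap closed form within
the `2/sqrt(n)` sampling tolerance).  Occluders are the selected atoms
themselves; XY minimum image applies.  The two probe conventions are
0.15 nm (water-like) and 1.5 nm (protein-like).  Per-peptide values sum
per grafted chain; time series average window-first (per chain over the
window, then across chains or replicas).

**Height maps and pockets.** Per XY grid cell (default 0.2 nm), the top
surface is `max(z + vdw)` of the atoms projecting into the cell; empty
cells take the nearest occupied cell's value (periodic XY metric).
Pockets are connected components (4-connectivity, EBImage `bwlabel`) of
cells deeper than `depth_threshold` (default 1.5 nm) below the
90th-percentile surface level; depth is the maximum drop below that
level and width the diameter of the largest inscribed disc (EBImage
`distmap` plus a half-cell correction at each end, since the transform
measures centre-to-centre).  `accommodates_probe()` asks whether any
pocket is at least as deep and wide as the IgV proxy (4 x 3 nm).  When
*comparing* morphologies, pockets narrower than 2 nm are ignored: a
brush's inter-chain canyons can be deep but sub-nanometre wide — "narrow
meshes" no protein-scale probe could enter.

**Convergence series.** Peptides qualify if any heavy side-chain atom
comes within 0.7 nm of the protein during the window; the series is the
per-frame mean over qualifying peptides of their minimum
side-chain-to-protein heavy-atom distance.  A flat series signals an
equilibrated interface.

# I/O and the pipeline

GRO files are fixed-width (nm, 3 decimals; atom and residue numbers wrap
at 100000, the GROMACS convention, so fields never overflow); frame times
ride in the title line.  PDB reading is delegated to `bio3d`
(multi-model), with division by 10 at the boundary; the writer emits a
minimal multi-model PDB including a CRYST1 record so boxes survive round
trips.  Moieties are inferred from residue names via an overridable map
(`AU` gold, `PEG`/`O2O`/`ACE`/`CYX` linker, amino acids peptide by
default — amend the map when a file contains a real protein), and grafted
chain numbers are inferred from residue ordering (chains are stored
linker-first; the bound-cysteine anchor is written `CYX` so the C-linker
chain is not split at its cysteine).  Within-chain selection metadata
(side-chain/C-alpha flags) survives a round trip only approximately;
positions are exact to format precision.

`run_pipeline()` executes build/simulate/analyze stages from a YAML-style
config, writes per-run manifests (config hash, seed, package version,
stage outputs) and a standard metrics JSON; `pipeline_report()` merges
runs into a comparison table and refuses windows of different lengths.
Outputs are reused unless `force = TRUE`.  The test-suite problem sizes —
25-chain brushes for morphology contrasts, 6-9-chain brushes elsewhere,
100 random frames for oracle comparisons — are the package's chosen
desk-scale study conditions.

# Known limitations

* The generator's attraction knob conflates every sequence-dependent
  effect into one scalar; it cannot rank two specific sequences.
* Pocket statistics are per-frame; no time-averaged surface is built.
* The builder's extended-conformation chains are a starting geometry, not
  an equilibrium ensemble; analyses of builder output alone reflect that
  idealisation.
* Anionic conjugates (net negative charge) are unsupported by the
  counterion bookkeeping.
* The height-map surface level (90th percentile) is meaningful only when
  elevated material covers more than ~10% of the patch; emptier systems
  need an explicit reference.
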