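---
title: "Methods: reactive-geometry classification, binding-mode clustering and supporting kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reactive-geometry classification, binding-mode clustering and supporting kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxtraj)
```

## The scientific question

Lipoxygenases initiate fatty-acid oxygenation by abstracting a hydrogen
from the bisallylic methylene (C13 of arachidonic acid, C11 of linoleic
acid) onto the hydroxide of the non-heme Fe³⁺–OH cofactor. Whether a
trajectory frame is geometrically competent for that step is decided by
two inequalities on three distances:

* *well-oriented*: $d(\mathrm{H{-}OH}) < d(\mathrm{C{-}OH})$ — the C–H
  bond points toward the hydroxide rather than away from it;
* *pre-catalytic*: additionally $d(\mathrm{H{-}OH}) \le 3$ Å.

`loxtraj` computes these per frame and per prochiral hydrogen, aggregates
them as at-least-one-hydrogen percentages over the trajectory, and
compares systems (mutant vs wild type) through fold changes and
mean-distance shifts. The surrounding analyses — binding-mode clustering,
hydrogen-bond anchors, helix turn counting, inter-monomer contacts,
Michaelis–Menten kinetics and SEC calibration — provide the structural and
kinetic context in which those percentages are interpreted.

## Classification: conventions and their rationale

Three conventions are fixed in the classifier and deliberately explicit:

1. **Boundary**: the distance criterion is inclusive
   ($d \le 3.000$ Å counts); the orientation criterion is strict
   ($d(\mathrm{H{-}OH}) < d(\mathrm{C{-}OH})$). Ties at exactly 3 Å are
   measure-zero for real data but the convention matters for constructed
   tests.
2. **Aggregation**: a frame is well-oriented / pre-catalytic when *at
   least one* of the two prochiral hydrogens satisfies the criteria.
   Reported summary tables in this field aggregate that way; per-hydrogen
   percentages (`pct_wo_S`, `pct_pc_S`, …) are nevertheless carried in
   every summary so a specific-hydrogen reading can always be recovered.
3. **Averaging window**: percentages are computed over all supplied
   frames; `summarize_geometry(..., discard_ns =)` drops an initial
   equilibration window when the user asks. Published tables do not always
   state which window was used, so the package makes the choice visible
   rather than implicit.

The classification is pure arithmetic on distances, so its unit tests
re-evaluate the two inequalities frame by frame with independent code and
check the closed-form expectation on generated ensembles (below).

## Prochiral hydrogen assignment

The proS/proR identity of the two bisallylic hydrogens is a chemical
label, not a per-frame property. The default route is an explicit mapping
in the topology config (force-field atom names → proS/proR), which avoids
any stereochemical computation. The geometric `AUTO` fallback implements
the minimal decision that distinguishes the two hydrogens: with the two
carbon neighbours ranked by a declared `branch_priority`
($C_{high} > C_{low}$) and priorities
$C_{high} > C_{low} > H_{promoted} > H_{other}$, a hydrogen is pro-R when
the scalar triple product of the unit bond vectors
$(\hat u_{C_{high}}, \hat u_{C_{low}}, \hat u_{H})$ at the reactive carbon
is negative — i.e. the 1→2→3 priority sweep appears clockwise with the
remaining hydrogen pointing away. A full CIP engine is out of scope: the
branch ranking for a given substrate is constant and is better declared
once in the config than re-derived. Tests pin the two properties that
matter: labels swap when the hydrogens' coordinates are exchanged and flip
under mirror reflection, and they are invariant under rigid motion.

## Superposition and binding-mode clustering

RMSD uses Kabsch superposition (SVD of the cross-covariance with the
determinant correction that excludes reflections), mass-unweighted, on the
substrate heavy atoms by default. Collinear point sets are an *error*, not
an answer: at rank < 2 the optimal rotation is degenerate and a reflection
can masquerade as a rotation. A config option fits on binding-pocket atoms
and measures ligand RMSD without refit (`pairwise_rmsd(fit_selection,
rmsd_selection)`); both modes are first-class, because published analyses
rarely state which reference was used and the two can differ materially.
The matrix is symmetrized as $(M + M^\top)/2$; with identical fit and
RMSD selections the two directions are already equal.

Clustering is the Daura/GROMOS neighbor-counting procedure at a 0.5 Å
cutoff — the de facto standard for cutoff-based MD clustering — with fully
deterministic tie-breaks: ties on neighbor count go to the lowest frame
index, final cluster ids are renumbered by decreasing size (size ties by
earliest member), and the centroid is the member of the largest cluster
minimizing total RMSD to its co-members (ties again by lowest index). The
0.5 Å cutoff is interpreted as the *neighbor* cutoff, not a cluster
radius. Tests compare the implementation against an independently coded
removal-order oracle on small random matrices and against planted
partitions with known labels.

## Hydrogen bonds, helices, contacts

Anchor hydrogen bonds use a geometric criterion:
$d(\mathrm{H \cdots A}) \le 3.5$ Å and
$\angle(\mathrm{D{-}H \cdots A}) \ge 120^\circ$. The distance cutoff is
deliberately permissive so that long carboxylate contacts around 3.3–3.4 Å
are counted; both cutoffs are arguments. Occupancy is exactly
events/frames per donor–acceptor pair.

Helix assignment uses a single criterion instead of the full DSSP
alphabet: the α-helical $i \to i{+}4$ backbone hydrogen bond, detected as
$d(\mathrm{O}_i \cdots \mathrm{H{-}N}_{i+4}) \le 2.7$ Å (falling back to
$\mathrm{O \cdots N} \le 3.5$ Å when amide hydrogens are absent). A
residue is flagged helical when it lies inside the span of at least one
intact bond. The span rule (rather than flagging only the donor residue)
is what makes the flags behave correctly at segment ends and at
helix/coil boundaries: the last four residues of an ideal helix are
covered by the bonds they accept, and a residue whose own carbonyl is
rotated away but which still sits inside an intact turn counts as helical
— consistent with how an N-terminal cap residue of a surviving turn is
usually perceived. One geometric fact discovered while validating on
constructed helices is worth recording: the $\mathrm{O}_i \cdots
\mathrm{N}_{i+4}$ geometry depends only on the torsions of residues
$i{+}1 \dots i{+}4$, because rotating $\psi_i$ carries the carbonyl oxygen
and the downstream chain together. Unwinding residues $1..k$ therefore
leaves the bond donated by residue $k$ itself intact. Turn counting is
`round(longest_run / 3.6)` — 3.6 residues per α-helical turn — so an
18-residue run gives 5 turns, 25 gives 7, and 7 gives 2.

Inter-monomer contacts require the atoms to be named in the config (e.g.
CD2 of a zipper leucine, NE2 of a histidine); there is no
closest-heavy-atom fallback, because a distance that cannot be attributed
to specific atoms cannot be compared across systems.

## Kinetics and SEC

The Michaelis–Menten fit is unweighted nonlinear least squares of
$v = k_{cat} S/(K_M + S)$ (Levenberg–Marquardt, 500 iterations max,
parameter tolerance $10^{-10}$), with $k_{cat,0} = \max v$ and $K_{M,0}$
the concentration at half-maximal rate interpolated on the
replicate-averaged curve. Replicate points enter individually; standard
errors come from the Jacobian at the optimum; negative estimates are an
error, never clamped. Catalytic efficiency is reported at full precision
and rounded to one decimal only at render time, which keeps rounding
inconsistencies in published tables diagnosable (e.g. a printed 8.3
against 54.40/6.6 = 8.24 — the package reports the computed value).

A sampling-precision fact that the Monte-Carlo tests compute and that
users should know: with 5% multiplicative noise on each of 3 replicates at
the default 7-point grid (2–160 µM), the sampling SD of $\hat K_M$ is
about 6% while $\hat k_{cat}$ is about 3%; both are unbiased to under 2%.
A "both parameters within 10%" event therefore occurs in just under 90% of
repeats — the $K_M$ margin is only ~1.6 sampling SDs — so recovery claims
at that threshold sit on a statistical knife edge at these noise levels.

SEC calibration regresses $y = (-\log_{10} K_{av})^{1/2}$ on the
hydrodynamic radius $R_h$ of at least three standards (two standards are
rejected as under-determined) and inverts the line for prediction. Base-10
logarithm is the chromatography convention; the base is an argument.
$K_{av} = 0$ (elution at the void volume) has no logarithm and is an
error, as is a zero slope.

## What the synthetic generators emulate — and what they do not

The generators stand in for production MD trajectories that are not
redistributable; each carries analytic ground truth so downstream results
are verified without re-deriving them.

* `gen_reactive_frames()` — cofactor oxygen at the origin, reactive carbon
  at $d \sim \mathcal N(\mu, \sigma)$ truncated at $d > b_{CH}$ (rejection
  sampling), one hydrogen at angle $\varphi$ to the C→OH axis
  ($b_{CH} = 1.09$ Å), the second mirrored out of plane. For
  $\varphi = 0$ the pre-catalytic fraction is
  $[\Phi((3 + b_{CH} - \mu)/\sigma) - \Phi((b_{CH}-\mu)/\sigma)]\,/\,
  [1 - \Phi((b_{CH}-\mu)/\sigma)]$; the general-$\varphi$ closed form is
  in `reactive_expected_fractions`. Tests check the empirical fraction on
  10,000 frames against this within the 99% binomial interval.
* `gen_clustered_frames()` — independent random conformers as templates,
  accepted only when all pairwise fitted RMSDs exceed the requested
  separation, plus isotropic jitter; infeasible parameter combinations
  (separation ≤ 6·jitter + 2·cutoff) are rejected up front.
* `gen_ideal_helix()` — poly-alanine backbone from ideal internal
  coordinates ($\varphi, \psi = -57^\circ, -47^\circ$, giving the
  canonical ~1.5 Å rise and ~100° twist, asserted in tests); unwound
  ranges get extended torsions ($-139^\circ, +135^\circ$).
* `gen_mm_data()` / `gen_sec_standards()` — forward models with
  multiplicative noise / exact calibration lines; defaults are the
  wild-type linoleate constants ($k_{cat} = 47.2\,s^{-1}$,
  $K_M = 21.4$ µM) and the canonical globular standards (20.9 / 35.5 /
  52.2 Å).

What they do *not* emulate: force-field physics, correlated frame-to-frame
dynamics, solvent, protein flexibility around the ligand, or the actual
2P0M coordinates. Passing tests therefore demonstrate that the
*measurement and classification machinery* is correct and deterministic —
not that any particular trajectory-derived percentage for the real enzyme
is reproduced. The absolute percentages published for the real systems
require the original trajectories; what the package reproduces from
printed tables is their arithmetic (folds, shifts, efficiencies).

## Determinism and problem sizes

Every generator takes a single seed, seeds one RNG stream once, and
restores the caller's RNG state; identical (parameters, seed) give
identical objects, and pipeline reruns with identical configs give
byte-identical output files (all rounding is deferred to
`report_tables()`). The test suite runs at desk scale: 10,000 frames for
the classification ensemble, 100 frames / 10 atoms for planted-cluster
recovery, 12–15 frames against the exhaustive clustering oracle, 100
Monte-Carlo kinetics fits — sizes chosen so the full suite completes in
well under a minute while keeping binomial test intervals tight enough to
be meaningful.

## Known limitations

* No binary trajectory readers (DCD/XTC); convert to multi-model PDB or
  the TSV frame table first (`bio3d` can do the former).
* Helix assignment is a single H-bond criterion, not DSSP; 3₁₀ and π
  helices are not distinguished.
* The AUTO prochiral route needs a declared bond list and branch priority;
  it does not infer bonds from distances.
* Hydrogen-bond detection assumes explicit hydrogens for the
  donor-side geometry (the N-only helix fallback is the lone exception).
* Michaelis–Menten fitting covers initial-rate data only — no
  progress-curve analysis, no inhibition models, no
  absorbance-to-rate conversion.
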