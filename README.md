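# loxtraj

Post-analysis toolkit for molecular-dynamics (MD) trajectories of
lipoxygenase–substrate complexes, written for structural biologists who
want to quantify how mutations at the ALOX15 dimer interface change the
reactive alignment of a fatty-acid substrate at the catalytic iron — and to
connect those geometric shifts to steady-state kinetics.

## What it computes

Rabbit ALOX15 abstracts a hydrogen from the bisallylic carbon of its
substrate (C13 of arachidonic acid, C11 of linoleic acid) onto the
hydroxide of the Fe³⁺–OH cofactor. For every trajectory frame the package
computes d(C–OH), d(H_proS–OH) and d(H_proR–OH) and classifies the frame
with the standard two-criterion geometry test:

* **well-oriented**: d(H–OH) < d(C–OH) for at least one of the two
  prochiral hydrogens (the C–H bond points at the hydroxide);
* **pre-catalytic**: additionally d(H–OH) ≤ 3 Å (boundary inclusive) —
  geometry compatible with hydrogen abstraction.

Summaries report mean distances and the percentage of well-oriented /
pre-catalytic frames; comparisons between systems report fold changes
(e.g. the 16-fold pre-catalytic enrichment of the Trp181Glu mutant with
arachidonic acid) and mean-distance shifts.

Around this central statistic the package provides:

* **Binding-mode clustering** — pairwise heavy-atom RMSD after Kabsch
  superposition, Daura/GROMOS neighbor-counting clustering at a 0.5 Å
  cutoff, and extraction of the centroid frame of the most populated
  cluster (the "most representative binding mode").
* **Prochiral assignment** — explicit proS/proR mapping from the topology
  config, or geometric assignment from the scalar triple product of the
  bond vectors at the bisallylic carbon.
* **Structural metrics** — carboxylate anchor hydrogen bonds
  (distance + angle criterion with per-pair occupancy), α-helix assignment
  from i→i+4 backbone hydrogen bonds with turn counting
  (3.6 residues/turn), and inter-monomer contact distance series
  (leucine zipper, Glu181–His585).
* **Kinetics & SEC** — Michaelis–Menten fits v = k_cat·S/(K_M+S) with
  catalytic efficiency k_cat/K_M, and size-exclusion calibration
  K_av = (V_e−V_o)/(V_t−V_o) with (−log₁₀K_av)^½ regressed on the
  hydrodynamic radius R_h.
* **Synthetic generators** — seeded trajectory/data generators with
  analytic ground truth (truncated-normal reactive distances, planted
  binding-mode clusters, ideal/partially unwound helices, noisy saturation
  curves, exact SEC lines) that exercise the whole pipeline end to end.

Input formats: multi-model PDB (one MODEL per frame), a plain TSV frame
table, YAML/JSON topology/selection configs, CSV kinetics and SEC tables.
All coordinates and distances are Å; rates s⁻¹; concentrations µM.

## Worked example

```r
library(loxtraj)

## two synthetic systems emulating a tightly- vs loosely-bound substrate
mut <- gen_reactive_frames(2000, d_mean = 3.6, d_sd = 0.4, seed = 101)
wt  <- gen_reactive_frames(2000, d_mean = 5.0, d_sd = 0.6, seed = 202)
summ <- function(g, label)
  summarize_geometry(classify_frames(compute_reactive_distances(g$trajectory)),
                     system = label)
s_mut <- summ(mut, "mutant"); s_wt <- summ(wt, "wildtype")
s_mut[, c("system", "mean_d_C_OH", "pct_well_oriented", "pct_precatalytic")]
#>   system mean_d_C_OH pct_well_oriented pct_precatalytic
#> 1 mutant    3.589925               100            89.65

cmp <- compare_summaries(s_mut, s_wt)
cmp$display_fold_precatalytic   # 13   (analytic expectation: 0.890/0.065)
cmp$display_delta_mean_d_C_OH   # 1.4  (Angstrom shift toward the cofactor)

## kinetics on a noisy synthetic saturation curve
fit <- fit_michaelis_menten(gen_mm_data(kcat = 47.2, KM = 21.4,
                                        noise_cv = 0.05, replicates = 3,
                                        seed = 7))
fit
#> <lox_mmfit> kcat = 47.92 +/- 0.92 s^-1;  KM = 20.2 +/- 1.22 uM;  kcat/KM = 2.4 s^-1 uM^-1

## SEC calibration and radius estimation
cal <- calibrate_sec(gen_sec_standards(slope = 0.02, intercept = 0.1),
                     Vo = 8, Vt = 24)
estimate_rh(cal, 12)
#> [1] 33.79626
```

The pre-catalytic percentage is the fraction of frames in which a
bisallylic hydrogen sits within abstraction distance of the hydroxide
while pointing at it — the quantity whose mutant/wild-type ratio explains
why an interface mutation can accelerate arachidonate oxygenation without
touching the active site.

A whole-pipeline run (validated config, CSV/JSON outputs, manifest) goes
through `run_pipeline()` / `report_tables()`, or the bundled wrapper:

```sh
Rscript inst/scripts/loxtraj-run.R --config run.yaml --out results/
```

Bundled reference tables (`alox15_kinetics_table()`,
`alox15_geometry_table()`) carry the published kinetic constants and
trajectory-averaged geometry percentages for wild-type rabbit ALOX15 and
its His585Glu / Trp181Glu interface mutants.

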