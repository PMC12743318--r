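# pettraj

Trajectory analysis for PET-degrading serine hydrolases adsorbed on
amorphous polyethylene terephthalate (PET).

IsPETase and PETaseSM14 share a Ser-His-Asp catalytic triad but respond to
salt in opposite ways: high NaCl inactivates IsPETase and boosts
PETaseSM14. Molecular-dynamics work explains that contrast through a small
set of binding-site observables, and `pettraj` implements that analysis
layer as a tested, reusable R package for anyone working with MD
trajectories of PET hydrolases (or similar enzyme-polymer systems):

* **d1-d4 marker distances** — cleft width (d1: Tyr Oη-Ile Cδ1, d2: Tyr
  Oη-Trp Cγ) and triad integrity (d3: Ser Oγ-His Nδ1, d4: the
  Trp159/His155-Asn support);
* **active/inactive classification** — a frame is active when
  d3 ≤ 5 Å; the classifier reports transitions, dwell times and
  reversibility;
* **reactive states** — frames where the Ser Oγ is simultaneously < 5 Å
  from the catalytic His nitrogen (Nε2) and from a PET ester carbon
  (C1/C8), counted per ester carbon;
* **pocket hydration** (water oxygens within 6 Å of the Ser Oγ) and
  **binding-site SASA** (Shrake-Rupley, probe 1.4 Å, deterministic
  960-point spiral);
* **enzyme-substrate contacts** per binding-site residue (5 Å, heavy
  atoms, minimum imaging) and time-averaged **residue distance maps**;
* **trans/gauche conformer statistics** of the PET ethylene-glycol
  O3-C9-C10-O1 torsion (gauche |φ| ∈ [50°, 90°], trans |φ| ∈
  [160°, 180°]), partitioned into enzyme-bound (within 8 Å of the Ser Oγ)
  and bulk fractions; amorphous bulk PET sits near trans:gauche = 14:82;
* **replica aggregation** (mean ± SD, n−1) and **condition contrasts**
  (signed percent change with propagated SD).

I/O covers PDB (multi-model) and PSF topologies and DCD trajectories,
with a VMD-like atom selection language and built-in site presets
`"IsPETase"` and `"PETaseSM14"` carrying the published atom mappings. A
synthetic ensemble generator produces enzyme/PET/water trajectories with
exact per-frame ground truth for every observable, so the whole pipeline
is testable without downloading any trajectory; the same functions run
unchanged on deposited real data.

## Worked example

Generate one synthetic replica of PETaseSM14 at 150 mM NaCl and analyse
it:

```r
library(pettraj)

cfg <- scenario_preset("PETaseSM14", "150 mM", n_frames = 200)
scn <- generate_scenario(cfg, seed = 1)
an  <- analyze_trajectory(scn$trajectory, scn$site)

print(scn)
#> pet_scenario: PETaseSM14 at 150 mM - 200 frames, 4270 atoms
#>   true active fraction 0.850, reactive frames 19, <pocket waters> 5.67

print(an$state)
#> state_series: 200 frames, active fraction 0.850, 2 transition(s), reversible

print(conformer_distribution(an$conformers))
#> conformer_summary (trans:gauche bound 0:96, bulk 14:82 )
#>   partition  class       mean sd n_replicas
#> 1     bound gauche 0.96000000 NA          1
#> 2      bulk gauche 0.82272727 NA          1
#> 3     bound  trans 0.00250000 NA          1
#> 4      bulk  trans 0.13732620 NA          1
#> 5     bound  other 0.03750000 NA          1
#> 6      bulk  other 0.03994652 NA          1

mean(an$hydration$count)   # pocket waters per frame
#> 5.67
attr(an$reactive, "total") # reactive configurations
#> 19
```

The enzyme is active for 85% of the run with a reversible inactivation
excursion; the substrate bound at the catalytic site is almost purely
gauche (0.25% trans) while the bulk slab shows the amorphous 14:82
trans:gauche composition; the pocket holds ~5.7 waters on average. Each
of these numbers equals the generator's ground truth for this replica.

A full multi-system run (both enzymes, both salt conditions, three
replicas each) with aggregated summaries, contrast table and delimited
text output:

```r
report <- run_pipeline(default_study_systems(n_frames = 500), seed = 1,
                       output_dir = "report")
print(report)
```

To analyse real deposited trajectories instead, point a system entry at
files: `list(enzyme = "IsPETase", condition = "150 mM", topology =
"is150.psf", trajectories = c("rep1.dcd", "rep2.dcd", "rep3.dcd"))`
(use `stride` for snapshot-cadence archives).

A thin command-line front end with verbs `generate`, `analyze` and
`report` is installed at `exec/petase-salt`.

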