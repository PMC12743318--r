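---
title: "Binding-site and conformer analysis of PET hydrolase trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-site and conformer analysis of PET hydrolase trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pettraj)
```

## The scientific problem

IsPETase (from *Ideonella sakaiensis*) and PETaseSM14 (from a marine
*Streptomyces* strain) are homologous serine hydrolases that depolymerise
polyethylene terephthalate (PET), but they respond to salt in opposite
ways: IsPETase loses most of its activity at high NaCl concentration while
PETaseSM14 peaks near sea-water ionic strength. Molecular-dynamics studies
of the two enzymes adsorbed on amorphous PET slabs explain this contrast
through a small set of trajectory-derived observables, which this package
computes from standard topology/trajectory files:

* **Cleft geometry (d1--d4).** Four marker distances: d1 (Tyr
  O$\eta$--Ile C$\delta$1) and d2 (Tyr O$\eta$--Trp C$\gamma$) measure the
  width of the substrate cleft; d3 (catalytic Ser O$\gamma$--His N$\delta$1)
  reports the integrity of the catalytic triad; d4 links the residue
  adjacent to the catalytic serine (Trp159 in IsPETase, His155 in
  PETaseSM14) to a conserved asparagine, the support whose loss precedes
  triad disruption.
* **Active/inactive state.** A frame is *active* when d3 $\le$ 5 Å, i.e.
  when the histidine can deprotonate the serine and hydrolysis can start.
  The classifier reports per-frame labels, transitions, dwell times and
  whether inactivation was reversible (any inactive$\to$active transition
  after the first inactivation).
* **Reactive states.** A frame-level proxy for catalysis-competent
  binding: the Ser O$\gamma$ is simultaneously strictly within 5 Å of the
  catalytic His nitrogen and of a PET ester carbon (C1/C8). The count is
  over ester carbons, not chains, so one frame can contribute more than
  one reactive configuration.
* **Hydration and exposure.** Waters whose oxygen lies within 6 Å of the
  Ser O$\gamma$ (6 Å is the Ser O$\gamma$--Tyr O$\eta$ distance, which
  spans the pocket), and the Shrake--Rupley solvent-accessible surface
  area of the six binding-site residues (probe 1.4 Å).
* **Substrate conformers.** The PET ethylene-glycol O3--C9--C10--O1
  torsion is classified with the absolute-value convention: *gauche* when
  $|\phi| \in [50^\circ, 90^\circ]$, *trans* when
  $|\phi| \in [160^\circ, 180^\circ]$, *other* outside both windows.
  Monomers within 8 Å of the Ser O$\gamma$ (any atom) form the *bound*
  fraction; the rest is *bulk*. Amorphous PET bulk is predominantly
  gauche, with a trans:gauche ratio around 14:82.

Replicas are aggregated as mean $\pm$ sample SD (n$-$1), and two salt
conditions of the same enzyme are contrasted as a signed percent change
with first-order error propagation.

## Dual His-nitrogen convention

The d3 definition uses His N$\delta$1 while the reactive-state definition
names the $\varepsilon$ nitrogen. Rather than harmonising them, the two
roles are independent fields of `site_spec()` defaulting to ND1 (d3) and
NE2 (reactive states), so each observable follows its stated definition;
either can be remapped. Similarly, published residue lists for PETaseSM14
occasionally conflict (an aspartate printed as "D204" where 204 is the
tabulated isoleucine, and "W155" where the sequence has H155); the presets
use the catalytic aspartate D202 and H155.

## Geometry kernels

All kernels are first-principles implementations validated against
independent oracles in the test suite:

* **Minimum imaging** wraps each separation component into
  $[-L/2, L/2]$; it is applied to solvent and substrate proximity
  (waters, reactive states, contacts, bound/bulk partition) but *not* to
  intramolecular distances (d1--d4, dihedrals), since the enzyme never
  spans the box. Only orthorhombic cells are supported; triclinic input
  is rejected.
* **Superposition** is the Kabsch SVD solution with the usual reflection
  correction; collinear atom sets are rejected. RMSD defaults to backbone
  atoms (N, CA, C, O), RMSF to C$\alpha$, both configurable, with a
  fall-back to all protein heavy atoms for reduced (marker-style)
  topologies.
* **Dihedrals** follow the signed IUPAC convention in $(-180, 180]$
  degrees.
* **Contacts and distance maps** count heavy-atom pairs below cutoff
  (strict) and time-average per-frame minimum inter-residue distances.
  They are computed by chunked vectorised pairwise arithmetic rather than
  cell lists: at the problem sizes this package addresses (binding-site
  residues against a few thousand substrate atoms) the vectorised path is
  faster in R and is bit-identical to the brute-force oracle by
  construction. The distance-map display cap (14 Å) is an attribute
  applied only at rendering, never to stored values.
* **SASA** uses the Shrake--Rupley point-sampling construction with a
  deterministic golden-section spiral (960 points per atom by default,
  giving $\sim$1% accuracy on closed-form cases; no RNG). Van der Waals
  radii come from a bundled Bondi-style element table and can be
  overridden per atom name, since the radii used by the original VMD
  analysis are not recorded. By default the whole protein occludes while
  only binding-site atoms are reported; occlusion can be restricted to
  the site itself.

Atom addressing uses a small VMD-like selection language (`name`,
`resname`, `resid` with ranges, `segid`, `chain`, `element`, boolean
operators). Indices are R-native 1-based everywhere; PDB serials remain
1-based at the I/O boundary. Coordinates are Å, times ns, angles degrees.

## File formats

PDB parsing and DCD reading are delegated to **bio3d**; the package adds a
PSF (`!NATOM`) parser, a CHARMM-layout DCD writer and a box-aware
multi-model PDB writer, all verified by round-trip tests (DCD to
single-float precision, PDB to $10^{-3}$ Å). Trajectories carry per-frame
orthorhombic box edges and strictly increasing times; a truncated final
DCD frame is dropped with a warning. Deposited data for the original
study ship as PSF/PDB topologies with DCD snapshots at a 10 ns cadence;
`read_trajectory(stride =)` handles both full-resolution and snapshot
files, and the run log echoes the stride so that comparisons with
published per-frame statistics can be interpreted at the correct cadence.

## The synthetic ensemble

Because the real trajectories require a large download, every analysis
stage is exercised against a generator with exact ground truth.

* **Marker dynamics.** Each of d1--d4 is a discrete-time mean-reverting
  (AR(1)/OU-like) process with stationary mean $\mu$, stationary SD
  $\sigma$ and relaxation time $\tau$ (frames):
  $x_{t+1} = \mu_{t+1} + e^{-1/\tau}(x_t - \mu_t) + \varepsilon_t$. An
  optional deterministic switch moves $\mu$ to a post-switch value at a
  given frame (optionally reverting later). This is the simplest process
  reproducing the observed "stable plateau + jump" phenomenology; the
  true state label is active where the d3 *mean path* is at or below the
  threshold, so ground truth is exact even under noise. Marker atoms are
  placed so that every measured pairwise distance equals the generated
  series exactly; the Tyr O$\eta$ sits 6 Å from the Ser O$\gamma$, the
  geometric origin of the pocket-water cutoff.
* **PET chains.** Chains are built from idealised internal coordinates
  (fixed bond lengths and angles) with CHARMM-GUI-like atom names; only
  the O3--C9--C10--O1 torsion is statistically meaningful. Gauche angles
  take a random sign (the classification is absolute-valued), and all
  class draws are rejected back into their closed windows so the sampled
  class always equals the measured class. Each monomer has 22 atoms and
  the chain is capped by two terminal hydrogens, which is the unique
  composition consistent with 200 atoms per 9-mer and 20,000 atoms per
  100-chain melt; an H-capped 9-mer melt in a 61.8 Å cube gives
  1.22 g/cm$^3$, matching amorphous PET. Melt chains are placed with
  random position and orientation; at melt density a hard-sphere clash
  check cannot converge by rejection, so the dense default is unchecked
  insertion (interpenetration is irrelevant to the torsion statistics),
  while a positive `clash_tol` enables the check for dilute systems.
* **Scenario composition.** A full scenario places, in a
  90 x 90 x 110 Å box: the markers; one adsorbed chain whose monomers
  near the serine carry a condition-specific *bound* conformer mixture
  (re-sampled every frame by rotating each monomer's O1 about the
  C9--C10 axis, so measured torsions equal sampled ones exactly); a bulk
  slab of 20 chains well below the site; waters that exchange between
  the pocket (per-frame Poisson count around the condition mean) and a
  far region; and an ester-carbon probe moved to 3 Å from the serine on
  a prescribed set of active frames, realising an exact reactive-state
  count. The adsorbed chain is positioned so that all ester carbons stay
  outside the reactive cutoff except the probe, and slid along its axis
  so that no monomer's bound/bulk membership depends on the per-frame O1
  placement (which would otherwise couple the partition to the torsion
  and bias the bound class statistics).

### Study-condition defaults

`scenario_preset()` encodes the four simulated systems. Marker means
follow the reported traces: PETaseSM14 d1 6.75 Å at both salts, d2
8.5 $\to$ 10.5 Å from 150 to 900 mM; IsPETase d1 9.0 $\to$ 10.7 Å with d2
$\approx$ 10.25 Å. d3 sits near 3.8 Å when active ($\sigma$ = 0.35 Å,
$\tau$ = 20 frames) and switches to 12--16 Å at inactivation: PETaseSM14
at 150 mM is active 85% of the trajectory with a reversible excursion
(76--91% of the run), and always active at 900 mM; IsPETase inactivates
irreversibly at 20% (150 mM) and 8% (900 mM) of the run, with d4 rising
shortly after. Pocket-water means are 5.7 $\to$ 7.7 (PETaseSM14, the
$\approx$+35% / "about two extra waters" contrast) and 9.0 $\to$ 9.5
(IsPETase, well hydrated, <10% change). Bulk conformer mixtures are
82:14:4 (gauche:trans:other) everywhere; bound mixtures are almost purely
gauche with 0.26% trans for PETaseSM14 at 150 mM, bulk-like for
PETaseSM14 900 mM and IsPETase 150 mM, and 56:32:12 for IsPETase at
900 mM. Absolute reactive-state frequencies are not published, only their
ratios; the defaults set IsPETase 150 mM to 0.12 of all frames and derive
the rest from the reported ratios (PETaseSM14 150 mM 20% lower; doubling
at 900 mM for PETaseSM14; halving for IsPETase), under the constraint
that reactive frames must fall inside active frames. Three replicas of
500--1000 frames at 0.5 ns/frame emulate the three 500 ns runs per
system; tests and the acceptance script use 500 frames per replica, which
keeps the full four-system study within a few minutes while leaving every
recovery tolerance comfortably wide.

### What the generator does and does not emulate

It reproduces the *statistical structure* the analysis consumes: marker
distance levels, noise and switching; conformer mixtures per partition;
pocket occupancy; reactive-state frequency; replica-to-replica
variability. It is not physical: there is no force field, no excluded
volume beyond placement heuristics, no water hydrogens, no ions (salt
enters only as condition labels), and hydrogens attached to re-sampled
glycol units do not follow the torsion. Passing recovery tests therefore
demonstrates the correctness of the measurement pipeline, not the realism
of any MD engine; on real trajectories the same code paths apply
unchanged.

## Numerical choices and degenerate inputs

Classification windows are closed (`[50, 90]`, `[160, 180]`), consistent
with published percentages that leave an unclassified remainder; the
activity threshold is an inclusive 5.0 Å ("d3 $\sim$ 5 Å"), while the
reactive cutoff is strict (`< 5 Å`) as defined. The bound/bulk rule is
inclusive (`<= 8 Å`) at monomer granularity, chosen because the torsion
is a per-monomer quantity; "excluding the bound fraction" removes bound
monomers, not whole chains. Empty selections are reported, not errors;
single-frame trajectories skip RMSF with a warning; systems without
waters or PET skip the corresponding stages with warnings. Distances in
the OU realisation are floored at 0.1 Å to respect positivity. All
randomness flows from a single integer seed (replica seeds are derived
deterministically from it), making every pipeline run bit-reproducible.

## Known limitations

* Orthorhombic boxes only; no XTC/TRR/NetCDF, velocities or forces.
* Multi-character chain tags do not survive the PDB writer (one-column
  chain field); melts therefore use globally unique residue numbers so
  monomers stay addressable after a round trip.
* The contact table uses the six binding-site residues of the SASA set;
  the published per-residue contact figure also includes the anchoring
  isoleucine, which can be added via a custom `site_spec()`.
* Tunnel sampling, electrostatic surfaces and isoelectric points are out
  of scope (external published tools).
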