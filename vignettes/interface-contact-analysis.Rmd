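---
title: "Interface contact analysis: models, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface contact analysis: models, criteria and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcontact)
```

## The problem

Given a two-chain protein–protein complex — here the parasporin PS2Aa1
(ligand chain) against the aminopeptidase N receptor (partner chain) — the
package nominates candidate interaction residues in three stages: rank a
docking ensemble by interface hydrogen bonds, score every ligand-chain
residue over MD replicates by contact persistence and center-of-mass (COM)
distance, and aggregate replicate selections into prevalence counts. Each
stage is an ordinary tabular computation on tibbles, so the whole pipeline
is scriptable and each intermediate is inspectable.

## Models and criteria

**Interface hydrogen bonds.** With no explicit hydrogens, a bond is any
cross-chain pair of donor-element and acceptor-element heavy atoms (N, O,
S) with distance $d \le 3.5$ Å, excluding pairs closer than 1.8 Å, which
are treated as covalent. With explicit hydrogens, the donor must carry a
bonded hydrogen giving a D–H···A angle $\ge 120^\circ$. The 3.5 Å / 120°
defaults are the conventional geometric criteria used across structural
biology tooling; the upstream docking protocol that motivated this package
does not publish its own definition, so the criteria are exposed in
`hbond_criteria()` and recorded in every report. Counts of such bonds are
Euclidean-invariant, which the test-suite asserts under random rigid-body
transforms.

**Ranking.** `rank_models()` sorts descending by bond count with *stable*
ties: published rankings show tied models in no discernible secondary
order, so any tie-break beyond input order would be an invention; stability
at least makes the result reproducible.

**Contact persistence.** A ligand residue is in contact in a frame when any
of its heavy atoms lies strictly within 4.5 Å of any partner-chain heavy
atom. The persistence fraction is the share of such frames, and relevance
requires persistence $> 0.80$ (strict, per the usual "more than 80% of
simulation time" phrasing). The per-frame contact gate is deliberately a
*different* metric from the COM distance: published residue lists include
residues whose mean COM distance exceeds 5 Å while still "in contact" at
80% frequency, which is only consistent if contact is atomic, not
COM-based. The 4.5 Å atomic cutoff is this package's choice of a standard
heavy-atom contact distance; it is configurable in `contact_criteria()`.

**COM distance.** Per frame, the residue's mass-weighted COM (hydrogens
included when present; `heavy_only` switches exist for hydrogen-free
inputs) to the COM of the *closest* partner residue, ties resolved to the
lowest partner residue number. Per replicate the series is summarised by
its mean and *population* SD ($\sqrt{\sum (d_i-\bar d)^2 / N}$).

**Aggregation and prevalence.** The default pooling concatenates per-frame
distances across replicates before taking mean and population SD; because
the source tables do not state whether they pool frames or average
per-replicate means, a `replicate_means` mode implements the alternative.
Prevalence counts how many replicates selected each residue; tiers are
`all_replicates`, `majority` and `single` (labels are ours — prose
descriptions like "in all three replicas" do not name tiers). A unique
maximal count yields the top residue; ties yield `NA`, never an arbitrary
pick. When a single replicate is supplied, a count of 1 equals the
replicate total and is labelled `all_replicates`.

## The synthetic-data generator

No structures or trajectories were deposited for the motivating study, so
fixtures are generated, seeded and desk-scale:

* `generate_complex()` builds two glycine-like strands whose closest
  heavy-atom approach is driven to a requested separation within 0.1 Å.
* `generate_ensemble()` plants an exact number of cross-chain N···O bonds
  at 2.9 Å (linear when hydrogens are emitted), with all other cross-chain
  pairs kept outside 3.5 Å; every model is verified against the detector
  before being returned, so the planted count is the ground truth for
  ranking tests.
* `generate_trajectory()` plants, per ligand residue, i.i.d. Bernoulli($p$)
  contact frames and COM distances drawn from N($\mu$, $\sigma^2$)
  truncated below at 0.1 Å and realised geometrically to within a 0.05 Å
  tolerance that is asserted at generation time.

The trajectory geometry deserves a note. The planted constraints are joint:
on *every* frame the COM distance must equal the drawn value, while
non-contact frames require every heavy atom at least 6 Å from the partner
and contact frames require an atom within 4.5 Å — including cells where
$\mu = 4$ Å. A compact residue cannot satisfy "COM at 4 Å but all atoms
beyond 6 Å", so planted ligand residues are two-equal-mass-atom dumbbells
whose arm length and orientation are recomputed each frame: arms point at
the partner on contact frames (near atom ≈ 2.5 Å) and perpendicular on
non-contact frames (arm $= \sqrt{6.6^2 - d^2}$, keeping every atom ≥
6.25 Å away). Partner anchors are compact four-atom clusters with exactly
placed COMs, 15 Å apart so each planted residue's nearest partner is
unambiguous. Frame jitter (default 0.02 Å) is applied antisymmetrically
within dumbbells and COM-corrected within anchors, so planted distances
survive it exactly. This geometry is statistically faithful and physically
absurd — there is no force field, no solvent, no bonded chain — which is
the right trade for validating estimators against closed-form sampling
distributions. Passing tests therefore demonstrate correctness of the
*statistics*, not realism of the dynamics; on real trajectories, contact
frames are autocorrelated and the persistence estimator's variance is
larger than the i.i.d. binomial intervals used here.

Contacts are i.i.d. rather than Markov-correlated because the reported
statistic — the fraction of frames — is insensitive to frame order, and
i.i.d. draws give exact acceptance intervals: binomial for $\hat p$, normal
for $\hat\mu$, and $N s^2/\sigma^2 \sim \chi^2_{N-1}$ for the population
SD. The recovery suite runs the grid $p \in \{0.5, 0.8, 0.95\}$, $\mu \in
\{4, 6, 8\}$ Å, $\sigma \in \{0.2, 0.8\}$ Å at 500 frames with three
independent seeds per cell and requires at least 95% of cells inside all
three 99% intervals — with three statistics per cell the expected pass
rate is $0.99^3 \approx 97\%$, so the bar tolerates ordinary sampling
variation without hiding systematic bias.

## Numerical and I/O choices

* Coordinates are Å throughout; residue identity is (chain, residue
  number, residue name) with author numbering preserved; labels render as
  `GLY256`.
* Cutoff comparisons are strict (`<`) for interface membership and atomic
  contact, and `>` for persistence, matching the printed wording of the
  criteria; the H-bond distance maximum is inclusive.
* PDB is the only structure format (multi-model PDB for trajectories):
  text, diffable, and sufficient at desk scale. Parsing and serialisation
  go through `bio3d`; alternate locations keep the highest occupancy (ties
  keep the first record), waters and HETATM records are dropped by
  default, and elements fall back from the element column to atom-name
  inference. Trajectory frames are verified to share an identical topology
  key; the first offending frame is named in the error, since silent
  misalignment of frames would corrupt every downstream statistic.
* Result tables are TSV with doubles rendered at 2 decimals, matching how
  the field prints Å quantities; written tables therefore round-trip at
  that precision, and repeated pipeline runs produce byte-identical tables
  (timestamps live only in the provenance file).
* Degenerate inputs error early with typed conditions: empty structures,
  single-chain models for interface operations, zero-mass residues,
  unknown residue lookups, empty ensembles or replicate lists.

## Problem sizes

The bundled test-suite works at deliberately small scale, chosen so the
whole suite runs in well under a minute of compute per module: oracle
sweeps use 100 random 10+10-residue complexes against exhaustive
all-atom-pair scans, recovery uses 54 runs of 500-frame single-residue
trajectories, and end-to-end fixtures use 3 replicates of 20–60 frames.
These sizes are statistical choices (the closed-form intervals above are
already tight at $n = 500$), not limits of the implementation — the
vectorised frame-major code path analyses thousands of frames per second.

## Known limitations

* Heavy-atom H-bond mode cannot distinguish donor from acceptor when both
  atoms' elements qualify; the reported orientation is then a convention,
  not an inference.
* No energetic scoring (ΔG, buried surface area), no salt-bridge or π
  interactions, no RMSD/RMSF or conformational clustering: the scope is
  the geometric contact statistics described above.
* Prevalence has no significance model — with three replicates there is no
  meaningful null — so counts are reported as counts, and conclusions
  should rest on the planted-truth validation pattern when applied to new
  systems.
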