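---
title: "Methods: irregular G4 motifs, intra-locked topology and melting analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: irregular G4 motifs, intra-locked topology and melting analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadlock)
```

This vignette documents the models, conventions and numerical choices
behind the package: what each analysis computes, which parameters matter,
what the synthetic generators do and do not emulate, and where a design
was genuinely open and a choice had to be made.

## 1. Irregular PQS queries

Classical putative-quadruplex-sequence (PQS) scanning looks for four runs
of three or more guanines.  Sequences built from short G-tracts (two or
even single guanines) can nevertheless fold into stable G4s, so the
package scans for a generalised family: `n_tracts` ordered G-runs
separated by loops of `loop_min`–`loop_max` non-G nucleotides, with
`n_isolated` of the tract positions relaxed from `G{2,}` to `G{1,}`.
One query is emitted per choice of the isolated positions —
`choose(n_tracts, n_isolated)` queries; nine tracts with two isolated
positions give 36.

Conventions, all of which are deliberate choices where a published
procedure leaves room:

* **Greedy tracts.** `G{m,}` consumes a maximal G-run; a loop may neither
  begin nor end inside a G-run (loops match `[ACT]` only).  Because a
  loop must end where the next G-run begins, a candidate match
  decomposes deterministically — there is no backtracking ambiguity.
* **Strict mode** (`strict_tracts = TRUE`) requires every tract to be
  exactly its minimum length and unflanked by further guanines, so the
  match cannot be embedded in longer runs.
* **Overlap policy.** `leftmost_nonoverlap` (default) reports greedy
  non-overlapping matches, like `grep -o`; `grep_line` reports at most
  one hit per record and query — a record is counted like a matching
  line, which is how line-oriented text tools count; `all_overlapping`
  reports every distinct match start (a match may then begin inside a
  long G-run).  Whole-genome counts obtained with line-oriented tools
  depend on this choice, which is why all three are provided and the run
  manifest records the one used.
* **N and soft-masking.** `N` matches neither a tract nor a loop.  With
  `respect_softmask = TRUE` lowercase (repeat-masked) bases match
  nothing; by default case is ignored.  Genome assemblies are
  soft-masked, so both behaviours are needed.
* **Strand.** Default is forward-only; `rev`/`both` scan the reverse
  complement and report on forward coordinates with the matched-strand
  text.  Coordinates are BED-style 0-based half-open throughout.

The test suite checks the scanner against an independent brute-force
oracle that decides membership of every substring directly from the
run-length decomposition (500 random G-rich strings per run, fixed seed).

## 2. Topology from coordinates

The analysis chain is per model, with an ensemble consensus (a feature is
reported when present in more than half of the models).

**Glycosidic angles.** χ is the torsion O4′–C1′–N9–C4 in the standard
sign convention, mapped to [0, 360).  Classification uses open
intervals: syn for 0 < χ < 90, anti for 180 < χ < 240, otherwise
*undefined* — boundary values are undefined.  Ensemble values are
circular means with circular standard deviations.

**Hoogsteen edges and tetrads.** A directed edge donor→acceptor is
recorded when both heavy-atom distances N2(d)–N7(a) and N1(d)–O6(a) are
≤ 3.5 Å.  The cutoff is the canonical restraint target 2.9 Å plus two
tolerances of 0.3 Å; heavy atoms are used because deposited models may
lack protons.  Each guanine keeps at most one outgoing and one incoming
edge (closest total distance wins), making the edge set a partial
permutation whose simple directed 4-cycles are the G-tetrads; 3- or
5-cycles are warned about, never promoted.  A tetrad must be planar
within 0.75 Å RMSD of the best-fit plane of its base heavy atoms (the
published protocols restrain planarity but print no threshold; 0.75 Å
accepts NMR-quality tetrads and rejects accidental cycles).

**Stack and polarity.** The stack axis is the first principal direction
of the tetrad centroids; adjacent centroids must be 2.5–5.0 Å apart
(canonical stacking ≈ 3.3–4 Å with margin), otherwise the tetrads form
separate blocks and an error lists them.  Which stack end is "bottom" is
physically arbitrary, so the package adopts the convention that the
layer containing the lowest-numbered guanine lies in the bottom half —
the way these structures are customarily drawn.  A layer's polarity is
the circulation sense of its donor→acceptor cycle about the axis,
computed as the sign of Σᵢ (vᵢ × vᵢ₊₁)·axis with vᵢ the centroid→N9
vector of the i-th cycle member.  Only *relative* polarity between
adjacent layers (same/reverse) is interpreted; the absolute sign flips
under mirror reflection, as the tests verify.

**Corner columns.** Guanines of adjacent layers are matched into
stacking columns by nearest projected base centroids (projection onto
the plane perpendicular to the axis, greedy closest-pair matching).  A
fixed distance threshold was considered and rejected: at the canonical
~30°/layer helical twist, same-column base centroids project ≈ 2–2.5 Å
apart but sugar atoms project ≈ 5 Å apart, so any absolute C1′-based
cutoff is fragile while nearest-centroid matching is scale-free.

**Loop taxonomy.** For every maximal run of non-tetrad residues
(possibly empty) between two sequence-consecutive tetrad guanines:

| situation | kind |
|---|---|
| flanks in the same layer, cycle-adjacent / cycle-opposite | edgewise / diagonal |
| same column, adjacent layers, ≥ 1 loop residue | bulge |
| same column, ≥ 2 layers apart | V-shaped |
| different columns, either flank lacking covalent column support | V-shaped |
| different columns, both flanks supported, same polarity | propeller |
| anything else | linker (diagnosed, not classified) |

"Covalent column support" means a sequence-adjacent guanine occupying
the neighbouring layer of the same column — the G–G step that normally
props up a corner.  A V-shaped loop is precisely a connector across
layers where that support is missing.  V-loops are subtyped by the
relative polarity of the two connected layers: **V_S** (same) and
**V_R** (reverse); the span in layers is |Δlayer| + 1.  A 0-nt
same-column step between adjacent layers is an ordinary tract step, not
a loop.

This operational taxonomy was validated against the published stacking
pattern of the AT26 fold (derived from its inter-layer NOE pairs): it
reproduces the reported assignment for that fold — four propeller loops, one edgewise
loop, a 2-nt V_S loop spanning two layers, a 0-nt V_R loop spanning
three, and two bulges.

**Intra-lock.** Blocks are maximal groups of adjacent layers without a
polarity reversal.  Bridging linkers are connectors (loops, bulges,
V-loops or bare G–G steps) whose flanks lie in different blocks.  A
structure is *intra-locked* when ≥ 2 blocks are fastened by ≥ 2 bridging
linkers; two stacked but independent bi-layered blocks (a single
linker) are not locked.  The threshold of two is the minimal number
that mechanically couples the blocks' folding.

**Ensemble RMSD.** For every unordered model pair, optimal least-squares
superposition (via bio3d) on the chosen subset, then coordinate RMSD;
reported as mean ± SD over pairs.  The "tetrad core" is defined as *all
heavy atoms of the tetrad guanine nucleotides* — reported core-RMSD
values in the literature rarely state whether sugars are included, so
the subset is configurable (`tetrad_core_heavy` vs `all_heavy`).

## 3. Restraint generation

Restraint constants are fixed by the standard G4 NMR protocol and are
golden-value tested: Hoogsteen H-bond distances H21–N7 (2.0 ± 0.2 Å),
N2–N7 (2.9 ± 0.3 Å), H1–O6 (2.0 ± 0.2 Å), N1–O6 (2.9 ± 0.3 Å), four per
donor→acceptor pair hence 16 per tetrad; dihedral restraints anti
(240 ± 70)° and syn (60 ± 70)° with explicit exclusions for guanines of
undefined conformation (G3 in AT26); NOE classes strong/medium/
medium-weak/weak at (2.7 ± 0.8), (3.8 ± 0.9), (4.6 ± 1.2), (5.5 ± 1.7) Å
for non-exchangeable and strong/medium/weak at (4.0 ± 1.2), (4.8 ± 1.4),
(5.5 ± 1.7) Å for exchangeable protons, with a 0.5 Å loosening for
thymine-methyl contacts.  Output is a neutral TSV/JSON table; an
XPLOR-flavoured `assign` emitter is provided for convenience without any
claim of engine-exact syntax.  Planarity weights (1 kcal mol⁻¹ Å⁻² for
tetrads) are recorded as metadata only — structure refinement itself is
out of scope.

## 4. Two-state melting analysis

The observed signal is modelled as
s(T) = θ·s_F(T) + (1 − θ)·s_U(T) with linear baselines and
θ the fraction folded; Tm is *defined* as the temperature where
θ = 0.5, found by linear interpolation between the bracketing points of
the empirical θ series (a 5-point running mean suppresses point noise
around the crossing; for a transition antisymmetric about Tm the
crossing location is unchanged).

Baselines are first fitted to the lowest and highest
`baseline_fraction` (default 0.15) of the temperature span.  For broad
transitions — a van't Hoff enthalpy of −45 kcal/mol spreads the
transition over tens of degrees — the transition tails contaminate
those end windows and bias Tm by 0.5–3 °C.  The baselines are therefore
refined by a global two-state van't Hoff least-squares fit (Tm, ΔH and
both lines free, Nelder–Mead); only the refined baselines are kept, and
Tm is still read off the empirical θ = 0.5 crossing.  ΔH is a nuisance
parameter and is never reported.  A fit is flagged unreliable
(infinite `tm_uncertainty`, with a warning) when the global fit fails
or explains less than half of the signal variance, or the residual
noise exceeds a quarter of the baseline separation.

θ crossing 0.5 several times triggers a warning and the crossing
nearest the steepest part of the transition is used.  Heating and
cooling branches are combined as mean ± mean deviation
(`tm_consensus`); `delta_tm` is the signed difference variant −
reference.

## 5. What the synthetic generators emulate

`plant_motifs_fasta()` plants exact motif copies at random
non-overlapping positions (minimum gap, default 10 nt) in a background
drawn from {A, C, T}.  A G-free background cannot contain any G-tract,
so planted instances are provably the only matches and recall/false
positives can be measured exactly.  Real genomes differ in base
composition, repeat structure and soft-masking — the planted benchmark
validates the scanner's bookkeeping, not its genome-scale hit counts.

`build_ideal_g4()` realizes a *plan* — a strand path over
(column, layer) slots plus per-layer polarities — as coordinates:
guanine bases are placed as planar cyclic Hoogsteen quartets with
N2–N7 and N1–O6 at 2.90 Å (an in-plane placement of the standard
guanine geometry solved once by least squares), stacked at rise 3.3 Å
and twist 30°/layer; reverse-polarity layers are built with the
opposite cycle circulation; O4′ is placed by internal-coordinate
construction to realize the planned χ per residue; loop thymines are
minimal non-clashing spacers (three atoms) on an outer arc at ~11.5 Å
radius.  Jitter is a *bounded* displacement: each atom moves in a random
direction by a uniform amount up to the bound.  With jitter ≤ 0.15 Å a
planted Hoogsteen distance can reach at most 3.2 Å, strictly inside the
3.5 Å detection cutoff, so the 100%-recovery property of the randomized
tests is exact rather than statistical (unbounded Gaussian jitter of the
same scale would make tail failures inevitable).  The fixtures are
analyzer-grade idealizations: bond lengths, sugar puckers, backbone
connectivity and force-field realism are *not* modelled, mirror-image
geometry is used for reversed layers, and only the analyzer-facing
criteria (H-bond distances, planarity, stacking geometry, χ) are
contractual.  Passing on fixtures therefore demonstrates the analysis
logic, not robustness to experimental coordinate error beyond the
jittered range.

The canned plan `plan_at26_like()` is a structural twin of the
intra-locked AT26 fold: same tetrad compositions, same column/stacking
assignment (as implied by its inter-layer NOE pairs), polarity
(+, +, −, −), syn guanines at residues 2, 15 and 27 and χ = 317° at
residue 3.  `plan_two_block()` is the single-linker contrast (two
blocks, not locked), `plan_parallel()` the all-parallel control and
`plan_vs_loops()` exercises V_S loops of span 2 and 3.

`simulate_melting_curve()` draws the van't Hoff two-state curve
θ(T) = 1/(1 + exp((ΔH/R)(1/T − 1/Tm))) in absolute temperature
(so θ(Tm) = 0.5 exactly), applies linear baselines and adds Gaussian
noise; sampling follows the usual CD melting protocol (15–90 °C,
0.5 °C steps).  Defaults: ΔH = −45 kcal/mol (a typical value for a
four-layer G4 with short loops), unit amplitude, noise given in signal
units so `noise_sd = 0.01` is 1% of the default amplitude.

## 6. Problem sizes and determinism

Every stochastic component takes an explicit seed and restores the
global RNG state.  The test suite uses fixed seeds chosen beforehand and
runs at desk scale: 500 random strings for the scanner oracle, 200
randomized coordinate fixtures for the recovery property, 100 simulated
curves for Tm recovery, 10-model ensembles for RMSD — sizes at which the
properties are already exact or tightly bounded while the whole suite
stays interactive.  Genome-scale scans (hg38) and the deposited AT26
coordinates are supported by the same code paths and are exercised by
opt-in tests when the user supplies the data
(`QUADLOCK_HG38_FASTA`, `QUADLOCK_6KVB`).

## 7. Known limitations

* Only unmodified guanines (DG/G) participate in tetrad detection;
  modified nucleotides (e.g. LNA) are outside scope.
* Handedness (left- vs right-handed backbone progression) is not called;
  polarity signs are relative only.
* Tetrad detection assumes at most one Hoogsteen partner per guanine
  direction; bifurcated or pentad/hexad arrangements are reported as
  warnings, not classified.
* The melting module is strictly two-state; multi-state transitions are
  flagged at best (multiple crossings warning), never resolved.
* The grep-line overlap policy approximates line-oriented counting at
  record granularity; exact replication of published genome-wide counts
  additionally depends on assembly choice (alternate contigs, masking)
  which the run manifest records but cannot decide.
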