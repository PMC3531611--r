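---
title: "Methods: phospho-scanning inference of fibril architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phospho-scanning inference of fibril architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphozip)
```

## The problem and the idea

Amyloid fibrils share a cross-beta core: beta-strands hydrogen-bonded into
sheets at a 4.8 Å repeat along the fibril axis, with pairs of sheets packed
so tightly that their side chains interdigitate across a solvent-free "dry"
interface — a steric zipper.  For a given peptide there is a limiting set of
eight zipper symmetry classes (strand orientation × which sheet faces meet ×
sheet polarity), and deciding which class a real fibril adopts normally
requires crystallography, solid-state NMR or cryo-EM.

Phospho-scanning offers a cheap structural probe.  A phosphomonoester on
Ser/Thr/Tyr titrates twice, so its charge is 0 at strongly acid pH, −1 at
mildly acid pH and −2 near neutrality.  If a phosphate is placed at
different positions of an aggregation-prone peptide and the variants are
assayed at the three pH values, the pattern of which positions block
assembly in the mono-anionic regime reports on which positions sit close
together in the fibril: electrostatic repulsion between nearby phosphates
is what stops assembly.  This package implements that chain of reasoning
for strand E of beta-2-microglobulin (residues 59–71, `DWSFYLLYYTEFT`,
capped at both termini), whose variant-by-pH outcome matrix ships as a
built-in fixture (`strand_e_outcomes()`).

## Charge model

Each ionisable group is treated independently with Henderson–Hasselbalch
speciation:

* Asp/Glu carboxylates, pKa 4.0 (both exposed in `charge_model()`);
* the phosphate's two dissociations at pKa1 = 2.1 and pKa2 = 6.7;
* an extensible side-chain table (Lys 10.5, Arg 12.5, His 6.0, Cys 8.3) so
  sequences beyond strand E still receive standard charges;
* capped termini contribute nothing.

The phosphate pKa values are a modelling choice, not a measured quantity:
they are the canonical range for phosphomonoesters and place the dominant
species at 0/−1/−2 at the three assay pH values (1.1, 3.6, 7.5), which is
the constraint the analysis actually uses.  `net_charge()` offers a
`dominant` mode (integer, per-site dominant species; ties at a pKa resolve
deterministically toward the protonated species) and a `fractional` mode
(expected charge, continuous in pH).  Dominant-mode charge is
monotonically non-increasing in pH for acid-only sequences, and the two
modes agree once the pH is ≥ 2 units from every pKa — both properties are
enforced by the test suite.

No attempt is made to model pKa shifts inside the fibril, charge–charge
coupling, or anything beyond integer/fractional site charges.

## ThT kinetics processing

Replicate fluorescence curves are processed exactly as a plate would be:

1. **Blank subtraction** — the dye-only negative control is subtracted
   pointwise (several blank wells are averaged first).
2. **Plateau normalisation** — each curve is divided by the mean of its
   final 10% of points (`plateau_fraction = 0.1`).  The extent of "the end
   point" is a free choice; 10% uses enough points to average noise while
   staying inside the plateau for curves that finish rising by two-thirds
   of the acquisition.
3. **Half-time extraction** — aggregation curves here cannot be fitted by
   a closed-form growth model, so `compute_t50()` finds the first upward
   crossing of 0.5 after the curve's global minimum (the global-minimum
   guard stops a downward noise spike from creating a spurious early
   crossing) and interpolates linearly between the bracketing samples:
   `t50 = t1 + (t2 − t1)(0.5 − y1)/(y2 − y1)`.  On a two-point bracket the
   formula is exact by construction; on a sampled sigmoid the error
   vanishes with the sampling step (the crossing sits at the inflection,
   where linear interpolation is most accurate).
4. **Replicate summary** — the per-well half-times are binned into 10
   equal-width bins over their range and a Gaussian
   `a·exp(−(x−μ)²/2σ²)` is least-squares fitted to bin centres and counts
   (unweighted; initialised at the sample moments with amplitude = tallest
   bin).  `μ` and `|σ|` are reported.  When the fit fails, explains less
   than half the count variance (R² < 0.5) or returns a σ wider than the
   data range, the summary falls back to the sample mean/SD and warns.
   With 40 replicates whose spread is narrow relative to the mean the
   histogram over `[min, max]` only spans ±1.5σ and is nearly flat, so the
   fallback fires regularly; the `method` field records which estimator
   produced each summary.  Forty identical values are returned directly
   with SD 0 — no fit is attempted on a degenerate histogram.
5. **Assembly calling** — a set whose median final plateau does not exceed
   `noise_k = 5` baseline standard deviations is called `no_fibrils` and
   right-censored at the last time point, mirroring how a plate with no
   visible fibrils after 4 days is reported as "t50 > 4 days" rather than
   with a number.

## Idealized zipper geometry

The builder is deliberately parametric — ideal bond lengths and angles,
uniform backbone dihedrals (default φ = −139°, ψ = +135°, the textbook
antiparallel beta conformation), Cβ placed tetrahedrally, no side chains
beyond Cβ, and no force field.  The coordinate convention is x = strand
axis, y = fibril (hydrogen-bond) axis, z = sheet normal.  A strand is
oriented so its carbonyls lie along y and its side-chain pleat along z;
sheets stack strands at 4.8 Å along y; zippers place two sheets 12 Å apart
between mean planes.  The resulting sheets put the bonded alternation of
backbone N···O contacts at 2.78–2.9 Å without any minimisation, which is
the geometric sanity check the tests enforce.

Antiparallel registries are generated from the pairing rule
`i ↔ (N+1) − i + s`: `s = 0` is the in-register pairing (5 ↔ 9 on a
13-mer), and the shifted registry uses `s = −1` (5 ↔ 8, 9 ↔ 4).  The
shift is exposed as a parameter; −1 is the default because it is the
registry that pairs Tyr5 with Tyr8′ and leaves Tyr9 opposite a
non-phosphorylatable position — the pattern the outcome screen requires —
while aligning the aromatic core.  In-register flips rotate the strand
180° about the sheet normal (faces preserved, as the same-parity pairing
requires); shifted flips rotate about the hydrogen-bond axis (faces
swapped, as the opposite-parity pairing requires).

The eight zipper classes are kept in one recorded taxonomy table
(orientation × face packing × polarity → id 1–8, plus the generating
rigid motion for sheet 2).  The two classes whose strand symmetry admits
the shifted registry are 7 and 8; they differ only in which faces meet at
the interface.  Their generating operations are anchored by the published
inter-sheet distance patterns for this peptide: pure translation along
the sheet normal (face-to-back) reproduces the class 7 pattern, and a
180° rotation about the strand axis (face-to-face) the class 8 pattern.
A steric check rejects any build that brings atoms of different sheets
within 2.2 Å; all eight classes build clash-free at the defaults.

### The Cβ–Cβ distance measure

`average_cb_distance(model, p)` averages, over every chain whose residue
`p` presents its Cβ **into the interface**, the distance to the nearest
interface-facing Cβ of the same position on the opposite sheet.  The
restriction to interface-facing side chains is the package's definition
and it matters: without it, some chain of the opposite sheet always sits
directly across the 12 Å gap, so the unrestricted nearest-pair average is
close to the sheet separation for *every* position and cannot
distinguish anything (the unrestricted variant remains available via
`interface_only = FALSE`).  Physically the restriction is the point — the
phosphates whose repulsion the argument invokes are the ones inside the
dry interface.

On the default class 7 build this measure gives 13.76 / 13.61 / 19.51 Å
at positions 5/8/9 — the split pattern (9 isolated, 5 ≈ 8) with values
within the ±1.5 Å tolerance appropriate for rigid ideal geometry.  The
class 8 build gives 8.4–8.8 Å at all three positions: the comparability
(spread < 0.5 Å) is reproduced, but the absolute values sit ~2 Å below
those of energy-minimised models, because a rigid ideal pleat at a fixed
12 Å plane separation packs face-to-face Cβ atoms closer than relaxed
side chains do.  The screening logic uses the *pattern* (gap between
aggregating and blocked positions), which is insensitive to this offset;
the absolute class 8 values are a known limitation of the no-force-field
design and are documented as such.

A note on the build parameters: the source description of the reference
models gives "two sheets of eight beta-strands each, separated by 12 and
4.8 Å" — read here as sheets 12 Å apart and strands 4.8 Å apart, the only
physically buildable assignment (a 4.8 Å plane-to-plane sheet separation
interpenetrates the side-chain pleats and fails the builder's own clash
check).  Both class builds therefore default to 12 Å.  Whether that 12 Å
is plane-to-plane or atom-to-atom is unstated in the source;
plane-to-plane is chosen and used consistently.

## Architecture screening

The screen turns a qualitative argument ("blocked variants must have
their phosphates closer than aggregating ones") into an explicit decision
rule.  For each candidate:

* **schematic arrangements** are scored by registry offset in residues,
  `|2p − (N+1) − s|` for antiparallel pairings, 0 for parallel
  (every site stacks on itself);
* **built models** are scored in Å by `phosphosite_separation()` —
  single-site variants use the inter-sheet Cβ average at their site;
  the double variant p3S10T is scored by its minimum over site pairs,
  where cross-site pairs (3, 10) use the nearest Cβ–Cβ contact between
  distinct chains anywhere in the assembly.  The cross-site term is what
  distinguishes p3S10T from p3S and p10T: in the shifted registry sites 3
  and 10 land on the same strand-axis register of adjacent strands, 4.8 Å
  apart, a phosphate–phosphate clash invisible to same-position scores.

A candidate survives only if every aggregating variant's separation
exceeds every non-aggregating variant's — strictly for the schematic
screen (equal spacing cannot explain different outcomes), and by a margin
(default 3 Å) for the model screen.  The 3 Å default is roughly the gap
the class 7 geometry opens between position 9 and positions 5/8, minus
the build tolerance; it is exposed as a parameter and the audit trail
prints every separation so the rule is inspectable.  Elimination is
monotone in the margin.  Outcome rows at pH 1.1 (everything aggregates)
and pH 7.5 (every phosphovariant blocked) are accepted but impose no
constraint; the control, with no phosphosite, never constrains.  The
screen reports *consistency*, not proof, and carries its standing
assumption — that all variants assemble into a common fibril morphology —
in the report header.

On the fixture the chain is: 3 arrangements → antiparallel shifted →
classes {7, 8} → class 7.

## Water penetration

Zipper integrity in multi-frame coordinate data is quantified by counting
water oxygens inside the dry interface.  The interface region is the
package's own geometric definition (the source of the criterion never
defines one): a slab between the two sheets' mean planes inset 1 Å on
each side, intersected with the prism over the convex hull of the
interface-facing Cβ projections dilated by 2 Å.  All geometry is computed
in the model's own frame (the sheet-normal axis joins the sheet
centroids), so counts are invariant under rigid motion — a property the
tests check against a brute-force point-in-prism oracle.  Points exactly
on a boundary are excluded (strict inequalities).  Waters are their
oxygen positions; hydrogens are ignored.

`penetration_series()` recomputes the region on every frame, so sheet
drift degrades the slab naturally; a frame whose mean-plane gap exceeds
twice the initial gap marks the trajectory dissolved outright (structural
collapse), regardless of count.  The verdict is `stable` only when every
frame holds fewer than 5 interior waters — the dryness criterion the
analysis inherits.  Ions are counted and reported separately but do not
enter the verdict, matching how the criterion is stated in terms of
waters alone.

## Synthetic data: what it does and does not show

`simulate_tht_replicates()` generates
`blank + A_i · L(t; τ_i, k) + ε(t)` with `τ_i ~ N(μ, σ)`,
`A_i ~ N(A, cv·A)` and white noise; L is logistic by default (a Gompertz
mode exists for asymmetry-robustness tests, with the ground-truth
half-time offset `−log(log 2)/k` accounted for).  The logistic is a
deliberate stand-in: the assay's curves resist closed-form fitting, and
any monotone sigmoid exercises the normalisation/interpolation path
identically.  Defaults are one plate condition: 40 replicates, half-time
10 ± 1 s, plateau 100 ± 10 (arbitrary units), noise SD 1 (1% of
plateau), blank 50, 121 time points to 3× the mean half-time.  A
wide-spread preset (`true_t50_sd` at half the mean) emulates the
condition where no single half-time is meaningful.  Recovery at these
defaults — pipeline mean within 2% and SD within 25% of truth, averaged
over seeds 1–10 — is an acceptance property of the package.

`simulate_zipper_trajectory()` jitters the base model (SD 0.3 Å by
default), recomputes the interface region on the jittered coordinates,
and places exactly the scheduled number of interior waters uniformly in
the region (2.8 Å water–water exclusion; impossible schedules raise a
capacity error) plus scheduled exterior waters outside it.  Because
placement follows the jitter, the ground-truth interior count is exact by
construction — which is precisely what makes it an oracle for the
counting code, and precisely why it says nothing about real water
dynamics.  The preset plateau levels in `traj_water_presets()` (dry;
60/20/0; 55/35/35) reproduce the qualitative behaviour classes of
solvated simulations of the three phosphotyrosine variants, as
annotations only: nothing in this package simulates solvent physics, and
passing these tests shows the counting and verdict logic is correct, not
that any fibril dissolves.

The same caveat applies across the package: synthetic plates have
Gaussian well-to-well variation and white noise but no drift, no
outlier wells, no dye depletion; ideal zippers have no twist, no
rotamers, no relaxation.  Green tests certify the inference machinery,
not the biology.

## Problem sizes and runtime

All computations are desk-scale by design: 8×2 zippers of a 13-mer
(1040 atoms), 40-replicate plates of ~121 points, trajectories of ~11
frames with ≤ 100 waters.  The full test suite and the analysis scripts
each run in well under a minute on one CPU.

## Known limitations

* Class 8 absolute Cβ–Cβ distances are ~2 Å below minimised-model values
  (see above); only the pattern is load-bearing.
* The charge model is per-site and context-free; fibril-environment pKa
  shifts are out of scope.
* The screen's decision rule collapses electrostatics to a distance
  threshold; it cannot weigh many small repulsions against one large one.
* PDB export marks only backbone + Cβ; no rotamers are fabricated.
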