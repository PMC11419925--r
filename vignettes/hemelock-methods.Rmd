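---
title: "The HemeLock method: interaction census, index, and Tm model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The HemeLock method: interaction census, index, and Tm model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemelock)
```

## Scope and model

`hemelock` quantifies how firmly a protein holds its heme cofactor and
maps that quantity onto melting temperature. The chain of reasoning is:

1. heme b carries two propionate side chains whose carboxylate oxygens
   accept hydrogen bonds, carbon hydrogen bonds and salt bridges from
   nearby residues;
2. across a structural ensemble, the *frequency* of each contact category
   and its *mean distance* summarise how persistent and how tight the
   lock is;
3. a weighted sum of frequency/distance ratios, plus an inverse
   residue-volume term for the key contact position, gives a single
   dimensionless **HemeLock index**;
4. the index relates linearly to the experimentally measured Tm.

The package implements the census, the index, the linear model and its
per-isozyme refinement, and the surrounding enzyme-kinetics arithmetic.
It does **not** run molecular dynamics, evaluate force fields, or fit
melt curves: its structural input is coordinate snapshots (single or
multi-model PDB), typically exported from an MD trajectory.

## Geometric criteria

All detection is heavy-atom only; hydrogens are never required, which
matches how the criteria are defined (the donor-hydrogen position is
implicit). A donor D, acceptor A (carboxylate oxygen), donor antecedent X
and acceptor antecedent Y (the carboxylate carbon) must satisfy:

| parameter | default | meaning |
|---|---|---|
| `d_max_no` | 3.4 Å | max D–A distance for N/O donors |
| `d_max_sc` | 3.8 Å | max D–A distance for S/C donors (backbone Cα included) |
| `d_max_salt` | 5.6 Å | max charged-N to carboxylate-O distance, Arg/Lys |
| `angle_min`, `angle_max` | 90°, 180° | window for both X–D–A and D–A–Y |

Salt bridges carry no angle condition and use the minimum distance over
the residue's charged nitrogens (NH1/NH2/NE for Arg, NZ for Lys) per
carboxylate oxygen.

Conventions that the criteria alone do not fix, and how this package
resolves them:

* **Antecedent combinations.** An interaction passes if *any* antecedent
  X gives both angles in the window — the most permissive reading of a
  two-angle definition. The accepted antecedent is recorded per event.
* **Dual classification.** An Arg/Lys nitrogen within 3.4 Å that also
  passes the angle test satisfies the hydrogen-bond and salt-bridge
  criteria independently, so both events are recorded by default;
  `salt_bridge_mode = "priority"` keeps only the salt bridge for users
  who prefer exclusive categories.
* **Donor dictionary.** The backbone donor is the Cα of every residue;
  sidechain polar donors are the standard N/O hydrogen-bond donors
  (Ser OG, Thr OG1, Tyr OH, Asn ND2, Gln NE2, His ND1/NE2, Trp NE1,
  Arg NE/NH1/NH2, Lys NZ), Cys SG is a sulfur donor, and every Cβ is a
  sidechain carbon donor. The dictionary is an editable table
  (`default_donor_rules()`, YAML-overridable via
  `read_interaction_config()`), so a curated list can be dropped in
  without code changes.
* **Propionates.** Both propionate groups (A and D) are acceptors by
  default; the scanner can be restricted to one
  (`default_acceptors(groups = "A")`), which is the group directly
  involved at the key contact position in lignin peroxidase.
* **Events are deduplicated** at the (donor atom, acceptor atom,
  category) level within a frame, so a donor contacting both oxygens of
  one carboxylate yields two events (they are distinct contacts).

## Frequencies

The published component ranges (backbone term up to 0.750 with weights
near 3 and distances near 3.5 Å) are consistent with a frequency on a
0–1 scale, so the default frequency is the **frame fraction**: the share
of frames in which the residue makes at least one contact of the
category. An `events_per_frame` mode (mean event count per frame, which
can exceed 1) is available; it is never smaller than the frame fraction.
Zero-event categories have I = 0 and an undefined mean distance, and the
corresponding index term contributes exactly 0 — forced by the ratio form
of the score, since any other convention would divide by an undefined
distance.

## The index and the linear model

With weights `w = (w1, w2, w3, w4, w5)`:

* interaction score = `w1·BBCHI/BBCHD + w2·SCHI/SCHD + w3·SCCHI/SCCHD +
  w4·SCSBI/SCSBD` (all units dropped by convention);
* size score = `w5 / volume(residue)`, using the Zamyatnin residue
  volumes shipped with the package (Gly 60.1 … Trp 227.8 Å³). This table
  was chosen because the published size-score endpoints (3.186 for Ala,
  1.239 for Trp at w5 = 282.3) are reproduced to four significant
  figures by 282.3/88.6 and 282.3/227.8, which the test suite asserts;
* HemeLock index = their exact sum; `Tm = a·index + b`.

The embedded published model is `w1 = 2.974, w2 = 0.9201, w3 = w4 = 0,
w5 = 282.3, a = 4.995 °C/unit, b = 42.86 °C`. Whether the two zero
weights were fitted to zero or dropped a priori is not documented; the
implementation carries all four terms and simply sets w3 = w4 = 0 in the
published vector, so users refitting on their own panels can recover
non-zero values.

### Fitting and identifiability

`hemelock()` fits the model to a variant panel. With fixed weights the
problem is ordinary least squares and is solved in closed form via `lm`.
When weights are free, the objective (maximal R² of Tm on the index) is
invariant under positive rescaling of the whole weight vector — the scale
is absorbed by `a`. The fitter therefore anchors `w5` (default 282.3) and
optimises `w1..w4 ≥ 0` by multi-start bounded local search (L-BFGS-B),
deterministic under a configurable seed. One start is the closed-form
warm start obtained by regressing Tm on the five per-term ratio
regressors and refactoring the coefficients as `a·w` (clamped to the
non-negative orthant); the published weights and seeded random draws
provide the remaining starts. Because of the anchoring, recovery tests
assert the weight *ratios* `w1/w5` and `w2/w5`, which are identifiable.

Degenerate inputs follow explicit conventions: identical indices across
the panel raise a degenerate-fit error; identical Tm values yield slope
0 with R² reported as 0 (the total sum of squares is zero, so the
conventional ratio is undefined and 0 is reported).

### Per-isozyme refinement

`refit_w5()` transfers a fitted model to a homologous isozyme by holding
`w1, w2, w3, w4, a, b` fixed and re-estimating only the size weight `w5`
to minimise the mean squared Tm error (denominator n, matching the plain
"mean squared error" reading). The prediction is linear in `w5`, so the
error curve is an exact parabola; `stats::optimize` on a bounded interval
finds its minimum to tolerance 1e-8, and the tests confirm agreement with
a dense grid scan.

## Trajectory observables

* **Superposition** is the Kabsch least-squares proper rotation (SVD with
  determinant correction, so reflections are excluded); selections of
  fewer than 3 atoms or collinear selections are rejected.
* **RMSD** defaults to the protein-core Cα selection, excluding the
  flexible termini (propeptide −7..−1 and C-terminal 329..344 under
  mature-protein numbering) — the convention under which ensemble
  stability is usually monitored for this enzyme family. The ranges are
  configurable per input.
* **Distance traces** report per-frame distances between two single atoms
  with mean and sample (n−1) standard deviation; published "±" values do
  not state their convention, and the sample form is this package's
  choice. A single-frame trace reports sd = 0 with a `degenerate` flag
  rather than NA. The anchor pair for the residue-181 observable is the
  propionate-A carboxylate oxygen and the residue Cα by default — the
  atom pair shown in the structural figures — and both selectors are
  configurable.
* Coordinates are treated as non-periodic: the interactions measured here
  are intra-complex and short relative to any reasonable solvent box.

Trajectories are carried as multi-model PDB, not binary DCD: the format
is text, diffable, and parsable everywhere (reading is delegated to
`bio3d`, with package-side validation of MODEL balance, per-model
topology, line-numbered coordinate errors, and the altloc policy: blank
and 'A' kept, others dropped with a count). Writing rounds to the
format's 3-decimal precision, and the round-trip tests assert
coordinate agreement at that precision.

## The synthetic-data generators

`make_pocket_trajectory()` emulates the geometry the census consumes: a
minimal heme (one carboxylate oxygen plus its carbon per propionate) and
minimal donor residues, one per requested donor. Placement is by explicit
geometric construction — the donor position is solved from the target
distance and both target angles, then jittered — rather than rejection
sampling, so window membership is guaranteed and the noiseless limit is
exact. Choices worth knowing:

* One oxygen per propionate keeps every event attributable to exactly one
  (donor, acceptor) pair, so the programmed occupancy maps one-to-one
  onto the recovered frame fraction.
* In-window jitter is clamped to conservative sub-windows (e.g. polar
  donors d ∈ [2.85, 3.39] Å, X–D–A ∈ [130°, 170°]) chosen so that the
  donor's own antecedent atoms can never drift inside a cutoff and
  create spurious events. Out-of-window placement is at 6.5–7 Å, clear
  of every cutoff.
* Default conditions: three donors (backbone 0.7, polar 0.5, salt bridge
  0.3 occupancy), 100 frames, 0.05 Å and 3° jitter — a persistent
  backbone contact with weaker polar/ionic partners, the pattern seen in
  stabilised heme pockets.

What the generator does **not** emulate: physical realism. There is no
excluded volume, no solvent, no correlated motion, no force field; frames
are independent Bernoulli draws. Passing recovery tests therefore
demonstrates that the census, aggregation and regression machinery are
correct — not that the geometric criteria themselves are the right model
of bonding in real trajectories.

`make_variant_panel()` draws per-variant summaries from plausible spans
(the weighted backbone term stays within 0–0.75 and the sidechain
hydrogen-bond term within 0–0.35) and applies a known linear Tm law with
Gaussian noise; `make_decay_series()` and `make_saturation_series()`
produce exponential decays and Michaelis–Menten rates on the 50–2000 µM
substrate grid used in practice (an 8-point grid by default). Every
generator returns its ground truth alongside the data and is
deterministic, byte-identical under a fixed seed.

## Kinetics conventions

* Residual activities are normalised to the t = 0 point before the
  ln(activity)-on-time regression; non-positive activities at late times
  are excluded with a count rather than failing the series, and a rising
  series yields a negative kd with a warning flag instead of an error.
* t½ = ln 2 / kd exactly, and the record keeps that identity.
* Michaelis–Menten fits use `minpack.lm::nlsLM` with Vmax₀ = max rate,
  KM₀ = concentration at half-max, both parameters bounded positive. A
  KM pinned at its lower bound (flat, saturated rates) is flagged
  (`km_boundary`) rather than reported as a confident estimate.
  Replicates are fitted as pooled points.
* Specific activity converts an absorbance slope via Beer–Lambert with
  ε310 = 9.3 mM⁻¹cm⁻¹ (one unit = 1 µmol product per minute); enzyme
  concentration from the heme Soret band uses ε409 = 168 mM⁻¹cm⁻¹.

## Problem sizes and tolerances in the test suite

The suite validates the scanner against an independent exhaustive
all-pairs oracle on 1000 random small frames; occupancy recovery on
500-frame ensembles at occupancies {0, 0.3, 0.6, 1.0} against exact
binomial 99% intervals; regression recovery on 12-variant panels, with
95% CI coverage measured over 200 replicate panels at σ = 1 °C; and
kinetics closed forms at machine precision. These sizes give the
stochastic checks comfortable statistical resolution while keeping the
default test run fast. Exact checks use tolerances at or below 1e-9;
statistical checks use the interval implied by their own sampling
distribution.

## Known limitations

* The published headline correlation between index and Tm (fitted on
  MD-derived interaction summaries over hundreds of nanoseconds) cannot
  be reproduced here: those per-variant summaries are not redistributable
  inputs. The packaged experimental-Tm fixture supports the bookkeeping
  (Tm gains between variants) and model-evaluation surfaces only.
* π-stacking, cation–π, hydrophobic contacts, heme-iron coordination and
  water-mediated bridges are out of scope; so are mmCIF input and DSSP
  analysis.
* The donor dictionary is a reasonable default, not a curated appendix;
  users with a vetted donor list should supply it via the config file.
* Whether "weighted frequency" in the original formulation implies any
  weighting beyond the w factors (e.g. per-propionate weighting) is not
  documented; this implementation applies none.
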