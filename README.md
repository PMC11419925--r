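# hemelock

Quantifying heme–protein non-bond interactions and predicting the
thermostability of heme enzymes from them.

## The problem

Heme enzymes such as fungal lignin peroxidases lose their cofactor — and
their activity — well below the temperatures industrial biocatalysis would
like to run at. How tightly the protein "locks" the heme in place turns
out to track melting temperature (Tm): variants whose residues pack closer
to the heme propionate groups and hydrogen-bond to their carboxylates melt
later. `hemelock` implements the computational side of that observation as
a reusable pipeline for structural bioinformaticians and enzyme engineers:

1. **Interaction census.** Given structural snapshots or a multi-model PDB
   ensemble, the scanner detects hydrogen bonds, carbon hydrogen bonds and
   salt bridges between heme propionate carboxylate oxygens and amino-acid
   donors, using heavy-atom geometric criteria: donor–acceptor distance
   d ≤ 3.4 Å for N/O donors (≤ 3.8 Å for S/C donors, backbone Cα
   included), both the X–D–A and D–A–Y angles in 90–180°, and d ≤ 5.6 Å
   for Arg/Lys salt bridges.
2. **HemeLock index.** Per residue and interaction category, the census is
   reduced to a frequency *I* (fraction of frames with a contact) and a
   mean distance *D*. The index combines them with an inverse
   residue-volume term:

   ```
   interaction score = w1·BBCHI/BBCHD + w2·SCHI/SCHD + w3·SCCHI/SCCHD + w4·SCSBI/SCSBD
   size score        = w5 / volume(residue 181)           [Å³]
   HemeLock index    = interaction score + size score
   ```

3. **Linear Tm model.** `Tm(°C) = a · index + b`, fitted by OLS (weights
   fixed) or by multi-start weight optimisation maximising R². The
   published fit is embedded: w1 = 2.974, w2 = 0.9201, w5 = 282.3,
   a = 4.995, b = 42.86, with a per-isozyme refinement of w5 available
   (`refit_w5()`).
4. **Kinetics arithmetic.** Specific activity from Beer–Lambert slopes
   (ε310 = 9.3 mM⁻¹cm⁻¹), first-order thermal deactivation constants
   (kd from ln(activity) regression, t½ = ln 2 / kd) and Michaelis–Menten
   fits.
5. **Synthetic ground truth.** Seedable generators build heme-pocket
   trajectories with programmed interaction occupancies, variant panels
   obeying a known linear Tm law, and kinetics series — so every stage is
   testable without an MD engine.

## Worked example

Census a synthetic 200-frame pocket ensemble, score the contact residue,
and predict Tm:

```r
library(hemelock)

pocket <- make_pocket_trajectory(
  donors = data.frame(kind = c("backbone", "polar"), occupancy = c(0.9, 0.4)),
  n_frames = 200, seed = 7)
agg <- aggregate_events(scan_trajectory(pocket$trajectory))
agg
#>   chain resseq resname category     I        D n_events n_frames
#> 1     A    181     GLY    BB_CH 0.880 3.498597      176      200
#> 2     A    182     SER     SC_H 0.415 2.992762       83      200

bd <- hemelock_index(summary_for_residue(agg, 181), "ALA")
bd
#> <score_breakdown> ALA: index = 3.9343
#>   interaction score 0.7480 (BB_CH 0.7480, SC_H 0.0000, SC_CH 0.0000, SC_SB 0.0000)
#>   size score        3.1862
predict_tm(bd)
#> [1] 62.50851
```

The backbone donor was programmed at 88% occupancy near 3.5 Å; the scanner
recovers I = 0.880 and D = 3.50 Å, worth 0.748 index units, and the
alanine size term (282.3 / 88.6 Å³ = 3.186) dominates — together
predicting a melt near 62.5 °C.

Fitting the linear model on a simulated variant panel (true law
Tm = 4.995·index + 42.86, 1 °C noise):

```r
fit <- hemelock(make_variant_panel(sigma = 1, seed = 2)$panel,
                weights = hemelock_weights())
fit
#> HemeLock index-to-Tm linear model
#>   Tm = 4.656 * index + 43.87  (n = 12, R^2 = 0.930, MSE = 1.43)
#>   weights (fixed): w1=2.974 w2=0.9201 w3=0 w4=0 w5=282.3
confint(fit)
#>       2.5 %    97.5 %
#> a  3.752948  5.558489
#> b 41.254469 46.490076
```

The usual methods apply: `coef`, `summary`, `predict`, `residuals`,
`plot`, `simulate`. `pclip_tm_panel()` ships the experimental Tm values of
the PcLiP01 variant set (`tm_gain(p, "E40S/V181A")` → +8.66 °C over wild
type).

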