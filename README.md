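# LineageHomeo

Statistics and models for time-lapse single-cell lineages of bacteria —
built for asking why a population of cells with normal single-cell growth
can still lose fitness. The canonical setting is the comparison of a
rod-shaped strain with a spherical mutant: the mutant's cells elongate at
the ancestral rate, yet sisters grow unequally, septa are misplaced, newborn
volumes spread into both tails, and cells in those tails fail to produce
offspring. LineageHomeo quantifies each link in that chain.

## What it computes

For a lineage forest (cells with volume trajectories, mothers and fates):

- **Elongation rate** per cell, from `V(t) = V0·e^(rt)` by least squares on
  `log V` (`fitElongationRate`), and the **septation rate** `ln 2 / τ̄`
  (`septationRate`); their balance classifies the size-homeostasis regime
  (`homeostasisCheck`) — septation faster than elongation means shrinking
  progeny.
- **Sister asymmetries** over pairs `(1,2)` sharing a mother
  (`extractSisterPairs`, `asymmetrySummary`):
  `Cg = ⟨|r1−r2|/(r1+r2)⟩`, `CT = ⟨|T1−T2|/(T1+T2)⟩` (both on pairs where
  both sisters proliferate), and the septum-placement precision
  `Cs = ⟨|V1−V2|/(V1+V2)⟩` on birth volumes.
- **Survival probability** `p` — the fraction of non-censored cells of a
  generation that divide — with the Wald 95% interval `1.96·√(p(1−p)/N)`
  (`survivalProbability`), and its profile over birth-volume bins
  (`survivalVsVolume`). The effective population growth rate is `p·r`
  (`effectiveGrowthRate`), from `dN = p·r·N·dt`.
- **Adder bookkeeping**: per-cycle added volume `ΔV = V_division − V_birth`
  (`addedVolume`); under adder control mean birth volume converges to the
  mean added volume within a few generations.
- **Shape metrics**: compactness `C = √(4·Area/π) / major axis` (1.0 for a
  circle), shape-branched volume `Ve` (ellipsoid at `C ≥ 0.7`,
  spherocylinder below), and the division-axis rotation `|sin θ|`.
- **Thin-shell mechanics** (Young–Laplace): `ΔP = 2T/R` (sphere), `T/R`
  (cylinder); at equal turgor and tension a rod of radius `Rc` rounds up to
  `Rs = 2Rc`, with volume ratio `Vs/Vc = 32·Rc/(3L)` — a factor 1.78 for a
  1 × 3 µm rod.
- **Bulk fitness**: doubling time `ln 2 / k`, generations `log2(Nf/N0)`,
  selection coefficient `s = ln(R(t)/R(0))/t` with relative fitness `1 + s`,
  and semi-log growth-curve phase identification (lag, max rate, yield).
- **A lineage simulator** (`simulateLineages`) with exponential growth,
  adder-triggered division, antisymmetric sister-rate noise calibrated to a
  target `Cg` (`calibrateSigmaG`), septum noise calibrated to `Cs`
  (`calibrateSigmaS`), and a U-tailed survival-vs-volume curve — so every
  estimator can be exercised against known ground truth.

## Worked example

Simulate a strongly perturbed spherical-mutant-like strain — sister rate
asymmetry 55%, septum error 19.4%, survival dropping outside 2.2–4.4 µm³ —
and analyse it like a tracked data set:

```r
library(LineageHomeo)

cfg <- SimulationConfig(sigma_g = calibrateSigmaG(0.55),
                        sigma_s = calibrateSigmaS(0.194),
                        survival = c(V_lo = 2.2, V_hi = 4.4,
                                     p_mid = 0.95, steepness = 2.5),
                        n_founders = 100, seed = 1)
lt <- simulateLineages(cfg)
lt
#> LineageTable: 826 cells (100 founders, generations 0-3), 17992 observations
#>   fates: divided 363, arrested 169, censored 294

survivalProbability(lt, generation = 1)
#> p = 0.580 +/- 0.068 (95% CI, N = 200)

pairs <- extractSisterPairs(lt, generation = 1)
asymmetrySummary(pairs)
#> Cg = 0.559 (n = 37), CT = 0.5405 (n = 37), Cs = 0.1719 (n = 100)

survivalVsVolume(lt, bins = c(0, 2.2, 4.4, 50), generation = 1)
#>   bin_lo bin_hi   N         p ci_halfwidth flagged
#> 1    0.0    2.2  20 0.2500000   0.18977618   FALSE
#> 2    2.2    4.4 157 0.6815287   0.07287582   FALSE
#> 3    4.4   50.0  23 0.1739130   0.15490703   FALSE
```

Reading the output: only 58% of first-generation cells manage to divide, and
the volume profile shows why — survival collapses in both tails (p = 0.25
below 2.2 µm³ and 0.17 above 4.4 µm³ versus 0.68 in the centre), which is
exactly the signature that misplaced septa (`Cs ≈ 0.17`) and unequal sister
growth (`Cg ≈ 0.56`, recovering the calibration target 0.55) produce. The
mechanical prediction for the rod-to-sphere transition is desk-scale:

```r
round(sphereToCylinderVolumeRatio(Rc = 0.5, L = 3), 2)
#> [1] 1.78
```

Real tracking data enter through `readLineageTable()` (long CSV, one row per
cell per frame, `# key=value` metadata header); see the package vignette in
`vignettes/lineage-homeostasis.Rmd` for the models, calibration details and
the simulator's assumptions.

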