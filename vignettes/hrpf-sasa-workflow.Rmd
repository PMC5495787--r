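---
title: "From footprinting dose-response to absolute side-chain SASA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From footprinting dose-response to absolute side-chain SASA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement model

Hydroxyl radical protein footprinting (HRPF) oxidizes amino-acid side
chains in proportion to how often a diffusing radical encounters them.
Fast photochemical oxidation of proteins (FPOP) generates the radicals
by laser photolysis of hydrogen peroxide; mass spectrometry with
electron-transfer dissociation (ETD) reads out the oxidized fraction of
each residue. Two physical quantities set a residue's apparent
reactivity:

* its **intrinsic chemistry** — free-amino-acid rate constants with
  hydroxyl radical span roughly three orders of magnitude; and
* its **steric exposure** — the average solvent accessible surface
  area, written ⟨SASA⟩, of its side chain.

`hrpfsasa` implements the chain of normalizations that isolates the
second quantity from the first, and turns the result into absolute
per-residue ⟨SASA⟩ estimates that can score candidate structural
models.

The pipeline, stage by stage:

1. **Residue-level quantification** (`peptide_oxidation_fraction()`,
   `residue_oxidation_fraction()`). Peptide oxidation is the oxidized
   share of summed species intensities. ETD c/z fragment ions localize
   it: the oxidized intensity fraction at each cleavage estimates the
   cumulative oxidation N-terminal to that cleavage, and differences
   between consecutive cleavages apportion it to residue segments.
2. **Dose-response regression** (`effective_dose()`, `fit_slopes()`).
   Oxidation is measured at several radical doses; the dose axis is the
   drop in adenine dosimeter absorbance at 260 nm (ΔA260), which folds
   radical generation and scavenging into one effective-dose number.
   Oxidation varies linearly with effective dose, and the per-residue
   slope of an ordinary least-squares regression is the residue's
   radical response rate.
3. **Normalization** (`npf()`, `native_denatured_ratio()`). Two routes:
   * *Free-amino-acid route*: the normalized protection factor
     NPF_i = Slope_i / (k_i/k_p), dividing by the residue type's rate
     constant relative to proline.
   * *Native:denatured route*: Slope_N/Slope_D for the same residue
     measured in folded and thermally denatured protein. Whatever
     sequence context does to a residue's intrinsic reactivity, it
     does identically in both states, so the ratio cancels it — no
     rate table needed.
4. **Structural reference** (`shrake_rupley()`,
   `ensemble_mean_sasa()`, `gxg_reference()`). Side-chain SASA is
   computed per structure and averaged over a conformational ensemble;
   fractional exposure divides by the fully-exposed value of the same
   residue type in an extended Gly-X-Gly tripeptide. The Gly-X-Gly
   value also serves as the denatured-state ⟨SASA⟩ model.
5. **Calibration and prediction** (`fit_calibration()`,
   `predict_sasa()`, `jackknife()`, `evaluate_predictions()`). An
   empirical line maps normalized reactivity (x) to fractional
   exposure (y); prediction inverts the measurement by applying the
   line to new reactivities and rescaling by the Gly-X-Gly reference
   to absolute Å². Robustness is assessed by a leave-one-out
   jackknife; accuracy by the prediction RMSD (Å²) and by R² computed
   against the identity line y = x, not a refitted line — the two
   differ, and the identity-line convention is the one that matches
   "predicted vs actual" plots.
6. **Model ranking** (`rmsd_sasa()`, `rank_models()`,
   `discrimination_report()`). Candidate structures are scored by
   RMSD_SASA = sqrt(Σ(SASA_current − SASA_ref)²/n) over the n residues
   present in both vectors. A reference can come from a crystal
   structure or entirely from footprinting. Models with backbone RMSD
   < 3 Å from the native structure should score systematically lower
   than models beyond 4 Å; `discrimination_report()` checks exactly
   that separation.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `probe_radius` | 1.4 | Å | water-sized probe, the universal convention |
| `n_points` | 960 | — | isolated-sphere error < 1%; cost is linear in points |
| van der Waals radii | shipped CSV | Å | united-atom values (C 1.87, N 1.65, O 1.40, S 1.85); carbons inflated to absorb unmodelled hydrogens |
| k/k_p table | shipped CSV | relative to Pro | compiled from aqueous radiolysis rate constants; the analysis is conditional on this table, which is data, not code |
| reactivity classes | >10 high, 4–10 moderate, <4 poor | k/k_p | boundary values fall downward (10 → moderate, 4 → poor) |
| `min_kkp = 4` filter | optional | k/k_p | free-amino-acid normalization degrades below it; used when calibrating in NPF mode |
| sulfur exclusion | on | — | Met/Cys suffer background oxidation that inflates apparent reactivity |
| `min_t = 3` detection filter | optional | t-statistic | a residue whose slope is under 3 SE carries no reactivity signal; mirrors "observed oxidized" coverage |

## The SASA engine

SASA uses the Shrake–Rupley construction: `n_points` test points on
each atom's solvent-expanded sphere (radius r_vdw + probe), a point is
exposed if outside every neighbouring expanded sphere, and the atom's
SASA is the exposed fraction of 4π(r+probe)². The test points come
from a golden-spiral (Fibonacci) lattice rather than random sampling,
so results are bit-stable across runs with no seed to manage.
Side-chain SASA sums atoms other than N, CA, C, O, OXT; hydrogens are
dropped at parse time (united-atom convention). Glycine reports zero
and is flagged; it never enters calibration. Per-residue values
partition the per-atom total exactly — this is asserted in the tests,
not just documented. Coincident atoms of equal radius occlude each
other symmetrically (boundary points count as exposed); non-finite
coordinates are an error.

The Gly-X-Gly reference table is *generated by the package itself*
(`build_gxg_reference()`): an extended (φ = −120°, ψ = +120°)
glycine-X-glycine backbone is built from ideal internal coordinates,
the side chain of X is grafted from a shipped library of idealized
amino-acid geometries, swept through twelve χ1 rotamers about the
CA–CB axis, and the central residue's side-chain SASA is averaged over
the sweep. Sweeping only χ1 (not the full rotamer tree) keeps the
generator simple; the resulting values agree with classical tripeptide
side-chain areas to within a few Å², and a test regenerates the
shipped table from scratch and requires agreement within 5%. Proline's
ring is kept rigid (no sweep), which yields a slightly smaller value
than tables that relax the ring.

## The synthetic study

Footprinting studies rarely deposit machine-readable per-residue
oxidation data, so the package carries a generator
(`simulation_config()`, `make_structures()`, `simulate_hrpf()`) that
emulates the statistical structure the analysis assumes, and the whole
test suite runs against it.

The generative law is

```
slope_i = c · (k_i/k_p) · fractionalSASA_i · context_i
```

with `c = 0.02` per ΔA260 unit, a per-residue lognormal
`context_i` whose log-SD is 0.15 / 0.4 / 0.8 for the high / moderate /
poor reactivity classes (sequence context perturbs poorly reactive
residues most — the qualitative finding the ratio route exists to
fix), five doses ΔA260 ∈ {0.05, …, 0.25}, three replicates, and
Gaussian replicate noise with SD `sqrt((0.05·μ)² + (2e-5)²)` — mostly
signal-proportional, because replicate footprinting quantification has
roughly constant relative precision across its dynamic range, with a
small absolute floor. The denatured state keeps each residue's
`context_i` but sets fractional SASA to 1 (the Gly-X-Gly model of a
denatured chain), so Slope_N/Slope_D equals fractional SASA exactly at
zero noise — the cancellation theorem the tests exercise end-to-end.

Structures are a 64-residue chain traced through a 4×4×4 serpentine
lattice with backbone pseudo-atoms and bulk-scaled side-chain
pseudo-atoms, giving genuinely buried interiors; an "unfolding" series
displaces all atoms along a fixed seeded field with 20 strictly
increasing magnitudes (0.3–6 Å); the native ensemble is five jittered
snapshots (SD 0.15 Å). The slope-recovery study refits 200
independently simulated replicates. These sizes are the package's
deliberate desk-scale choices: large enough for burial, class coverage
and stable correlations, small enough that the full suite runs in
about a minute.

What the generator does **not** emulate: radical diffusion and
scavenging kinetics, peptide digestion and MS sampling (coverage is
complete by construction), real side-chain geometry and rotamer
packing, secondary structure, and any nonlinearity in the
dose-response (multi-point FPOP is treated as linear throughout, as
the method assumes). Passing tests therefore demonstrate that the
*inference machinery* is correct under the model's own assumptions —
they do not certify accuracy on any real protein.

## Numerical and design choices

* **Regressions.** Plain unweighted OLS everywhere, with an intercept
  by default (`force_origin` available); inverse-variance weighting is
  deliberately not the default since replicate SDs are plotted, not
  modelled, in the practice this package follows. Errors-in-variables
  fitting is not used: both axes carry error, but prediction only ever
  maps x to y.
* **Regression direction.** Fractional exposure (y) on normalized
  reactivity (x), because prediction runs that way; the direction is
  configurable in `fit_calibration()`.
* **Dual-protein calibration** pools points from both proteins rather
  than averaging per-protein fits.
* **Residue-set policy in RMSD_SASA**: strict key intersection, n
  counts only compared residues, and footprinting-derived references
  never impute unmeasured residues — imputation would fabricate
  agreement.
* **ETD apportionment rule.** Cumulative fragment fractions are
  anchored at f(0) = 0 and f(L) = 1; negative consecutive differences
  (fragment noise) are clipped to zero with a warning and shares are
  rescaled to conserve the peptide-level fraction. Segments between
  unobserved cleavages are reported as unresolved ranges, never split
  by guesswork. The rule lives behind a single function so an
  alternative apportionment can replace it; residue-level ETD
  quantification conventions differ between laboratories and this
  default should not be assumed to match any particular one.
* **Altloc policy**: highest occupancy wins, ties broken by altloc
  letter; multi-MODEL files become ensembles; HETATM kept only via an
  explicit retain list (e.g. `"HEM"`).
* **Ensemble SD** is the population SD across snapshots (weighted when
  weights are given).
* **Clipping**: predicted fractional exposure below 0 clips to 0 with
  a warning; fractions above 1 are kept with a warning (surface
  residues can exceed the tripeptide reference).

## Known limitations

* The k/k_p table is a compilation; any statistic that depends on it
  is conditional on the table. The native:denatured route exists
  precisely to avoid this dependence.
* The Gly-X-Gly table is a reconstruction from idealized geometry, not
  a copy of any published table; regenerate with
  `build_gxg_reference()` if you change radii or probe.
* Whether published side-chain accessibility analyses used side-chain
  or whole-residue SASA is often ambiguous; this package defaults to
  side-chain-only and exposes `whole_residue = TRUE`.
* No mmCIF input; no nonlinear (radical-depletion) kinetics; no
  hierarchical multi-protein calibration beyond pooling.

## Reproducing the headline numbers

`scripts/acceptance.R` regenerates two synthetic proteins, runs both
normalization routes, calibrates on one protein, predicts absolute
⟨SASA⟩ for the other, ranks the unfolding series against crystal- and
footprinting-derived references, and writes every statistic as JSON:

```{sh}
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
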