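---
title: "Quality-by-design formulation development with nlcqbd: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-by-design formulation development with nlcqbd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlcqbd)
```

`nlcqbd` implements the computational chain behind a quality-by-design (QbD)
development of a nanostructured lipid carrier (NLC) formulation: screening of
process factors with a two-level fractional factorial design, response-surface
optimization on a central composite design (CCD), multi-response desirability
optimization, diffusion-controlled release-kinetics fitting, and the scalar
characterization formulas used for lipid nanoparticles. This vignette explains
each model, its assumptions, the tunable parameters, and the design choices
made where conventions were genuinely open.

## 1. Experimental designs and coding

Factors live on two scales. The *natural* scale carries units (mg of solid
lipid, µl of oil, minutes of sonication); the *coded* scale is dimensionless,
with the convention

$$x = \frac{X - \text{center}}{\text{step}},$$

so the factorial levels sit at $\pm 1$. All model fitting happens on coded
variables — the standard response-surface convention — because it keeps the
design matrix well conditioned and makes coefficients comparable across
factors. `to_natural()` and `to_coded()` convert both ways; natural axial
levels are displayed rounded to one decimal (e.g. a lipid factor with center
500 mg and step 250 mg has axial levels $500 \pm 250\sqrt2$, displayed as
853.6 and 146.4 mg).

`ffd_design(k, p, generator)` builds the canonical standard-order
$2^{k-p}$ fraction. The generator defaults, for $p = 1$, to aliasing the last
factor with the interaction of all base factors (`E=ABCD` for $k = 5$), the
standard highest-resolution half fraction: every main effect is then aliased
only with a four-factor interaction (resolution V). The defining-contrast
subgroup, resolution and alias sets are computed from the generator words by
symmetric-difference algebra, and `alias_structure()` exposes them. Worth
noting: the packaged 16-run screening table's fifth factor column equals the
product of the first three (a resolution-IV labelling). Because main-effects
estimation only needs column orthogonality and balance — which hold for any
half fraction — the screening analysis is unaffected by which labelling
generated the table, and the generator choice matters only when *new* designs
are created.

`ccd_design(factors, alpha, n_center)` builds the CCD in standard order:
$2^k$ factorial points, $2k$ axial points, `n_center` center replicates
(default 5). `alpha = "rotatable"` gives $(2^k)^{1/4}$, i.e. $\sqrt 2$ for
two factors, which places every non-center point on a circle of radius
$\sqrt2$ — the design's support, and later the optimization region.
Randomized run order is seed-controlled and stored separately
(`$run_order`); the canonical standard-order table is never shuffled, so
designs are reproducible objects and the randomization is metadata.

## 2. Screening ANOVA

For a balanced two-level design the effect of factor $j$ is the difference of
mean responses at its high and low levels; the coded regression coefficient
is half of that. Because the columns are orthogonal contrasts, each main
effect carries a single-degree-of-freedom sum of squares
$SS_j = n\,\beta_j^2$ and the decomposition
$\sum_j SS_j + SS_{res} = SS_{tot}$ is exact, independent of fitting order.
`screen_anova()` computes these from the contrasts directly and tests each
factor with $F = SS_j / MS_{res}$; the test suite cross-checks every number
against an independent `lm()`/`anova()` route.

The model is *main effects only*. With 16 runs and 5 factors this leaves 10
residual degrees of freedom; including all two-factor interactions would
saturate the design and make the residual test impossible without pooling,
so the simplest self-consistent model is used and saturated requests fail
with an explicit pooling message. The default significance level is 0.01,
and no multiple-testing correction is applied across responses — raw
p-values are always reported so any threshold can be applied downstream.

On the packaged screening table this selects the solid-lipid amount for
particle size, nothing for the polydispersity index, and lipid plus
surfactant for the Z-potential:

```{r screening}
t1 <- qbd_table("table1")
coded <- code_two_level(t1, c("lipid_mg", "surfactant_mg", "oil_ul",
                              "sonication_min", "power_pct"))
screen_anova(coded, t1$size_nm, alpha = 0.01)
```

## 3. Response-surface models and selection

Four nested polynomial classes are available on coded variables: first-order,
first-order plus two-factor interactions, pure quadratic (linear + squared
terms), and full second-order. All are ordinary least squares via `lm()`;
$R^2$ is the ordinary centered coefficient of determination.

**Selection criterion.** Because the classes are nested, ordinary $R^2$ is
monotone in the term set and would always pick the full second-order model.
`select_model()` therefore ranks classes by *adjusted* $R^2$ (ties broken
toward fewer parameters) while reporting both. On the packaged CCD table
this yields second-order for particle size ($R^2 = 0.80$) and pure quadratic
for PDI ($R^2 = 0.97$) and Z-potential, reproducing the study's selections;
for the Z-potential the ordinary $R^2$ of the selected pure-quadratic model
computes to 0.64 from the packaged table.

**Prediction error.** `predict(..., se = TRUE)` returns the standard error
for a *new observation*, $s_{pred} = \hat\sigma\sqrt{1 + h}$ with $h$ the
leverage of the new point, plus the relative error
$100\,s_{pred}/|\hat y|$. The new-observation form (the $+1$ term) was
chosen because the quantity is used to judge whether a freshly synthesized
formulation matches its prediction; it is always at least the residual SD.
Prediction outside the coded design radius warns (extrapolation) but does
not fail.

## 4. Desirability optimization

Each response is mapped to $[0,1]$ with the Derringer–Suich
smaller-is-better transform

$$d(y) = \begin{cases} 1 & y \le A \\ \left(\frac{B-y}{B-A}\right)^s & A < y < B \\ 0 & y \ge B,\end{cases}$$

and the overall desirability is the geometric mean
$D = (\prod_i d_i)^{1/m}$, so a single unacceptable response annihilates
$D$.

**Bounds convention.** The defaults take $A$ and $B$ as the *observed*
minimum and maximum of each response in the design table
(`specs_from_data()`), which is how desirability analyses are conventionally
driven when no external specification limits exist; an alternative mode
derives bounds from the fitted surfaces' range over the design disk
(`specs_from_surfaces()`). The data-range convention is the package default
because it is determined by the experiment itself and, on the packaged
tables, it locates the joint optimum at $D = 0.90$ near 617 mg lipid /
707 mg surfactant. The shape exponent defaults to $s = 1$ (linear), and all
specifications are plain lists, so alternative bounds or weights are one
argument away. The Z-potential is minimized as its signed value in mV,
consistent with treating all three responses uniformly.

**Optimizer.** `maximize_desirability()` runs a self-contained Nelder–Mead
simplex (reflection 1, expansion 2, contraction 0.5, shrink 0.5; convergence
when the simplex diameter falls below $10^{-8}$ or after 500 iterations)
from every design point plus seeded random starts, with points outside the
design region (coded disk of radius $\sqrt2$ by default; a box mode exists)
penalized to $D = 0$. Desirability surfaces are only piecewise-smooth —
flat at $d=1$/$d=0$ plateaus with kinks at the bounds — which is exactly
where simplex methods are more trustworthy than gradient ones; the
multi-start covers the risk of a start landing on a flat region, and a
run in which *every* start collapses to $D=0$ warns explicitly. The test
suite checks the optimizer against a $201 \times 201$ grid-search oracle.

```{r desirability}
tab <- qbd_ccd_table()
surfaces <- lapply(c(size_nm = "size_nm", pdi = "pdi", zeta_mv = "zeta_mv"),
                   function(r) select_model(tab, r)$surface)
maximize_desirability(surfaces, specs_from_data(tab, names(surfaces)),
                      seed = 7,
                      factors = list(
                        factor_spec("lipid_mg", center = 500, step = 250),
                        factor_spec("surfactant_mg", center = 700, step = 200)))
```

## 5. Release kinetics: the Crank sphere model

For diffusion out of a monolithic sphere with uniformly dispersed drug, the
released fraction $F = M_t/M_\infty$ admits two classical approximations in
the reduced time $x = K\tau$, with $\tau = \max(t - t_{lag}, 0)$:

* early time (valid to $F \approx 0.4$): $F = 6\sqrt{x/\pi} - 3x$;
* late time (valid from $F \approx 0.6$): $F = 1 - \frac{6}{\pi^2}e^{-\pi^2 x}$.

The late-time exponent is negative — the expression must decay toward
complete release — and the rate constant $K$ (h⁻¹) lumps geometry and
diffusivity. The lag time models the delay imposed by a dialysis membrane
and is applied as a pure time shift, with $F = 0$ before $t_{lag}$.

**Joining the branches.** The two approximations never cross: across their
common mid-range the late expression sits about 0.05 *above* the early one
(the gap depends only on $x$, so it is the same for every $K$), and their
closest approach (6 × 10⁻⁴) happens near $F = 0.87$, far outside the early
branch's validity. Any hard switch therefore puts a visible step in the
curve. `release_fraction()` instead blends linearly over the window in
which the rising early branch passes from 0.4 to 0.6: pure early below,
pure late above, continuous everywhere. Each branch also carries a `valid`
attribute flagging its own range, so users can see when a value comes from
outside an approximation's validity zone.

**Fitting.** `fit_release()` follows a staged procedure:

1. $K$ from the late-time linearization: $\log(1-\bar F)$ is linear in $t$
   with slope $-\pi^2 K$ over points with $\bar F \ge 0.6$ (replicates
   averaged first). The regression is weighted by $(1-\bar F)^2$ — the
   delta-method variance factor of the log transform — because with additive
   noise on the fraction scale the log residuals explode as $\bar F \to 1$
   and unweighted least squares lets near-complete-release points dominate.
   The weights change nothing for noise-free data.
2. $t_{lag}$ by least squares of the joined model against *all* observed
   points, $K$ held fixed, searched over $[0,\ \text{first sampling time}]$.
3. Optionally (`joint = TRUE`), simultaneous refinement of $(K, t_{lag})$
   by Nelder–Mead on the fraction-scale sum of squares — the recommended
   final step for noisy data, since that scale is where the noise is
   homoscedastic.

$R^2$ and MSE are reported over all points of all replicates. Fractional
release is structurally independent of the initial drug mass — the model has
no dose parameter — mirroring the diffusion-controlled mechanism.

## 6. Characterization formulas

* Entrapment efficiency: $EE = (W_0 - C_{FR} V_f)/W_0 \times 100$, with
  $W_0$ the drug input (mg), $C_{FR}$ the free-drug concentration (mg/ml)
  and $V_f$ the final volume (ml). Negative results are reported with a
  measurement warning rather than clipped silently.
* Drug loading: the same encapsulated mass divided by the lipid-phase mass.
  The denominator defaults to solid lipid plus oil, the oil converted from
  volume at a configurable density (0.95 g/ml default);
  `lipid_phase_mass()` makes the convention explicit and a solid-lipid-only
  denominator is just a different argument.
* Crystallinity index: $CI = \Delta H_{disp} / (\Delta H_{ref} \times C\%)
  \times 100$, with the bulk myristyl myristate reference
  $\Delta H_{ref} = 241.91$ J/g as the default and the lipid-phase
  concentration in % w/v.
* Bragg inversion: $d = \lambda / (2\sin\theta)$ with $\theta$ half the
  scattering angle; $\lambda$ defaults to 0.154 nm (Cu Kα), so d-spacings
  are reported in nanometres. (The packaged diffraction table's printed
  column header says Å, but its values are numerically nanometres; the
  package keeps nm throughout.)
* Replicate summaries use the $n-1$ sample SD; `two_sample_t()` provides
  pooled and Welch statistics in closed form with the $p=1$ convention for
  identical zero-variance groups.

## 7. Synthetic data generators

Every pipeline stage has a seeded generator so the whole chain is testable
without laboratory data. `sim_doe_responses()` evaluates a known
second-order surface at any coded design and adds i.i.d. Gaussian noise;
`sim_release_curve()` samples the joined Crank model (defaults:
$K = 0.033$ h⁻¹, $t_{lag} = 0.2$ h, nine sampling times over 24 h,
$\sigma = 0.02$ on fractions, six replicates — a realistic dialysis release
study regime) and clips to $[0, 1.05]$; `sim_replicates()` draws replicate
measurements. Gaussian noise is used everywhere because no richer error
model is identifiable from summary tables; that is also the generators'
main limitation: real DLS and HPLC errors are typically heteroscedastic and
occasionally skewed, real release profiles can show adsorption artifacts,
and none of that is emulated. Passing tests on synthetic data therefore
demonstrate correctness of the estimators under the stated model, not
robustness to instrument-specific artifacts.

## 8. Numerical choices and degenerate inputs

* Nelder–Mead: standard coefficients, simplex-size tolerance $10^{-8}$,
  500-iteration cap, seeded multi-start; out-of-region points get $D = 0$.
* Release fitting needs at least two qualifying late-time points below
  complete release; fewer is an explicit insufficient-data error, and a
  non-positive fitted $K$ is a fit-failure error rather than a silent
  absurdity.
* A lag estimate that converges to the lower search boundary is snapped to
  exactly 0 when that is at least as good, so true zero-lag curves report 0.
* Exact ties in model selection (all classes interpolating) resolve to the
  smallest class.
* Two-level coding requires exactly two distinct natural levels per factor;
  anything else is an error, not a guess.
* The table loader normalizes Unicode minus signs and reads
  semicolon-separated files with decimal commas, the two transcription
  hazards of the packaged tables' source format.

## 9. Test problem sizes

The suite exercises the estimators at sizes chosen to keep Monte-Carlo
tolerances honest while remaining quick: 2000 null-calibration screening
tables, 500-replicate coefficient-bias checks, 200-simulation release
recovery at the default noise regime, a $201\times201$ desirability grid
oracle, and $10^5$-draw law-of-large-numbers checks on the replicate
generator. All simulations are seeded and deterministic.

## 10. Known limitations

* Fraction generators and fits assume the sphere model; Higuchi,
  Korsmeyer–Peppas and Baker–Lonsdale comparators are out of scope.
* Only smaller-is-better desirability is implemented — the shape the joint
  minimization needs; target-is-best and larger-is-better are not provided.
* General $2^{k-p}$ fractions require an explicit generator for $p > 1$;
  there is no minimum-aberration search, blocking, or split-plot support.
* The screening ANOVA is main-effects-only by design; interaction screening
  would need pooling rules that are deliberately left to the analyst.
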