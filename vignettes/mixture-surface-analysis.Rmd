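---
title: "Modelling entomopathogen-insecticide mixture bioassays with epfmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling entomopathogen-insecticide mixture bioassays with epfmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epfmix)
```

## The problem

Microbial control agents (entomopathogenic fungi such as *Beauveria
bassiana* or *Cordyceps farinosa*) are increasingly co-applied with
conventional insecticides (here, the lipid-synthesis inhibitor
spiromesifen) against pests such as the glasshouse whitefly. The question
a mixture bioassay answers is whether the combination kills more, less, or
exactly as much as one would expect from the two agents acting
independently. `epfmix` implements the full analysis chain for such
two-agent bioassays: single-agent concentration-response fitting, the
independent-action (Bliss) reference surface with parametric deviations,
nested model selection, interaction classification, lethal-time (LT50)
estimation, and the ANOVA-based decision of which replicate bioassays may
be pooled. A synthetic-data generator reproduces the replicated
leaf-cohort design so every stage can be exercised and validated without
access to raw laboratory data.

## Reference model

Each agent alone follows a two-parameter log-logistic on the unaffected
fraction, with an additive background mortality and the upper limit fixed
at one:

$$\mathrm{mortality}(c) = 1 - (1 - m_0)\, q(c), \qquad
  q(c) = \frac{1}{1 + (c/\mathrm{EC}_{50})^{\beta}}.$$

This is the simplest family consistent with a monotone dose-response and
with what the mixture reference needs; richer four-parameter upper limits
are reserved for the time-to-kill model, where a plateau below one is an
observed feature of the data. Lethal concentrations are defined on the
Abbott scale (mortality over and above background):
$\mathrm{LC}_x = \mathrm{EC}_{50}\,(x/(1-x))^{1/\beta}$, so the LC50
equals the EC50 exactly.

Under independent action (Bliss independence), the probability of
surviving the mixture is the product of the single-agent survival
probabilities, $P_m = p_A\, p_B$. Two agents each killing 25% leave a
joint unaffected fraction of $0.75^2 = 0.5625$; two agents each killing
80% leave $0.04$, i.e. 96% expected mortality. The latter identity is
also the design rule the generator's default layout respects: mixture
cells whose expected mortality exceeds 90% are excluded
(`design_ceiling_filter()`), because interactions cannot be resolved when
nearly everything is expected to die anyway.

## Deviation surfaces

The fitted mixture surface is

$$P = \mathrm{logit}^{-1}\bigl(\mathrm{logit}(q_1 q_2) + G\bigr), \qquad
  \mathrm{mortality} = 1 - (1 - m_0)\,P,$$

where $G$ is a parametric deviation evaluated on the toxic-unit
composition of the mixture: $tu_i = c_i/\mathrm{EC}_{50,i}$,
$T = tu_1 + tu_2$, $z_i = tu_i/T$. The supported patterns are

| kind | form | interpretation |
|------|------|----------------|
| `NONE` | $G = 0$ | independent action |
| `SA` | $G = a\,z_1 z_2$ | the same deviation at every composition |
| `DR` | $G = (a + b\,z_1)\,z_1 z_2$ | deviation depends on the mixture ratio; sign switches at $z_1^\* = -a/b$ |
| `DL` | $G = a\,z_1 z_2\,(1 - b\,T)$ | deviation depends on the total dose level; sign switches at $T = 1/b$ |

Design choices worth stating explicitly:

* **Where the deviation enters.** $G$ is added on the logit of the joint
  unaffected fraction. This keeps predictions inside $(0,1)$ for *any*
  parameter values, reduces exactly to the reference at $G = 0$, and
  vanishes identically on the single-agent edges ($z_1 z_2 = 0$), so the
  mixture surface always agrees with the single-agent curves there. The
  insertion is isolated in one place (`predict_surface()`) so an
  alternative transformation could be swapped in.
* **Sign convention.** $a > 0$ means antagonism: positive $G$ raises the
  survival logit, hence lowers mortality relative to independent action.
  The synergy-signed quantity used for classification and reported in the
  interaction map is $-G$. This is stated in the printed output because
  mixture-toxicity sign conventions vary across software.
* **Composition scale.** $z$ is defined on toxic units, not raw doses, so
  "the proportion of the mixture" is potency-weighted. The `DR` switch
  point is reported both as $z_1^\*$ and as a raw dose ratio
  $(\mathrm{EC}_{50,2}/\mathrm{EC}_{50,1})(1-z^\*)/z^\*$, since users
  usually express it as a concentration ratio; the relative potency
  $\mathrm{EC}_{50,1}/\mathrm{EC}_{50,2}$ is reported alongside.

Fitting (`fit_surface()`) maximises the joint binomial likelihood of all
replicate-level counts — control, single-agent and mixture cells together,
on *uncorrected* mortality, since $m_0$ is part of the model — or
minimises the sum of squared proportion residuals; $R^2$ is always
reported on observed vs predicted proportions, whatever the objective.
When the data pool several bioassays, each bioassay gets its own $m_0$ by
default: each has its own control cohort, and forcing one background rate
onto heterogeneous controls leaks lack-of-fit into the deviation terms
(a single shared $m_0$ remains available via `m0_by_bioassay = FALSE`).
The deviation and single-agent parameters stay shared, so nested-test
degrees of freedom are unaffected.
Fungal doses should be the measured deposition (conidia mm⁻²), chemical
doses the nominal concentration; no chemical deposition assay exists in
this design, and the asymmetry is deliberate. Initialisation is a
deterministic multi-start (single-agent edge fits anchor the EC50s and
slopes; deviation parameters start at 0 and ±1), and deviated fits restart
from the fitted null so that a larger model can never end up with a worse
objective than the model nested inside it.

Model selection (`compare_surface_models()`) walks the nested chain
`NONE` → `SA` → {`DR`, `DL`} with likelihood-ratio tests (or
$N\ln(SS_0/SS_1)$ for least-squares fits) against $\chi^2$ with the
parameter difference as degrees of freedom, keeping the simpler model
unless $p < \alpha$ (default 0.05). Note the parsimony tie-break: a
deviated model must *earn* its parameters.

## Time to kill

`fit_time_mortality()` fits the four-parameter probit-on-log-time law

$$F(t) = \mathrm{lower} + (\mathrm{upper} - \mathrm{lower})\,
  \Phi\!\bigl(\mathrm{slope}\,(\log t - \log \mathrm{LT}_{50})\bigr),$$

so the curve passes through $(\mathrm{lower}+\mathrm{upper})/2$ at
$t = \mathrm{LT}_{50}$ by construction. Deaths observed at 48-h censuses
are interval-censored onto the census day. Because repeated censuses of
one cohort are not independent binomial draws, the default likelihood
treats each replicate cohort's census increments as a single multinomial
draw over death intervals plus a survivors' cell; a per-census binomial
option exists for comparison with simpler tools, and the two agree
closely in practice. Standard errors come from the observed information
with the delta method on $\log \mathrm{LT}_{50}$; confidence intervals
are profile-likelihood on log time by default (with a log-scale Wald
option), because the profile respects the asymmetry that appears when the
mortality plateau is only weakly identified inside the horizon and the
quadratic approximation is then too narrow. An LT50 beyond the study
horizon is reported with an `extrapolated` flag rather than being
censored, since published tables do print such values (with
correspondingly enormous standard errors).

`compare_lt50_constraint()` refits all treatments jointly with one shared
LT50 (treatment-specific lower, upper and slope) and compares against the
free model by a likelihood ratio on $\#\mathrm{treatments} - 1$ degrees
of freedom. `lt50_reduction_table()` reports, per mixture, how many days
faster the mixture reaches 50% mortality than the *faster* of its two
single agents, with errors propagated as the root sum of squares;
negative reductions are reported, not suppressed.

## Pooling replicate bioassays

Whether replicate bioassays may be combined is decided as in practice: a
two-way ANOVA of Schneider-Orelli-corrected terminal mortality on
treatment and bioassay (Type II sums of squares, inert in the balanced
case but pinned for unbalanced data), followed by pairwise t-tests
between bioassays with Bonferroni adjustment. Pairwise contrasts are
computed on residuals after removing treatment means, so bioassay
differences are not confounded by treatment composition; a raw-means
option exists for comparison. The pooling partition is the set of
*maximal* bioassay subsets containing no significant pair — these may
overlap (e.g. {1,2} and {1,3} when only 2 vs 3 differ), in which case the
overlapping sets are analysed separately. The partition is advisory: the
pipeline consumes an explicit user-chosen pooling set, because silent
automation of that decision would make analyses hard to reproduce.

The Schneider-Orelli correction itself is
$(a - b)/(100 - b) \times 100$ on percentages. Negative corrected values
(treated mortality below control) are returned with a warning rather than
truncated at zero — truncation would bias the downstream ANOVA.

## The synthetic generator

`generate_bioassay()` and `generate_time_course()` draw data with the
statistical structure the analysis assumes, from one truth record:

* 12 treatment cells plus control (`default_mixture_design()`): LC15,
  LC50, LC80 singles of both agents; LC15 crossed with all three partner
  levels; LC50 × LC15; LC50 × LC50; LC80 × LC15 — the cells admissible
  under the 90% expected-mortality ceiling.
* 3 replicate leaves × 23–24 nymphs per treatment (at least 70 per
  treatment), 3 replicate bioassays.
* Background mortality 2.7%, 14.3% and 3.3% in the three bioassays —
  values at the span observed in practice, deliberately heterogeneous so
  the pooling machinery has something to decide.
* Realised fungal doses are lognormal around the LC-target with CV 0.15
  (published deposition tables show SDs roughly 5–20% of means); chemical
  doses are exact, mirroring the pipeline's dose semantics. Coverslip
  deposition triplicates are drawn around the same realised means, so the
  calibration table and the dose column tell one consistent story.
* Terminal deaths are binomial with probability given by the truth
  surface; time-course deaths are individual draws from the
  four-parameter law binned onto 48-h censuses (cumulative counts are
  monotone by construction).

What the generator does *not* emulate: spatial structure on the leaf,
between-leaf frailty beyond the dose scatter, instar progression,
cadaver-borne secondary infection, or any correlation between terminal
and time-course noise. Passing recovery tests on this generator therefore
demonstrates correctness of the estimators under the design's sampling
model, not robustness to biological structure the model does not contain.

## Numerical choices

* Optimisation is multi-start BFGS on transformed parameters (log for
  positive parameters, logit for proportions) with a single Nelder-Mead
  polish from the best start; the starting grid is deterministic, so a
  fit is a pure function of its data.
* The joint unaffected fraction is clamped to
  $[10^{-12}, 1 - 10^{-12}]$ before the logit; when $G = 0$ the reference
  is returned exactly (no round trip through the logit).
* Likelihood-ratio statistics that come out negative because an
  alternative optimiser stalled are clamped at zero with a warning, never
  reported as negative evidence.
* Covariances come from the observed information (inverse numeric
  Hessian, with a pseudo-inverse fallback for near-singular cases); for
  least-squares fits they are scaled by the residual variance.
* Degenerate inputs fail loudly with typed errors: all-dead/all-alive
  dose-response data, zero-mortality or time-constant time courses,
  single-level ANOVA factors, saturated designs.

## Validation scale

The package's statistical guarantees are checked by simulation at the
design scale described above: 400 null replicates for the size of the
`NONE`→`SA` likelihood-ratio test, 100 replicates for dose-ratio
parameter recovery and selection (truth $a = -2$, $b = 6$ over three
pooled bioassays), and 200 replicates each for LT50 interval coverage and
for retention/rejection of the shared-LT50 constraint (equal LT50s vs a
5 d vs 15 d split). These sizes give Monte-Carlo standard errors of about
one to four percentage points on the reported rates. The dose-ratio
selection probability at this effect size sits close to its acceptance
bound (around 0.8); the realised rate is reported by the test rather than
smoothed over.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 42, deviation = list(kind = "DR", a = -2, b = 6))
sim <- generate_bioassay(cfg)
report <- run_pipeline(sim$observations, kinds = c("SA", "DR", "DL"),
                       time_course = generate_time_course(cfg))
print(report)
```

The report prints the ANOVA and pooling tables, the nested
model-comparison chain per pooled set, the selected surface with its
parameters and $R^2$, the interaction map with any dose-ratio switch
point, and the LT50 table with the shared-LT50 test.

## Known limitations

* Two agents only; no concentration-addition reference (the
  independent-action reference is the one this design targets).
* One background-mortality parameter per fitted surface: pooled bioassays
  share an $m_0$ even when their control mortalities differ, which is a
  mild misspecification exactly when the pooling decision is borderline.
* The shared-LT50 joint refit optimises up to $3K + 1$ parameters for
  $K$ treatments; for very many treatments a profiled approach would be
  preferable.
* LT50 extrapolation beyond the horizon relies entirely on the parametric
  tail and should be read as such.
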