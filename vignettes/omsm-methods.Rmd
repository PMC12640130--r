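---
title: "The organic matter supply model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The organic matter supply model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Compound-specific nitrogen isotope analysis of amino acids (AA-CSIA) is a
powerful tool for tracing organic matter through planktonic food webs.
"Source" amino acids such as phenylalanine and lysine change little with
trophic transfer and preserve the isotopic baseline, while "trophic" amino
acids such as glutamic acid, alanine, and proline become enriched in
^15^N with each transfer. In the mesopelagic ocean, a zooplankton consumer
may draw on several basal pools of particulate organic matter — fresh
surface particles, large sinking particles, small suspended particles —
and may be separated from them by an unknown number of trophic steps, some
through heterotrophic protists and some through metazoans. The two step
types fractionate amino-acid nitrogen differently, so the amount of trophic
discrimination a tracer accumulates depends on *which* supply pathway is
used — which is exactly the unknown the mixing model is trying to estimate.
Mixing and trophic discrimination therefore have to be solved
simultaneously, which is what this package does.

## The model

For tracer $j$ (an amino-acid $\delta^{15}$N value, per mil), source group
$i$, and consumer sample $k$, the model is the following hierarchy.

**Sources.** Replicate source measurements are normal,
$X_{j,i,r} \sim N(\mu_{j,i}, \sigma_{j,i})$, with vague priors:
$\mu_{j,i} \sim U(-100, 100)$ per mil, and a gamma(0.001, 0.001) prior on
the dispersion. The gamma prior is placed on the *precision*
$1/\sigma^2_{j,i}$, the conventional BUGS encoding of that phrase; a flag
(`sigma_prior = "sd"`) selects the literal reading instead. Because
$\mu_{j,i}$ and $\sigma_{j,i}$ are sampled, within-source natural
variability propagates into every downstream quantity without explicit
error formulas.

**Mixing.** Each consumer has mixing coefficients
$f_k \sim \mathrm{Dirichlet}(\alpha)$ (uniform, $\alpha = 1$, by default),
and the base of its food web mixes linearly in delta space:
$\mu_{j,k,\mathrm{base}} = \sum_i f_{i,k}\,\mu_{j,i}$. Linear
$\delta$-mixing is an approximation — there is no concentration weighting.

**Trophic structure.** Two designated trophic tracers, disjoint from the
mixing set, estimate the food-web geometry. A *constant-discrimination*
tracer (default Pro, $\Delta^{15}$N $= 5.8 \pm 1.7$ per mil per step) gives
total food-web length
$\mu_{\mathrm{FWL},k} = (Y_{j,k} - \mu_{j,k,\mathrm{base}})/\Delta$, and a
*variable-discrimination* tracer (default Glx, metazoan
$\Delta = 8 \pm 1.7$) gives metazoan steps the same way. FWL$_k$ and
MTS$_k$ are sampled from normals centred on these plug-in values with
standard deviations from relative-error propagation,
$$\sigma = |\mu| \sqrt{(\alpha_{j,k}/Y_{j,k})^2 +
(\sigma_\Delta/\Delta)^2},$$
and protozoan steps are always the difference,
$\mathrm{PTS}_k = \mathrm{FWL}_k - \mathrm{MTS}_k$ — PTS is never an
independent parameter. The relative-error form is implemented exactly as
written: its first term divides by the consumer's *absolute* tracer value
rather than by the enrichment $Y - \mu_\mathrm{base}$, so the propagated
uncertainty depends on the isotopic reference scale. The package does not
second-guess this; the Monte-Carlo oracle in the test suite quantifies the
divergence, and a warning is raised when a trophic tracer value sits within
1 per mil of zero, where the formula degenerates.

**Mixing-tracer likelihood.** Each mixing tracer follows its
discrimination class: *conservative* tracers pass the base value through
unchanged; *constant* tracers add $\mathrm{FWL}_k \cdot \Delta$;
*variable* tracers add
$\mathrm{PTS}_k \Delta_\mathrm{proto} + \mathrm{MTS}_k \Delta_\mathrm{meta}$.
Observed values are normal around these predictions with SDs combining
analytical uncertainty $\alpha_{j,k}$ and TDF uncertainty in quadrature
(e.g. $\sqrt{\alpha^2 + (\mathrm{PTS}\,\sigma_\mathrm{proto})^2 +
(\mathrm{MTS}\,\sigma_\mathrm{meta})^2}$ for the variable class). Note
that the constant-class and variable-class quadratures do not coincide
even with equal SDs: splitting FWL into PTS + MTS inside the quadrature
gives a strictly smaller total, and the test suite pins this down so the
two forms are never silently "simplified" into each other.

All consumers are fit jointly in a single graph and share the source
parameters; each gets its own $f_k$, FWL$_k$, and MTS$_k$.

## The TDF registry

The packaged registry (`tdf_default()`) carries per-amino-acid
discrimination factors from controlled feeding studies of aquatic,
ammonia-excreting consumers, with pooled values for constant-class tracers
(Ala $6.3 \pm 2.6$, Pro $5.8 \pm 1.7$, Gly $2.9 \pm 3.1$, Ser
$2.6 \pm 3.2$, Phe $0.3 \pm 0.5$, Lys $1.2 \pm 1.2$ per mil) and separate
metazoan/protozoan values for variable-class tracers (Glx $8 \pm 1.7$ /
$0.5 \pm 1.0$, Asx $5.7 \pm 1.9$ / $0.8 \pm 1.4$, Leu $5.6 \pm 2.4$ /
$1.4 \pm 0.6$, Thr $-5.9 \pm 1.5$ / $-2 \pm 0.6$). The metazoan Thr value
is the regression-based estimate, which agrees with the feeding-study mean
but carries less uncertainty. Ile and Val are present in the registry
(pooled values) but excluded from the default configuration: their
protozoa-versus-metazoa differences are only marginal (p between 0.05 and
0.1) and their fractionation is poorly constrained. Phenylalanine is
treated as conservative by default — its empirical TDF is small enough
that, in short food webs, fixing it at zero buys precision at negligible
cost in bias; `treat_phe_conservative = FALSE` restores the empirical
value. The `tdf_estimation` functions (`aggregate_tdfs()`,
`compare_groups()`, `classify_tracer()`, `regression_tdf()`) reproduce
this derivation pipeline from a feeding-study compilation and field data,
so the registry can be rebuilt or extended from new compilations.

## Sampling and summaries

The posterior is explored with Gibbs sampling through JAGS (via
\pkg{rjags}); this mirrors the BUGS lineage of the model and its
adaptation / burn-in / sampling protocol directly. Defaults: three chains,
5,000 adaptation steps, 10,000 burn-in, 10,000 sampling steps thinned by
10 (3,000 retained draws). All chain RNGs are seeded from one integer, so
runs are bit-reproducible. The sampler is not trusted blindly: a
hand-written `log_posterior()` implements the same joint density
independently, and the test suite checks the MCMC posterior against a
dense-grid numerical integration on a low-dimensional toy, against
closed-form conjugate behaviour on a source-only model, and against the
Dirichlet prior in a prior-only run. Convergence is flagged per parameter
with split-$\hat R$ (< 1.05) and effective sample size (> 200); failures
produce a warning and travel with the draws into the summaries — they are
reported, never silently ignored.

Two numerical guards matter. First, the trophic-step SD can reach zero
when a plug-in mean crosses zero (the relative-error form multiplies by
$|\mu|$); inside the sampler the SD is floored at $10^{-6}$ per mil so the
precision stays finite. `log_posterior()` applies the same floor; the pure
`trophic_uncertainty()` function implements the formula with no floor.
Second, initial values are deterministic — $f$ at the simplex centroid,
FWL/MTS at their plug-in estimates from empirical source means, source
parameters at group sample statistics — which speeds convergence without
affecting the stationary distribution.

Posteriors are summarised by the mean, the kernel-density mode (Gaussian
KDE, Silverman bandwidth, 512-point grid; mixing fractions are estimated
on the logit scale and back-transformed to avoid boundary bias), and 50,
75, 90, and 95% highest density intervals. The HDI is the shortest
contiguous window of sorted draws containing the requested mass, pooled
across chains; plateaus are tie-broken deterministically toward the lowest
window. Hypothesis tests use `hdi_excludes()` with a closed-interval
convention: a null value sitting exactly on an endpoint is not excluded.
Multimodal (union-of-intervals) HDIs are not supported.

## The simulator and what passing tests mean

`simulate_sources()` draws replicate source measurements around fixed
group means with a common within-group SD (default 1 per mil, 3 groups ×
5 replicates). The default geometry mimics open-ocean particle pools:
surface particles lowest and small particles highest on Phe/Lys and the
trophic tracers (the first axis of separation), with Thr as the orthogonal
axis on which large particles are uniquely low. Group separations are
several per mil — at least three within-group SDs on some axis for every
pair. `simulate_consumers()` then draws, per sample, mixing fractions from
a uniform Dirichlet, protozoan steps from $U(0, 1)$, and metazoan steps
from $U(1, 2)$ (food-web lengths between 1 and 3), and computes tracer
values through the forward model from the empirical source means and the
mean TDFs. Generation is deterministic by default (`noise_sd = 0`); the
analytical SD supplied for fitting defaults to 0.5 per mil, a typical
AA-CSIA measurement uncertainty.

The simulator emulates group-mean structure and within-group scatter only.
It does not emulate depth or seasonal structure within source pools,
non-normal or correlated within-group variation, TDF values that differ
from the registry means, or analytical error in the generated consumer
values. Passing recovery tests therefore demonstrate internal consistency
— the sampler recovers parameters from data generated by the model's own
forward equations under realistic geometry — not field accuracy, which is
bounded by how well the registry TDFs and source sampling represent a real
system.

At the validation scale used in the tests (3 sources, 20 consumers,
quarter-length chains) the 95% HDIs cover the true mixing fractions and
trophic parameters in well over 85% and 90% of cases respectively, and the
acceptance script (`scripts/acceptance.R`) re-runs the full-size study (50
consumers, default chain lengths, about a minute of compute) and writes
the recovered coverage and discrepancy statistics as JSON. These problem
sizes were chosen to characterise the estimator while keeping a full run
comfortably interactive.

## Design decisions

* **Backend.** The sampler is JAGS through \pkg{rjags} rather than a
  hand-rolled kernel: the model is a BUGS-style graph, JAGS is its native
  habitat, and independence is preserved by validating against
  grid-integration and closed-form oracles that share no code with the
  sampler.
* **No truncation by default.** FWL and MTS are untruncated normals;
  nothing in the model's formulation demands positivity, and negative
  tails are informative about uncertainty. `truncate_trophic = TRUE`
  truncates both at zero for users who want the constraint.
* **Non-fractionating variant.** `nonfractionating = TRUE` reproduces the
  simplified model used by earlier source-amino-acid studies: Thr is
  dropped, Phe and Lys are treated as conservative, and no trophic
  parameters are estimated. It exists mainly for comparison; the full
  model estimates the large-particle fraction substantially better.
* **Wide CSV layout** (one column per amino acid) matches how AA-CSIA
  data are deposited; amino-acid aliases (`Glu` → `Glx`, `Asp` → `Asx`,
  case-insensitive, full names accepted) are canonicalised at the door.
* **Experiments are the unit of TDF averaging**; compilation filters
  (aquatic ammonia-excreters, trophic position ≤ 3, one anomalous
  vegetable-meal experiment dropped) are declarative, logged rules rather
  than hard-coded row deletions.
* **Regression-TDF uncertainty** is first-order quadrature:
  $\sigma^2 = (se_m \cdot \mathrm{TDF}_\mathrm{ref})^2 +
  (m\,\sigma_\mathrm{ref})^2 + \sigma_\mathrm{Phe}^2$. This treats the
  slope, the reference TDF, and the Phe TDF as independent error sources.

## Known limitations

* Mixing is linear in delta values; concentration-weighted mixing is out
  of scope.
* Single-interval HDIs only; heavily multimodal posteriors (e.g. from
  nearly collinear sources) will be summarised coarsely.
* The protozoan TDF values rest on very few controlled feeding studies;
  uncertainty in `sd_proto` is honest but the means themselves are weakly
  constrained.
* Only nitrogen tracers are supported; carbon isotopes of essential amino
  acids would slot in as conservative tracers but are not implemented.
* The relative-error trophic-uncertainty formula is reference-scale
  dependent near 0 per mil (warned, not corrected).
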