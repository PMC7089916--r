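---
title: "Predictability of association patterns from scan samples: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictability of association patterns from scan samples: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scansoc)
```

## The problem

In species that travel as one large group but whose members cannot all see
each other — terrestrial monkeys in forest, for instance — the "subgroup" is
whoever is in visual contact with a focal individual at a scan. Interactions
happen in front of these ad-hoc audiences, and how predictable the audience
is constrains the kind of social knowledge that pays off. `scansoc`
quantifies that predictability at two levels: the entropy of whole subgroup
compositions against a permutation null, and dyad-level association
preferences explained by individual attributes.

The expected input is one season of scan samples (a 0/1 presence matrix over
a fixed roster, one row per scan, with the focal recorded), an attribute
table (sex, age class, mother identity, infant-of-the-year flag), and
optionally dated supplant interactions for dominance ranks. Only individuals
present the whole season and old enough to move independently (over 3 years;
adult at over 5 for females, over 7 for males) enter the analysis
(`filter_season()`, `assign_age_class()`).

## The constrained permutation null

Scan data from focal follows are not exchangeable rows: subgroup sizes vary,
the focal is present in its own subgroup by construction, individuals differ
in gregariousness, and consecutive scans within a follow are strongly
autocorrelated. `permute_dataset()` therefore randomizes membership while
preserving all four structures:

* per-scan subgroup size is kept;
* the focal is kept and is always a member;
* the remaining `size − 1` members are drawn from the roster minus the focal
  by weighted sampling without replacement, weights proportional to each
  individual's observed occurrence frequency;
* maximal runs of identical consecutive scans (same composition *and* same
  focal) receive one draw copied across the run, so scans that are identical
  in the observed data are identical in the randomized data.

Design notes, decided where the procedure leaves room:

* *Runs require an identical focal.* A composition repeated across a focal
  change is two runs: autocorrelation arises within follows, not across
  them.
* *Weights are raw occurrence frequencies*, not renormalized to exclude the
  focal's own contribution — the simplest reading of "occurrence likelihood
  in the observed data". (The alternative was considered; at the data
  densities involved the two differ negligibly, and the chosen convention is
  the one the validator audits.)
* *Weighted sampling without replacement* is successive draws with
  renormalization (base R `sample(prob = )`), exact for the stated contract.
* *Reproducibility*: per-realization seeds derive from the master seed by a
  counter scheme, so an ensemble is bit-reproducible.
* The run constraint is directional, as stated: observed-identical scans stay
  identical. Two *adjacent distinct* runs can, with small probability, draw
  the same composition and merge in a maximal-run recomputation; the audit
  (`validate_ensemble()`) therefore checks constancy within observed runs,
  sizes, and focal membership, which is exactly the stated constraint set.

One property worth knowing: sequential weighted sampling does not reproduce
the weights as inclusion probabilities exactly — occupancy is slightly
flattened toward uniform, increasingly so as subgroup size approaches group
size. See "limits of the entropy ratio" below.

## Entropy measures

`shannon_entropy()` uses base 2 (bits) by default. The bits bound
`H ≤ log2(n_scans)` is the consistency check: seasons of ~4600 scans with
observed entropies of ~11.8 bits respect `log2(4615) = 12.17`, which a
natural-log reading would not. The base is configurable but every reported
number is in bits.

`expected_entropy()` is the *mean of per-realization entropies*, not the
entropy of the pooled distribution (the procedure's description reads most
naturally as one entropy per permutation; pooling would also inflate the
expectation by mixing B supports). The pooled distribution over all
realizations is used only where a single reference distribution is required:
KL divergence and JS distance in `entropy_report()`.

Numerical conventions: `0 · log 0 = 0`; the observed/expected ratio is 1 by
convention when both entropies are 0 and an error when only the expectation
is 0; KL against the pooled null smooths the reference at
`epsilon = 1 / (B · n_scans)` (one pooled pseudo-count, configurable),
because compositions observed but never permuted otherwise give infinite KL;
JS needs no smoothing (the mixture covers both supports).

### Limits of the entropy ratio

`bias_experiment()` regenerates the methodological calibration: on a grid of
group sizes and scan counts under fully random association, KL and JS move
strongly with both group size and data density (they track support-size
saturation), while the observed/expected ratio stays flat to well under 1% —
the ratio is the measure that travels across datasets.

Two deliberate choices there. First, the experiment's generator default is
`gregariousness_sd = 0`: it isolates group size and data density under
random association. Second, the reason this matters is itself a finding:
with heterogeneous gregariousness *and* subgroups spanning more than about
half of a small group (e.g. mean subgroup 6 in a group of 10), the weighted
null's occupancy flattening biases the expected entropy upward and the ratio
genuinely drops below 1 (we measured ~0.975 at group size 10, 2000 scans).
At the group sizes this method targets (≈ 20+ individuals, subgroups well
below half the group) the effect is negligible — the null calibration at
group size 30 stays within 1.000 ± 0.005 with heterogeneous gregariousness.
A ratio below 1 in a small, dense group is therefore not necessarily dyadic
structure; it can be gregariousness heterogeneity interacting with the null.

## Dyadic association

The simple ratio index is computed as
`SRI = n_together / (n_a_only + n_b_only + n_together)`. The formula is
often printed as `P_AB / (P_A + P_B + P_AB)`; read literally with `P_A`
*including* joint sightings the index could never reach 1, contradicting its
stated range, so the lone-count reading (the standard simple-ratio
definition) is the default and the literal one is available as
`sri(..., literal = TRUE)` for comparison. A dyad never seen at all has
SRI 0 by convention.

The pairwise affinity value is `PAV = SRI_obs − SRI_exp`. (The source
procedure describes "subtracting the observed from the predicted" yet
interprets positive values as more-than-expected association; the
interpretation fixes the sign, and obs − exp is what is implemented.)

Significance is a strict one-sided permutation test: `p_rank` counts
permutations with permuted SRI *strictly below* the observed value, and the
flag requires `p_rank > (1 − alpha) · B` — for B = 1000 and alpha = 0.05 the
observed SRI must beat at least 951 permutations. Ties count against
significance (conservative).

`bootstrap_scans()` resamples scans with replacement and reports each dyad's
SRI standard deviation; small values (the reference seasons gave a maximum
of 0.01) indicate the number of scans pins down the association indices.

## Dominance ranks

Ranks come from standard sequential Elo updating on supplant records
(`elo_ratings()`: winner gains `k · (1 − p_expected)`, logistic expectation
on the base-10/400 scale, default `k = 100`, initial 1000; total rating is
conserved). The likelihood-optimized Elo variant used in some field studies
is deliberately not implemented: ranks enter the models only through *daily
ordinal standardization* (`standardized_ordinal_rank()`: top rank 1, bottom
0, ties share the mean position, a lone individual is 1), which discards
cardinal detail, so the simplification is benign. Season ranks are plain
means of daily values (`yearly_rank()`).

## Assortativity models

`build_dyad_rows()` produces one row per dyad per season with: binary
kinship (mother–offspring or maternal siblings), sex combination
(reference `female_female`), age combination (reference `adult_adult`),
newborn-infant combination (reference `no_no`), and the absolute difference
of season ranks. The rank difference is z-standardized across the pooled
table for fitting (raw values are retained in `rank_diff_raw`).

The full model is kinship + rank difference + sex, age, infant combinations
+ sex×rank + sex×age. `enumerate_submodels()` generates every subset that
respects marginality (an interaction only with both parents) — 52 models —
and `multimodel_inference()` ranks them by AICc
(`−2logLik + 2k + 2k(k+1)/(n−k−1)`, `n` = dyad-year rows), computes Akaike
weights, the 95% best-model confidence set, and per-predictor summed
weights. Predictor weights are only interpreted when the intercept-only
model is outside the confidence set; the result carries that flag. The
"expected weight assuming all models perform equally well" is defined here
as the fraction of models containing the predictor; published tables built
with other software report different expected weights for the same model
set, so the definition evidently varies — ours is documented and pluggable
rather than silently matched.

**Random effects and the fallback.** The stated mixed structure is random
intercepts for both individuals, the dyad, and the year, plus random slopes
for rank difference in the individual identities and year; `fit_model(...,
random_effects = TRUE)` fits exactly that via lme4, identically across all
submodels. The default for the resampling-heavy machinery is the documented
fixed-effects-only fallback (`glm`/`lm`): the synthetic generator produces
data with zero random-effect variance, resampling multiplies the fit count
by 52 × selections, and non-convergence bookkeeping (non-convergent fits are
dropped from weight normalization with a logged count, never imputed) is far
better behaved. The mixed route is exercised in the tests once at small n.

**Dyad-flip resampling.** Which member of a dyad is "individual 1" is
arbitrary but matters once per-individual random effects exist.
`dyad_flip_inference()` repeats the whole inference under random member
labellings (reference analysis: 1000 selections) and reports mean estimates
and mean summed weights. Whether the original procedure re-ran the full
all-subsets inference per selection or only refit the full model is
ambiguous; both are implemented (`refit_subsets`), defaulting to the full
re-run. With the fixed-effects fallback the flip is a no-op by construction
— the tests assert exactly that.

Diagnostics: `vif()` implements the generalized VIF (determinant formula) on
the fixed-effects design without interactions, since that is what the
published check used; `r2_mixed()` is the Nakagawa decomposition with
distribution-specific residual variance `π²/3` for binomial-logit models and
random-slope contributions approximated by slope variance × covariate
variance; `influence_check()` refits with each year/individual left out and
reports maximal estimate shifts.

## The synthetic generator

The source study is empirical and specifies no generative model; the
generator is a package artifact whose *defaults are the study's stated
world*: 30 individuals (observed rosters 28–40), 65% female (observed female
proportions 0.53–0.86), ~5000 scans per season (observed 4615–6601), focal
follows of 4 scans (1-h follows, 15-min scans), subgroup sizes
`1 + NegBinom(mu = 5, size = 8)` truncated at 17 — hitting the observed mean
6 and maximum 17 at season scale — and, where the study states nothing,
one-time realistic choices: autocorrelation probability 0.3 (consecutive
scans do repeat, rate unreported), gregariousness SD 0.5 on the log-weight
scale (clear but not extreme heterogeneity), 8 matrilines, 25% subadults,
40% of adult females with newborns. All affinity effects default to zero, so
the default world is a null world; structure is injected explicitly
(`affinity_effects`) and the full ground truth (affinity matrix,
gregariousness, ranks) is exported alongside every dataset so recovery tests
never re-derive it.

Membership is built per scan by sequential conditional sampling: weight
`∝ exp(gregariousness + mean affinity to already-selected members)`. That
keeps generation O(n·s) per scan and makes early picks non-dominant; it does
*not* define a proper joint distribution over subgroups, and none is
claimed. What a green calibration test establishes is therefore: on data
with this focal-follow structure, autocorrelation, size distribution, and
(for criterion-2-style checks) gregariousness heterogeneity, the pipeline's
type-I rate and entropy ratio are nominal. What it cannot establish:
behaviour under demographic turnover within a season, observer error,
spatially driven association, or non-stationary gregariousness — none of
which the generator emulates.

## Pipeline and determinism

`run_pipeline()` executes scan data → permutation ensemble → entropy report
→ bootstrap → dyad table → assortativity, stamps every artifact with a
config hash and the master seed, and aborts on the first stage error naming
the stage. Configs are R lists or JSON files (this environment provides no
YAML parser for R; JSON is the config format). Identical config + seed gives
byte-identical CSV/JSON outputs. `pipeline_report()` renders the bundle as
deterministic markdown. The exported functions are the interface; the
acceptance script under `scripts/` is a thin wrapper over them.

## Known limitations

* The entropy ratio is trustworthy at the target group sizes but biased
  below 1 for small, dense groups with heterogeneous gregariousness (see
  above) — a property of weighted permutation nulls generally, made explicit
  here.
* KL/JS smoothing (`epsilon`) is a choice; published analyses do not state
  how never-permuted observed compositions were handled.
* Elo here is the standard sequential variant; analyses calibrated to the
  likelihood-optimized variant may rank border-line individuals differently
  on sparse supplant data.
* The expected-Akaike-weight definition varies across software; compare
  summed weights to *this* package's expected weights, not across tools.
* With the fixed-effects fallback, dyad-flip resampling is a no-op and its
  variance across selections is zero by construction; variance appears only
  with `random_effects = TRUE`.
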