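---
title: "From bedside screening to game levels: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From bedside screening to game levels: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chclevels)
```

## The problem

Early after an acquired brain injury, full neuropsychological batteries are
often impossible to administer, yet cognitive rehabilitation should begin as
soon as possible. A bedside screen such as the Addenbrooke's Cognitive
Examination Revised (ACE-R) is feasible: it yields five subscores
(attention & orientation, memory, verbal fluency, language, visuospatial
function, 100 points in total). Rehabilitation training games, however, are
organised around the nine broad domains of the Cattell-Horn-Carroll (CHC)
model of cognitive abilities — GC, GF, GRW, GQ, GSM, GLR, GV, GS, GA — each
with six difficulty levels. `chclevels` implements the bridge: an expert
weighted-transfer calculation from ACE-R subscores to CHC *saturations*
(normalised performance values), segmentation of each saturation into a
starting game level, two machine-learning surrogates of that calculation,
and the statistical harness used to compare any predictor against expert
level assignments.

## The expert conversion

Raw subscores are normalised by their subscale maxima (defaults 18 / 26 /
14 / 26 / 16; configurable via `acer_schema()`) to a profile
$x \in [0,1]^5$. A $5 \times 9$ transfer matrix $w$ of percentages — each
row distributing one ACE-R domain's contribution over CHC domains, each row
summing to 100 — defines the saturation of CHC domain $c$ as the
column-normalised weighted mean

$$ s_c = \frac{\sum_d w_{dc}\, x_d}{\sum_d w_{dc}}. $$

This form guarantees $s_c \in [0,1]$, maps the perfect profile to full
saturation and the zero profile to zero, and is monotone nondecreasing in
every subscore, so a better screen never yields a harder recommendation in
the wrong direction. A matrix with an all-zero column is rejected at load
time (the saturation would be undefined) rather than silently reported as 0.

Two caveats about the shipped default matrix. First, its *row multisets*
(28/28/28/16, 15/39/46, 25/25/50, 61/8/31, 12/12/13/63) are fixed by the
published factor analysis, but the attachment of each row percentage to a
specific CHC column is not unambiguous in the published rendering; the
default assignment follows column order and semantic plausibility, is
explicitly marked as a configuration choice, and can be replaced wholesale
with `read_transfer_matrix()`. All shipped tests rely only on
assignment-invariant row facts (row sums, row maxima). Second, whether the
upstream calculation normalises by column sums (as here) or uses raw
weighted sums is not documented; the column-normalised mean was chosen
because it makes the saturation a genuine [0,1] performance value and lets
levels span the full 1–6 range.

Saturations become game levels by splitting the unit interval into six
equal segments: level $= 1 + \lfloor 6v \rfloor$, capped at 6. Segments are
half-open with the top segment closed, so a value exactly on a boundary
takes the higher level; the map is deterministic, monotone, and surjective
onto $\{1,\dots,6\}$.

## The neural-network surrogate

The surrogate is a fully connected 5-7-9 multilayer perceptron with
logistic activations (steepness 1). The hidden size follows the
geometric-mean rule $N_h = \sqrt{N_i N_o} = \sqrt{45} \approx 7$. Training
material is machine-generated: 1000 input vectors drawn uniformly on
$[0,1]^5$, each labelled with the expert conversion's saturations
(`mlp_training_set()`), so the network is a smooth surrogate of the
transfer calculation, learned rather than coded.

Training is classic online backpropagation on the quadratic loss

$$ L(w, b) = \frac{1}{2n} \sum_x \lVert y(x) - a(x) \rVert^2, $$

with weights updated after every pattern and the pattern order reshuffled
each cycle (epoch). The learning rate follows a staged schedule — 1.0 for
cycles 1–1000, 0.5 for 1001–2000, 0.1 beyond — so adaptation first finds
the solution region coarsely and then refines it. Weights and biases are
initialised uniformly on $[-0.5, 0.5]$ under the run seed; a fixed seed
gives a bit-identical trajectory.

Three numerical choices deserve comment:

* **Stopping rule.** Training stops at the first cycle whose *total error*
  $E$ — the Euclidean norm of the nine-dimensional output-error vector,
  averaged over the training set — falls to 0.07 or below. On unit-scaled
  outputs this corresponds to a root-mean-square error of roughly 0.02 per
  CHC domain, i.e. near-perfect learning of the whole set. Stopping on the
  quadratic loss itself at the same numeric threshold would halt after a
  single cycle with a surrogate too coarse to respect the level
  segmentation (about half of all level recommendations would differ from
  the expert conversion); the error-norm form is the reading under which
  the threshold, the staged schedule, and the surrogate's fidelity are all
  mutually consistent. With the defaults the rule is met after roughly
  60–100 cycles and the final quadratic loss is about 0.003.
* **Update regime.** Per-pattern (online) updates are the default; a
  full-batch mode exists mainly so the monotone decrease of the loss under
  small steps can be verified mechanically.
* **Safety rails.** A hard cap of 10,000 cycles prevents an infinite loop
  for unlearnable configurations (reported as `converged = FALSE` with a
  warning, not an error); a non-finite loss aborts with a training error.

Note that the sigmoid steepness and the learning rate are independent
parameters even though both are conventionally written $\alpha$.

After training, `predict(fit, data, type = "level")` composes the forward
pass with the same six-segment rule. On 10,000 fresh uniform profiles the
shipped test suite requires exact level agreement with the expert
conversion of at least 90% per CHC domain and a mean absolute saturation
error of at most 0.05; the trained surrogate typically achieves 90–95%
agreement and a mean absolute error of about 0.02.

## The linguistic fuzzy surrogate

The second predictor is a minimal linguistic fuzzy system in the style of
evaluative-expression rule bases. Each variable lives on a *context*
(here $[0,1]$ with centre 0.5). An evaluative expression is
(modifier)(base term) with base terms *small*, *medium*, *big* and eight
modifiers ordered from narrowing to widening: *extremely*, *significantly*,
*very*, none, *more-or-less*, *roughly*, *quite-roughly*, *very-roughly*.
Memberships are trapezoids: *small* has kernel $[0,\, 0.2f]$ and support
$[0,\, 0.5f]$ where $f$ is the modifier's width factor
(0.4, 0.6, 0.8, 1.0, 1.25, 1.5, 1.75, 2.0); *big* is the mirror image;
*medium* is anchored at the context centre with kernel half-width $0.05$
and support half-width $0.25$, scaled only by narrowing modifiers. These
constants are package defaults, not a claim about any external system's
settings: they were chosen so that (a) narrowing modifiers give pointwise
smaller memberships than the bare term and widening ones larger (the
monotonicity chain), and (b) the defuzzified values of the expression set
tile the six level segments (below).

Rules are learned one per observation — the best-fitting expression (the
membership maximiser, ties to the more specific expression) per input
variable and for the output — then filtered: duplicates collapse, and
identical antecedents with conflicting consequents keep the majority
consequent, ties resolved toward the lower defuzzified value. The tie
policy is clinically conservative: when the evidence is balanced, start the
patient at the easier level. Inference is perception-based logical
deduction: a rule's firing degree is the minimum of its antecedent
memberships (Gödel conjunction); the firing rule is the degree maximiser,
with degree ties (within $10^{-9}$) going to the most specific antecedent.
An observation at which every rule fires at degree zero is outside learned
experience; `predict()` then falls back to the expert conversion for that
domain and says so in a warning.

Defuzzification maps the consequent back to a crisp value at the kernel
endpoint facing the context centre: the kernel supremum for *small*-type
expressions, the infimum for *big*-type, the centre for *medium*. The
defuzzified value therefore grades with the modifier (*extremely small*
$\mapsto 0.08$, *small* $\mapsto 0.2$, *very-roughly small* $\mapsto
0.4$, ...), which is what lets a rule base discriminate six levels. The
frequently cited alternative — the outermost kernel endpoint — collapses
every small-type consequent to 0 and every big-type to 1, leaving a
three-valued predictor; it was rejected on those grounds. With the shipped
constants, `dee_defuzzify(best_expression(v))` stays within 0.15 of $v$
across the unit interval (the granularity of a 24-expression set), and a
rule base learned from the expert conversion on a diagonal grid reproduces
the conversion's levels on at least 85% of the grid.

The optional sign component of evaluative expressions is not implemented:
all package variables are nonnegative scores. Rule bases serialise to
plain text, one `IF ... THEN ...` line per rule, and round-trip exactly.

## The evaluation harness

`compare_levels(expert, predicted)` reproduces the comparison methodology
used to validate the predictors:

* a **signed level-error table** per CHC domain: counts of predictions at
  or below the expert level versus above it, with the positive-error
  percentage. The sign convention is clinical: a prediction *above* the
  expert level is the harmful direction, because the patient may start a
  game beyond their capability;
* a **statistical screen** per domain: expert and predicted mean levels
  and both a one-way fixed-effects ANOVA and a Kruskal-Wallis rank test on
  the two level sets, flagged at the 5% level; a domain is `REJECT`ed when
  either test is significant. Treating expert and predicted levels as two
  independent groups mirrors the printed methodology, even though a paired
  design would also be defensible for these data; the harness follows the
  table layout it emulates.
* a **Bonferroni all-pairwise comparison** (`bonferroni_pairwise()`) for
  comparing per-domain error distributions across the nine CHC factors:
  pair $(i,j)$ differs when $|\bar y_i - \bar y_j| / \sqrt{\mathrm{MSE}
  (1/n_i + 1/n_j)}$ exceeds the two-sided critical value at familywise
  level $\alpha$ over $k(k-1)/2$ pairs. The critical value uses the
  Student-$t$ quantile for error df up to 120 and the limiting
  standard-normal quantile beyond — the convention of classical Bonferroni
  tables and of the legacy multiple-comparison reports this output is
  formatted after (at df 6318 and $\alpha = 0.05$ over 9 groups this gives
  3.1970).

Degenerate inputs have defined results rather than NaNs: identical values
across all groups give $F = 0, p = 1$ and $H = 0, p = 1$, and a zero
mean-square error flags every unequal-mean pair with a warning. The
Kruskal-Wallis p-value is the chi-square approximation with $k - 1$
degrees of freedom (with tie correction); against the exhaustive
permutation distribution on tiny balanced designs it agrees to a few
thousandths in the decision-relevant tail ($p \lesssim 0.05$), which is
where the 5% verdicts are made, and to within a few hundredths elsewhere.

Report files mirror the published formats: positive-error percentages with
two decimals (`1.42%`), p-values with five.

## The synthetic cohort

The reference study population (703 patients; 351 men and 352 women; ages
19–97; education 126 primary / 182 vocational / 254 secondary / 141
university) is not publicly available, so `simulate_cohort()` generates
cohorts with exactly that demographic structure. ACE-R subscores come from
a one-latent-factor severity model: patient severity $u \sim
\mathrm{Uniform}(0,1)$, each normalised subscore $= \mathrm{clip}(u +
\varepsilon, 0, 1)$ with $\varepsilon \sim N(0, 0.1^2)$. This is the
simplest structure that makes the five subscores positively correlated —
as cognitive subscores are — and spreads CHC saturations over all six
levels. Raw scores are the normalised values scaled to the schema maxima
and rounded to whole points, as ACE-R is scored in integer points.

Expert labels are the conversion's levels with optional symmetric
disagreement noise: with probability `label_noise` (default 0.05) a label
shifts one level up or down, clipped to 1–6. One-level symmetric noise
reflects the granularity at which clinicians and the calculation actually
disagree; the default rate is of the order of the positive-error
percentages observed in practice. Setting `label_noise = 0` recovers the
conversion exactly — the two limits bracket the unknowable question of
whether real expert levels were computed or independently judged.

What the generator does *not* emulate: diagnosis-specific score profiles
(stroke versus dementia produce different subscore shapes, not just
severities), age or education effects on scores, and any dependence
structure beyond the single factor. Tests passing on synthetic cohorts
therefore validate the pipeline's mechanics and statistics, not clinical
performance on real patients.

## Problem sizes and reproducibility

The shipped tests train the surrogate on 1000 generated vectors (the
protocol's sample size) and probe it on 10,000 fresh ones; the fuzzy
self-consistency experiment uses a 101-point diagonal grid; statistical
identities are checked on small randomised designs under fixed seeds; the
cohort tests use the full default 703 patients. A single global seed fans
out to per-stage derived seeds (stable hash of the stage name), so
`simulate` / `train` / `predict` / `evaluate` runs are individually and
jointly reproducible; the command-line pipeline produces byte-identical
outputs under a fixed seed.

## Known limitations

* The Table-column attachment of the default transfer matrix is a declared
  configuration, not ground truth; analyses that depend on *which* CHC
  column a weight occupies should supply their own matrix file.
* The fuzzy engine implements exactly the evaluative-expression subset
  needed here: no sign component, no rule chaining, no fuzzy arithmetic,
  and membership constants that are package defaults rather than a
  reproduction of any particular historical tool.
* The harness's independent-groups ANOVA ignores the pairing of expert and
  predicted levels within patient; it reproduces the printed methodology
  rather than the most powerful design.
* The surrogate's fidelity guarantees are with respect to the expert
  conversion on uniform profiles, not with respect to clinicians.
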