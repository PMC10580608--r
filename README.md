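# chclevels

Cognitive rehabilitation games are organised around the nine broad domains
of the Cattell–Horn–Carroll (CHC) model of intelligence — crystallized
intelligence (GC), fluid intelligence (GF), reading/writing (GRW),
quantitative reasoning (GQ), short-term memory (GSM), long-term storage and
retrieval (GLR), visual processing (GV), processing speed (GS), auditory
processing (GA) — each offered at six difficulty levels. Early after a brain
injury, though, the only feasible assessment is usually a bedside screen
such as the Addenbrooke's Cognitive Examination Revised (ACE-R), which
yields five subscores (attention & orientation, memory, fluency, language,
visuospatial). `chclevels` is for clinicians and methodologists building or
auditing automated rehabilitation planning: it converts an ACE-R profile
into CHC domain saturations and a starting game level per domain, trains
machine surrogates of that conversion, and evaluates any level predictor
against expert assignments.

The core calculation: normalised subscores $x \in [0,1]^5$ pass through a
5×9 expert transfer matrix $w$ (percentages, each row summing to 100) as a
column-normalised weighted mean

$$ s_c = \frac{\sum_d w_{dc}\,x_d}{\sum_d w_{dc}}, \qquad
   \text{level}_c = 1 + \lfloor 6\,s_c \rfloor \ (\text{capped at } 6). $$

Around it the package provides:

* **`recommend_levels()`** — the deterministic expert conversion (the
  reference every other predictor is measured against);
* **`mlp_train()` / `predict()`** — a 5-7-9 multilayer perceptron trained by
  online backpropagation with a staged learning rate (1.0 / 0.5 / 0.1) on
  1000 machine-generated profiles labelled by the conversion;
* **`fes_learn()` / `predict()`** — a linguistic fuzzy rule base
  (evaluative expressions, perception-based logical deduction,
  defuzzification of evaluative expressions);
* **`compare_levels()`, `bonferroni_pairwise()`** — signed level-error
  tables, per-domain ANOVA and Kruskal–Wallis screens, and a Bonferroni
  all-pairwise grouping report;
* **`simulate_cohort()`** — synthetic patients with the demographic
  structure of the reference clinic population (703 patients, 351 men,
  ages 19–97, education 126/182/254/141) and correlated subscores from a
  one-latent-factor severity model.

All user-facing functions take a data frame first and return tibbles, so
they chain with the pipe; fitted objects support `tidy()`, `glance()` and
`autoplot()`. A thin command-line wrapper (`exec/chclevels`) exposes the
pipeline as `simulate`, `convert`, `train-nn`, `predict-nn`, `learn-fes`,
`predict-fes`, `evaluate`.

## Worked example

```r
library(chclevels)

patients <- tibble::tribble(
  ~id, ~attention_orientation, ~memory, ~fluency, ~language, ~visuospatial,
  1L, 17L, 24L, 12L, 25L, 15L,   # near-ceiling screen
  2L, 12L, 14L,  6L, 18L,  9L,   # moderate impairment
  3L,  8L,  6L,  3L, 11L,  5L    # severe impairment
)

patients |> acer_normalize() |> recommend_levels()
#> # A tibble: 3 × 15
#>      id attention_orientation memory fluency language visuospatial    gc    gf
#> 1     1                    17     24      12       25           15     6     6
#> 2     2                    12     14       6       18            9     4     3
#> 3     3                     8      6       3       11            5     3     2
#> # i 7 more variables: grw <int>, gq <int>, gsm <int>, glr <int>, gv <int>, ...
```

Patient 1 starts every game near the top level; patient 3 starts GF at
level 2 because their fluency and visuospatial scores (the GF contributors)
are low. The underlying saturations are available via `chc_saturation()`
(patient 3's GC saturation is 0.365, hence level 3).

Training the neural surrogate of the conversion and predicting with it:

```r
fit <- mlp_train(mlp_training_set(1000, seed = 42), seed = 1)
fit
#> <chc_mlp> 5-7-9 network, 91 cycle(s), final loss 0.00281, total error 0.06979 (converged)

predict(fit, acer_normalize(patients), type = "level")
# identical levels to the expert conversion for these three patients
```

The final quadratic loss 0.00281 corresponds to a per-domain RMS error of
about 0.02 saturation units; the stopping rule (total output error ≤ 0.07)
is reached here after 91 cycles. Evaluating a predictor against expert
labels on a full synthetic cohort:

```r
coh <- simulate_cohort(seed = 1)          # 703 patients, 5% label noise
cmp <- compare_levels(coh, recommend_levels(coh))
cmp$error_table
#> # A tibble: 9 × 5
#>   domain n_le0 n_gt0 total pct_gt0
#> 1 gc       691    12   703    1.71
#> 2 gf       686    17   703    2.42
#> 3 grw      682    21   703    2.99
#> # ...

glance(cmp)
#> # A tibble: 1 × 4
#>       n n_domains n_reject pct_gt0_overall
#> 1   703         9        0             2.1
```

With the default 5% expert-disagreement noise, about 2% of predictions land
above the expert level (the clinically risky direction — the patient might
start a game beyond their capability), and no domain's mean level differs
significantly from the experts' at the 5% level (`n_reject = 0`).

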