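# aoalearn

Accumulator models of word age-of-acquisition (AoA) distributions.

Parent-report vocabulary norms (MCDI-style) report, for each early-learned
word, the proportion of children producing it at each month of age from 16
to 30 months. Read down a word's column, that is an empirical cumulative
AoA distribution over a population of learners. `aoalearn` models it as the
outcome of a stochastic accumulator: a child samples word-relevant events
with cumulative intensity Λ(t) = δ·t^D and acquires the word at the N-th
event, so the acquisition age follows a generalized gamma law

    F(t) = P(N, δ t^D),    E[T] = δ^(-1/D) Γ(N + 1/D) / Γ(N),

with three named learning processes as special cases — **cumulative
learning** (D = 1, gamma AoA), **rate-change learning** (N = 1, Weibull
AoA), **cumulative-and-rate-change learning** (full Weibull-gamma family)
— plus a **logistic** growth-curve alternative. The package is aimed at
developmental psycholinguists and modellers who want to ask *which
learning process best explains a word's AoA distribution* and how the
fitted parameters (accumulation N, change-of-rate D, base rate δ) relate
to word class, age, and psychological attributes.

## What it provides

* **Distribution layer** — `aoa_cdf()`, `aoa_pdf()`, `aoa_hazard()`,
  `aoa_mean()`, `aoa_quantile()`, `classify_hazard_shape()`,
  `rate_for_mean()` for all four families.
* **Simulation** — `draw_acquisition_age()` (event-level simulator),
  `simulate_norms()` (cohort proportions), and `make_mcdi_fixture()`, a
  synthetic MCDI-style population (654 words, 389/102/63/98 words in
  noun/verb/adjective/closed classes + 2 agrammatical items, 1000 children
  per word) with known ground-truth parameters.
* **Fitting** — per-word maximum likelihood for each family
  (`fit_word()`, binomial cross-entropy over months with n = 1000),
  BIC = −2L + k·ln(15) model selection (`select_model()`, `fit_norms()`).
* **Analyses** — `median_aoa()` (first month ≥ 50%, censored → 31),
  `crosstab_selection()` + `chi_square_independence()` (class × model and
  median-AoA × model tables), `correlate_with_attributes()` (Pearson r
  with Fisher 95% CIs against e.g. frequency or imageability),
  `moving_average_trend()` (20-word window over words ranked by fitted
  mean AoA), `estimated_mean_aoa()`.
* **CLI** — `aoa_cli()` with subcommands `simulate | fit | select |
  analyze | demo` (wrapper script in `inst/cli/aoalearn`).

See `vignettes/accumulator-aoa-models.Rmd` for the model, the numerical
choices, what the synthetic generator does and does not emulate, and which
family distinctions are identifiable on the truncated 16–30 month window.

## Worked example

Simulate one cumulative-learning word (N = 12 exposures, constant rate,
mean AoA 23 months) for a cohort of 1000 children, then recover the
process from the 15 monthly proportions:

```r
library(aoalearn)

spec  <- data.frame(word = "dog", class = "noun", kind = "gamma",
                    N = 12, D = 1, delta = 12/23, slope = NA, intercept = NA)
norms <- simulate_norms(spec, population_spec(1000, 16:30, seed = 42))
p     <- as.numeric(norms[1, sprintf("p%d", 16:30)])

sel <- select_model(p, 16:30, word = "dog")
sel$winner
#> <word_fit> dog [gamma] loglik = -8654.093, BIC = 17313.601
#> <learning_params> N = 11.7638, D = 1, delta = 0.513523  [gamma family]

sapply(sel$candidates, function(f) round(f$bic, 1))
#>         gamma       weibull      logistic weibull_gamma
#>       17313.6       17329.2       17321.6       17316.3

median_aoa(p, 16:30)                        #> 23
round(estimated_mean_aoa(sel$winner), 2)    #> 22.91
classify_hazard_shape(sel$winner$params)    #> "monotone_increasing"
```

The gamma (cumulative) family wins on BIC, recovering N ≈ 11.8 against the
true 12; the runner-up full family pays the ln 15 ≈ 2.7 penalty for its
third parameter. The fitted median (23 months) is the first month at which
half the cohort produces the word, and the model-implied mean AoA (22.9
months) agrees with the 23-month truth.

End-to-end synthetic pipeline with a selection-accuracy report:

```sh
Rscript inst/cli/aoalearn demo --seed 7 --out demo_out --n-words 120
```

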