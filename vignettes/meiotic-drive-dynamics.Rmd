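---
title: "Modelling X-linked meiotic drive: from segregation mechanics to population fate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling X-linked meiotic drive: from segregation mechanics to population fate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiodrive)
```

## The problem

An X-linked meiotic driver is a selfish genetic element that biases male
gametogenesis so that more than half of a carrier's functional sperm carry
the X chromosome. Its transmission advantage comes at a population cost:
every extra daughter is a lost son, and a driver that is too successful
skews the sex ratio until males become limiting and the population collapses
— the classic paradox of sex-chromosome drive. `meiodrive` packages two
complementary models of this situation and the count statistics used to
analyse the relevant experiments:

1. a **deterministic discrete-generation population model** of an X-linked
   driver in a promiscuous species, with an analytic extinction threshold;
2. a **mechanistic branching model of male meiosis** in which a
   spermatid-killing protein segregates asymmetrically in both meiotic
   divisions, which caps the realised drive strength;
3. **synthetic-data generators** mirroring the cytological scoring and
   progeny sex-ratio assays used to measure these quantities, and the
   **exact count tests** applied to them, composed into a seeded end-to-end
   pipeline.

## The population model

Write X′ for the driving X. Generation $n$ carries $M_n$ males and $F_n$
females, subdivided into X′Y ($A_n$), XY ($B_n$) males and X′X′ ($C_n$),
X′X ($D_n$), XX ($E_n$) females; $R_n = A_n/M_n$ and
$K_n = (2C_n + D_n)/(2F_n)$ are the X′ frequencies among male and female X
chromosomes. Drive strength $t \in (0.5, 1]$ is the frequency of X-bearing
sperm sired by driver males (normal males segregate 1:1); $t = 0.5$ is
admitted as the Mendelian control.

Two demographic parameters close the model: the reproduction index $z$
(offspring per reproducing female, $z \ge 2$) and the mating index $w$
(females one male can fertilize, $w \ge 2$). If $w M_n \ge F_n$ every
female reproduces and the egg pool is $N = z F_n$ (*female-limited*
regime); otherwise only $w M_n$ females are fertilized and $N = z w M_n$
(*male-limited*). The regime test is inclusive ($\ge$) on the female-limited
side. Sons and daughters then follow

$$M_{n+1} = \left(\tfrac12 - t\right) N R_n + \tfrac{N}{2}, \qquad
  F_{n+1} = \left(t - \tfrac12\right) N R_n + \tfrac{N}{2},$$

with the five genotype counts obtained by pairing eggs (X′ at frequency
$K_n$) with the pooled sperm classes; `advance_counts()` implements this and
conserves $A+B = M$, $C+D+E = F$ to floating point. The frequencies obey the
size-free recursion implemented in `advance_frequencies()`:

$$R_{n+1} = K_n, \qquad
  K_{n+1} = \frac{K_n}{2} + \frac{t R_n}{(2t-1) R_n + 1}.$$

The compact form above is the production code; the algebraically equivalent
expanded allele-counting form
$[K/2 + tR + (t - \tfrac12)KR]/[1 + (2t-1)R]$ is kept in the test suite as
an oracle, together with a direct egg-by-sperm enumeration of the genotype
counts. For every $t > 0.5$ both frequencies rise to fixation
($R_n, K_n \to 1$), faster for stronger drive.

### Threshold, phases and numerical choices

At fixation the change rate $Total_{n+1}/Total_n$ is $z t$ in the
female-limited regime and $z w (1 - t)$ in the male-limited one. A steady
state (rate exactly 1) is impossible while females are limited — the
balance condition there gives $t = 1/z \le 0.5$, outside the drive domain —
so the critical drive strength solves $z w (1 - t) = 1$:

$$t_{\mathrm{threshold}} = 1 - \frac{1}{z w},$$

minimised at $0.75$ for $z = w = 2$. `analytic_threshold()` evaluates the
formula (and exposes the rejected female-limited candidate);
`numeric_threshold()` re-derives it end-to-end by bisection on the sign of
the simulated long-run log change rate. The long-run rate is measured only
after allele-frequency convergence ($R > 1 - 10^{-6}$), because every
trajectory — including doomed ones — goes through a transient growth phase
that would otherwise contaminate the sign test.

`simulate_trajectory()` classifies outcomes with these conventions, all
configurable:

* **extinction** when either sex falls below one expected individual
  (`extinction_floor = 1`; the model is real-valued, so extinction needs a
  numerical convention);
* **steady** when, after fixation, $|rate - 1| < 10^{-6}$ holds for 50
  consecutive generations; a drive strength exactly at the threshold
  classifies as steady;
* **expansion** when, after fixation, the rate stays above $1 + 10^{-6}$
  for 50 consecutive generations;
* **undetermined** at the horizon otherwise. A population in sustained
  post-fixation decline that has not yet reached the floor within the
  horizon is reported as extinction by `classify_dynamics()` (the decline
  rate is then locked below 1).

Populations are expected counts in double precision; frequencies are only
clipped to $[0,1]$ at the last ulp. The default horizon is 500 generations
for raw trajectories and 2000 for phase classification, which resolves
declines as slow as the 0.01-step sweep grid requires; classification stops
early once an outcome is locked, which also keeps growing populations far
from floating-point overflow. Defaults follow the standard initialisation
$M_0 = F_0 = 1000$, $R_0 = K_0 = 1/1000$, $z = w = 2$.

```{r phases}
parameter_sweep(c(0.6, 0.7, 0.75, 0.8, 0.9, 1.0), 2, 2)[, 1:6]
```

## The meiosis model

The driver of interest here kills spermatids: a protein expressed in
spermatocytes ends up in a subset of spermatids and blocks their nuclear
compaction. Four probabilities map cytology onto drive strength
(`meiosis_params()`):

| parameter | meaning | default source |
|---|---|---|
| `p1` | MI segregates the protein asymmetrically (one secondary spermatocyte gets all of it) | scored fraction of telophase I cells, ~0.8 |
| `q`  | given asymmetric MI, the protein cosegregates with the Y | scored fraction among asymmetric telophase I cells, 0.64–0.82 |
| `p2` | an MII division is asymmetric (one spermatid inherits the protein); chromosome-independent | scored fraction of telophase II cells, ~0.8 |
| `k`  | a protein-bearing spermatid dies | 1 (compaction defects appear fully penetrant) |

Assumptions: protein presence is binary (cells are scored positive or
negative; dilution is not modelled); a symmetric division leaves both
daughters positive (no loss branch, since all spermatocytes score positive
before meiosis); and the two MII divisions are independent — their
correlation is not experimentally addressed, so independence is an explicit
modelling choice. Nondisjunction is deliberately *not* part of this
mechanism; it enters only as an observation-level contaminant in the
synthetic FISH tables.

Each protein-positive secondary spermatocyte yields $2 - p_2$ expected
positive spermatids, giving closed forms (per meiosis, out of 2 spermatids
per chromosome)

$$E[Y^+] = (2 - p_2)(p_1 q + 1 - p_1), \qquad
  E[X^+] = (2 - p_2)(p_1(1 - q) + 1 - p_1),$$

with the protein-positive Y fraction $(1 - p_1 + p_1 q)/(2 - p_1)$
independent of $p_2$, and realised drive strength

$$t = \frac{2 - k\,E[X^+]}{(2 - k\,E[X^+]) + (2 - k\,E[Y^+])}.$$

The fully asymmetric, fully Y-biased, fully penetrant case kills exactly one
of the two Y spermatids: two X and one Y sperm survive, $t = 2/3$. This is
the model's central point — sequential asymmetry in MII spares half the
Y-bearing spermatids, capping the drive strength well below both complete
drive and the $0.75$ extinction threshold:

```{r meiosis}
expected_spermatid_composition(meiosis_params(1, 1, 1))
drive_strength_from_cytology(meiosis_params(1, 1, 1, 1))
analytic_threshold(2, 2)$t_threshold
```

`simulate_meioses()` is the Monte Carlo twin (per-meiosis Bernoulli draws,
bitwise reproducible under a seed); the suite checks it against an
exhaustive enumeration of the branching tree. `estimate_cytology_params()`
inverts scoring tables into binomial MLEs with exact Clopper–Pearson
intervals (`q` only among asymmetric cells, flagged `NA` when there are
none).

## Synthetic data: what it emulates and what it does not

The generators reproduce the *statistical structure* of three assay types,
with every table carrying its seed and generating parameters:

* `gen_telophase_counts()` — binomial per-cell scoring of MI/MII asymmetry
  and (MI only) Y-cosegregation;
* `gen_spermatid_fish_counts()` — X/Y identity of protein-positive
  spermatids, contaminated by a 0–4% nondisjunction class that downstream
  analysis must exclude (default rate 0.02, mid-band);
* `gen_progeny_counts()` — the sex-ratio assay: 10 males per genotype, 5
  mating periods each, per-period offspring Poisson with mean 60 (chosen so
  a genotype pools roughly 3,000 offspring, matching the scale at which
  such assays are informative; real per-male brood-size distributions are
  not published, so Poisson is a stand-in), each offspring female with
  probability $t$, plus an optional per-period `age_trend` emulating the
  observed rise of the female fraction as males age (default 0).

They do **not** emulate imaging, FISH signal intensity, overdispersed or
correlated brood sizes, male-to-male heterogeneity in drive strength, or
genotyping error. Passing tests therefore demonstrate correctness of the
inference machinery under the stated sampling model, not robustness to
those real-data features. Presets (`drive_presets()`) are labelled
parameter bands, not measurements.

## Statistics

The exact tests follow the "sum of probabilities no larger than the
observed outcome's" two-sided convention with a pinned relative tie
tolerance of $10^{-12}$ (conventions differ between tools, which is why it
is stated). `fisher_exact_two_sided()` conditions on both margins
(hypergeometric); `binomial_two_sided()` tests a single proportion against
a 50:50 null. The X-versus-Y spermatid null is a *one-sample* question, so
the pipeline uses the exact binomial test there and reserves the 2×2 Fisher
test for between-genotype comparisons; reports of "Fisher's exact test"
against a 50:50 null in this literature do not print their 2×2 construction,
and this split is the cleaner reading. Sex-ratio comparisons between
genotypes use the classic equal-variance unpaired $t$ test on per-male
female:male ratios (the common graphing-software default; Welch behind a
flag). No multiple-testing correction is applied: per-comparison exact
$P$ values are reported, as is conventional for these assays.

`run_full_pipeline()` chains everything under one master seed (per-stage
sub-seeds are derived deterministically): generate driver and control
genotypes, exclude nondisjunction spermatids, estimate
$(\hat p_1, \hat q, \hat p_2)$ and $\hat t$ (pooled female fraction, exact
binomial CI), run the three tests, and confront $\hat t$ with
$t_{\mathrm{threshold}}$ for the configured demography:

```{r pipeline}
report <- run_full_pipeline(list(preset = "XSte200_Y", seed = 42))
report
```

Identical configuration and seed give byte-identical JSON via
`write_pipeline_report()` (12 significant digits, fixed key order).

## Problem sizes and limitations

The shipped defaults — 500 scored cells per telophase table, 1,000 FISH
spermatids, 10 males × 5 periods × Poisson(60) progeny, 500–3,000
simulated generations, $10^5$ Monte Carlo meioses in the heaviest check —
are the sizes at which the package's own test suite and acceptance script
run; they were chosen to make binomial standard errors small relative to
the effects of interest, and they keep the entire suite in well under a
minute.

Known limitations, deliberate non-goals:

* the population model is deterministic — no drift, no demographic
  stochasticity, no overlapping generations, no driver fitness costs, and
  no suppressor dynamics; the extinction floor of one expected individual
  is a convention, not a prediction of extinction time in finite
  populations;
* the meiosis model has no protein-amount dilution, no meiotic-catastrophe
  (high-expression sterility) regime, and assumes independent MII
  divisions;
* exact generation counts to extinction are validated by ordering
  properties (stronger drive dies no later), since only trajectory shapes,
  not printed numbers, are available to pin them.
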