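# meiodrive

Tools for studying X-linked meiotic drivers that kill Y-bearing sperm: how
strong their drive really is, and what that strength does to the population
that carries them. The package is aimed at evolutionary geneticists and
modellers working on sex-chromosome drive (the motivating system is a
*Drosophila* X-linked spermatid killer), and at anyone who needs a clean,
seeded testbed for the count-based statistics used in such studies.

## What it computes

**Population fate.** A deterministic discrete-generation recursion tracks
males `M_n`, females `F_n`, genotype counts and the driving-X frequencies
`R_n` (males) and `K_n` (females) under drive strength `t` (fraction of
X-bearing sperm from driver males), reproduction index `z` (offspring per
reproducing female) and mating index `w` (females one male can fertilize).
The frequency recursion is

    R[n+1] = K[n]
    K[n+1] = K[n]/2 + t R[n] / ((2t - 1) R[n] + 1)

and the egg pool switches from `z F_n` (enough males for all females,
`w M_n >= F_n`) to `z w M_n` once males become limiting. The steady state at
fixation of the driving X exists only in the male-limited regime and gives
the extinction threshold

    t_threshold = 1 - 1 / (z w)

minimised at **0.75** for `z = w = 2`: any driver stronger than that drives
the population extinct, any weaker one lets it keep expanding (while still
fixing itself). `numeric_threshold()` recovers the same boundary from
simulation by bisection.

**Drive strength from meiosis mechanics.** A branching model of one male
meiosis with four probabilities — MI asymmetry `p1`, Y-cosegregation `q`,
MII asymmetry `p2` (chromosome-independent), killing penetrance `k` — yields
closed-form spermatid compositions and the realised drive strength. The
fully asymmetric, fully Y-biased case leaves 2 X : 1 Y surviving sperm, i.e.
`t = 2/3`: sequential asymmetry in meiosis II spares half the Y-bearing
spermatids and caps the drive *below* the 0.75 extinction threshold.

**Synthetic studies and exact statistics.** Seeded generators emulate
telophase scoring tables, X/Y FISH counts among protein-positive spermatids
(with a low nondisjunction class that analyses must exclude) and per-male
progeny sex counts; exact two-sided Fisher, exact binomial and unpaired t
tests, plus drive-strength estimation with Clopper–Pearson intervals, are
composed into a deterministic end-to-end pipeline
(`run_full_pipeline()`).

## Worked example

```r
library(meiodrive)

analytic_threshold(2, 2)
#> extinction threshold (analytic): t = 0.75 at z = 2, w = 2

drive_strength_from_cytology(meiosis_params(p1 = 1, q = 1, p2 = 1, k = 1))
#> [1] 0.6666667

parameter_sweep(c(0.6, 0.7, 0.75, 0.8, 0.9, 1.0), 2, 2)[, 1:6]
#>      t z w    outcome transition_generation extinction_generation
#> 1 0.60 2 2  expansion                    NA                    NA
#> 2 0.70 2 2  expansion                    NA                    NA
#> 3 0.75 2 2     steady                    NA                    NA
#> 4 0.80 2 2 extinction                    56                   108
#> 5 0.90 2 2 extinction                    39                    55
#> 6 1.00 2 2 extinction                    31                    40
```

Drivers at 60–70% strength expand the population indefinitely, 75% holds it
exactly steady, and anything stronger collapses it — faster the stronger the
drive (`transition_generation` is where growth turns to decline,
`extinction_generation` where a sex drops below one expected individual).

The pipeline ties mechanism, inference and forecast together on synthetic
data:

```r
run_full_pipeline(list(preset = "XSte200_Y", seed = 42))
#> synthetic drive study: preset 'XSte200_Y', seed 42
#>   drive strength: t_hat = 0.5808 [0.5628, 0.5987] (cytology-implied 0.5876)
#>   threshold at z = 2, w = 2: 0.7500; margin -0.1692 -> expansion
#>   p-values: FISH vs 50:50 1e-24; sexes vs control 3.54e-09; per-male t 5.88e-05
```

Here ~3,000 synthetic offspring give a pooled drive-strength estimate of
0.581 (95% CI 0.563–0.599) against a cytology-implied truth of 0.588; the
driver sits 0.17 below the extinction threshold, so the forecast is
continued population expansion, and all three tests reject their nulls (the
spermatid pool is Y-enriched and the sex ratio is female-shifted relative
to the control genotype).

See the vignette (`vignettes/meiotic-drive-dynamics.Rmd`) for the model
derivations, assumptions and numerical conventions.

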