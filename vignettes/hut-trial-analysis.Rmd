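---
title: "Analysing trapping-bednet experimental hut trials with huttrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing trapping-bednet experimental hut trials with huttrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(huttrap)
```

## The problem

Experimental hut trials are the WHO-standard field assay for bednets:
volunteers sleep under candidate and reference nets in purpose-built huts,
and every morning the mosquitoes inside each hut are collected and scored.
`huttrap` implements the analysis for trials of *hybrid trapping bednets*
(T-LLINs) — conventional long-lasting insecticidal nets carrying an
insecticide-free upper trap compartment that captures mosquitoes attacking
the roof. The endpoint of interest is mortality: because a trapped mosquito
is removed from the biting population regardless of its insecticide
resistance status, it is counted as killed even if alive at collection.

The package covers the whole workflow: rotation-schedule construction,
validated hut-night count records, endpoint summaries, the increased
killing-effect statistic, nonparametric inference with significance
letters, and a calibrated simulator so every stage can be exercised
without field data.

## Trial design

The reference layout has 5 arms x 2 replicate nets = 10 huts and 10
sleepers. Sleepers rotate through huts by a daily cyclic shift (the
rotation rule is not more specifically standardised, so the simplest
balanced choice is used); nets move every 3 nights along the rows of a
randomised Latin square, so that over a full 10-block cycle each physical
net visits each hut exactly once:

```{r design}
design <- build_schedule(default_arms(), n_nights = 34, seed = 1)
design
head(as.data.frame(design))
```

`n_nights` defaults to 34: trial reports of this design quote roughly 68
hut-nights per arm (two replicate huts), consistent with a six-week trial
with collections most nights. Trials whose length is not a multiple of the
rotation period simply truncate the final block. `validate_schedule()`
re-checks every invariant (one sleeper and one arm per hut per night, net
moves only on period boundaries, no hut revisited within a cycle) and
returns violations rather than raising, so it can be used on imported
schedules. When a schedule is read from CSV the physical net identities
are gone, and the revisit check degrades gracefully to the arm level,
where up to `n_replicate_nets` visits per hut and cycle are legitimate.
Huts are treated as exchangeable units; hut geometry and window-trap
placement are not modelled, and residual hut-to-hut differences are
absorbed by the rotation and, in simulation, by multiplicative hut
effects.

## Records and endpoints

One record is one hut x night x species group, with four mutually
exclusive fates: `trapped`, `dead_untrapped` (immediate insecticide
kill), `alive_delayed_dead` (died during the 24-36 h post-collection
holding period) and `alive_survived`. Where mosquitoes were found dead
(in the room or in window exit traps) is deliberately collapsed: no
mortality endpoint distinguishes the two. The death count of a record is
`trapped + dead_untrapped + alive_delayed_dead`.

`summarize_arm()` aggregates to per-hut-night totals and reports daily
means and SDs over hut-nights (denominator $n-1$), the mortality
percentage $100\,D/E$ and the trap-attributable share $100\,T/D$ (defined
as trapped over *deaths*, not entries, and 0 when $D = 0$). Zero-catch
hut-nights are real observation nights and enter the means.

## The increased killing effect

The statistic at the heart of the analysis is the excess kill of the
candidate net over a reference net, as a percentage of a reference catch.
Two formulations circulate for this design, differing in the denominator:

* **methods** — $100\,(K_c - K_r)/T_r$, scaling by the *reference arm's*
  catch $T_r$;
* **control-adjusted** — $100\,[(K_c - K_u) - (K_r - K_u)]/T_u$, which
  algebraically reduces to $100\,(K_c - K_r)/T_u$: the untreated-control
  kill $K_u$ cancels, and the *untreated-control* catch $T_u$ is the
  common denominator.

Both are implemented (`killing_effect_methods()`,
`killing_effect_control_adjusted()`), and the cancellation is verified by
a quantified property test. On the reference trial's published arm totals
the control-adjusted formulation reproduces the reported headline values
to within rounding (58.9/38.4/31.8 vs 58.5/38/31.5) while the methods
formulation does not (52.1/24.8/23.4); the exact denominator and rounding
behind the printed values are not recoverable, so the package makes the
control-adjusted variant the default and reports the discrepancy rather
than silently resolving it:

```{r reproduce}
reproduce_reference_results()
```

`flagged` marks rows more than half a percentage point from the printed
value. Because the control-adjusted denominator is shared, its values are
directly comparable across reference nets.

## Inference

Arms are compared on per-hut-night values with the Kruskal-Wallis test
(mid-ranks, tie-corrected H, $\chi^2_{k-1}$ reference), followed by
Conover-Iman rank comparisons: $t$ statistics on rank means with the
pooled tie-corrected rank variance, $N-k$ degrees of freedom, and
Bonferroni correction (multiplication by $k(k-1)/2$, capped at 1). Head-to-head
comparisons of the candidate against each arm use the two-sample
rank-sum (Wilcoxon/Mann-Whitney) test — the two-sample form is the right
reading here because arms are compared between huts, never paired within
them. When the combined sample size is at most 12 the rank-sum p-value is
computed by exact enumeration of all assignments of the pooled mid-ranks,
which keeps toy fixtures exact even under ties; larger samples use the
tie-corrected normal approximation. The test suite cross-checks both
tests against brute-force permutation oracles for all combined sizes up
to 9.

Summary tables carry compact letter displays built by insert-and-absorb:
two arms share a letter exactly when their adjusted pairwise comparison
is non-significant. That biconditional is the defining property and is
verified exhaustively on hundreds of random significance patterns.
Letters are ordered a, b, c, ... by first use over arms in input order;
the specific letter sequence of any published table depends on its raw
data and is not a reproduction target.

## The simulator

`simulate_trial()` draws, for each hut-night and species group, a
negative-binomial entry count with mean
$\mu = \text{baseline} \times \text{hut effect} \times \text{night effect}
\times \text{deterrence}$, then assigns fates sequentially: trapped
first (mosquito attack concentrates on the roof, where the trap sits),
then immediate insecticide kill, then delayed death among survivors.
Sequential Bernoulli draws mirror the mutually exclusive scoring of real
collections. The closed-form arm mortality is therefore
$p_{trap} + (1-p_{trap})\,p_{imm} + (1-p_{trap})(1-p_{imm})\,p_{del}$,
with trap-attributable fraction $p_{trap}$ over that total
(`closed_form_expectations()`).

Parameter choices and what they emulate:

* `entry_dispersion = 1.5` (negative-binomial size): hut catches are
  strongly overdispersed — reference daily SDs are of the order of the
  daily means — and $k = 1.5$ reproduces that magnitude.
* `hut_effect_sd`, `night_effect_sd` (0.25): mean-one log-normal
  multiplicative effects; sleeper attractiveness is folded into the
  night effect, as the two are not separately identifiable from a
  rotation of this kind.
* `baseline_entry_mean` is the *An. gambiae* entry rate per hut-night;
  the other-species group scales by `(1 - species_mix)/species_mix`, so
  `species_mix` is the *An. gambiae* share of the total catch (0.388 in
  the reference trial).
* `deterrence_multiplier` defaults to 1 everywhere: entry-rate
  differences between arms of the reference trial were not statistically
  significant. The calibrated set `reference_trial_params()` nonetheless uses
  the observed relative entry rates (9.0 : 10.3 : 7.5 : 11.2 : 6.6) as
  multipliers, because the killing effect scales kill *counts* by the
  control *catch*: with equal expected entries everywhere, no parameter
  choice could reproduce killing effects anywhere near the reference
  magnitude. The multipliers are an empirical entry pattern, not a claim
  of deterrence.
* Delayed mortality is a single Bernoulli per surviving mosquito; the
  24-36 h holding window is not time-resolved.

`reference_trial_params()` is calibrated once, to the reference arm
mortalities (0.88, 0.72, 0.81, 0.89 with ~47% trap share, 0.26) via the
closed form above.

What passing simulation tests do and do not show: the generator
reproduces the count structure the analysis assumes — overdispersion,
multiplicative nuisance effects, exclusive fates, the endpoint
magnitudes. It does not emulate behavioural responses (irritancy-driven
early exit, net-age effects, carry-over between nights), spatial hut
differences or misclassification of fates, so recovery of its own
parameters is evidence of internal consistency, not of field validity.

## Problem sizes and numerical conventions

Parameter-recovery checks simulate 2 huts/arm x 2000 nights (about
4000 hut-nights per arm), at which scale estimated arm mortalities sit
within one percentage point of their closed-form values (binomial SE
~0.3 points) and killing effects within three delta-method Monte-Carlo
SEs; three fixed seeds guard against a lucky draw. Property suites use
200 seeds for design invariants, 100 random instances for the
rank-test-vs-enumeration identity (combined $n \le 9$, the exhaustively
enumerable range) and 200 random significance patterns for the letter
display. Degenerate inputs follow fixed conventions: complete ties give
$H = 0$, $p = 1$; a zero-death arm has trap-attributable share 0;
killing effects with a single arm yield an empty table rather than an
error.

## Known limitations

Only mortality endpoints are implemented: deterrence, exit rates and
blood-feeding inhibition are out of scope, as are personal-protection or
community-level epidemiological projections and models of
insecticide-resistance dynamics. The daily means/SDs and letter
sequences of any particular published table cannot be reproduced without
its raw nightly records; they are covered instead by the simulator
calibration and the letter-display invariant.
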