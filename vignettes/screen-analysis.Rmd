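---
title: "Robust analysis of arrayed siRNA reporter screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust analysis of arrayed siRNA reporter screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaiscreen)
```

## The screening problem

An arrayed loss-of-function screen asks, gene by gene, whether knocking
a gene down changes a pathway readout. Here the readout is an
NF-κB-driven luciferase reporter: each well of a 384-well plate receives
one siRNA (the library carries three independent siRNAs per gene), cells
are stimulated — etoposide for the DNA-damage-induced arm of NF-κB
signalling, TNFα for the canonical arm — and the relative luminescence
(RLU) per well measures pathway output. Knockdown of a pathway
*activator* lowers the stimulated signal; knockdown of a *suppressor*
raises it.

Raw RLU is dominated by nuisance structure: plates differ in cell
number, reagent age and reader drift (a multiplicative plate effect),
and well-level noise is right-skewed and roughly proportional to signal.
The analysis therefore has four stages, each available as a standalone
function and orchestrated by `run_screen()`:

1. plate-wise robust Z normalization (`normalize_screen()`),
2. per-plate Z′-factor quality control (`plate_qc()`),
3. gene-level aggregation and rank-based hit calling
   (`aggregate_gene_scores()`, `select_hits()`, `apply_exclusion()`),
4. dual-stimulus counter-screen classification (`classify_groups()`).

## Plate-wise robust Z

Each plate is its own reference population:

$$z_w = \frac{x_w - \operatorname{median}(x_S)}{c \cdot
\operatorname{median}_{v \in S}\,|x_v - \operatorname{median}(x_S)|}$$

with $S$ the plate's sample wells and $c$ the MAD scale constant.
Median/MAD (rather than mean/SD) keeps a handful of strong hits from
inflating the plate's own scale estimate, and per-plate centring removes
the multiplicative plate effect entirely — the Z-score is invariant
under $x \mapsto a x + b$, $a > 0$, which the tests assert.

Numerical conventions, stated so results are exactly reproducible:

* the median of an even-sized subset is the midpoint of the two central
  order statistics;
* `mad_constant` defaults to 1.4826 (the normal-consistency factor and
  the convention of the R/KNIME family of screening workflows); passing
  `mad_constant = 1` gives the unscaled MAD. Two algebraic identities
  hold per plate and are tested: $\operatorname{median}(z) = 0$ and
  $\operatorname{median}(|z|) \cdot c = 1$;
* control wells are never in $S$ and receive no Z-score;
* a plate whose sample wells have zero MAD cannot be scored; it raises a
  classed degenerate-plate condition and `normalize_screen()` excludes
  it with a logged reason rather than emitting infinite scores.

No row/column (edge-effect) polish is applied: the pipeline scores
plates exactly as measured, and the simulator likewise generates no
spatial gradients by default.

Where the assay includes the TOX viability channel,
`viability_normalize()` divides RLU by per-well viability first, so
toxicity does not masquerade as pathway inhibition. Plates lacking the
channel fail fast; nothing is imputed.

## Plate quality control

`z_factor()` implements
$Z' = 1 - 3(\sigma_p + \sigma_n)/|\mu_p - \mu_n|$
with sample standard deviations, the standard effect-size measure of a
screening window. The positive controls are operationalized as the
stimulated nontargeting-siRNA wells and the negative controls as the
DMSO vehicle column (both layout-configurable, since plate designs
differ in which wells are free). Plates pass at $Z' \ge 0.1$; failing
plates are flagged for repetition, never silently dropped, and repeated
plates are resolved by `resolve_repeats()` (keep-latest by default,
keep-best-Z′ optionally). The report also counts plates below and
at-or-above 0.5 — the conventional excellent-assay mark — and computes
Spearman's ρ between replicate plates over sample wells (average ranks
on ties) as the reproducibility statistic.

## Gene-level hit calling

With three siRNAs per gene, the gene score in each direction is the
*best-scoring* siRNA: the signed minimum Z for the activator direction
and signed maximum for the suppressor direction. This directional
extremum (not $|z|$) matches the screen's reading of low-Z activators
and high-Z suppressors. Because a single efficacious siRNA can carry a
gene, a stricter `method = "second_best"` aggregation (two-of-three
evidence) is available but off by default — the primary rule is a design
choice the package exposes rather than hides.

Selection is by rank count — 1,000 activator and 100 suppressor
candidates by default — not by a Z threshold. Ties at a boundary break
deterministically (equal Z, then lexicographically smaller gene id), so
shuffled input yields byte-identical flag sets. Genes whose every siRNA
sat on an excluded plate are reported in an unscored side table, not
ranked. `apply_exclusion()` then removes candidates in user-supplied
categories (ribosome, proteasome, general transcription/RNA-processing
machinery) — genes required for any reporter expression, hence
uninformative — recording the category per gene.

## Counter-screen classification

The counter screen re-assays the activator candidates under both
stimuli. The classification rule is an explicit, deterministic
thresholding: group I if the gene's etoposide-arm RLU is strictly below
$f_{eto} \times \theta_{eto}$ (treatment-control reference), group II if
its TNFα-arm RLU is strictly above $f_{tnf} \times \theta_{tnf}$ (the
siTRAF6 reference — TRAF6 is required for the DNA-damage arm but has no
prominent role in TNFα signalling, making its knockdown a natural
"still responds to TNFα" yardstick). Both multipliers default to 1.0;
genes exactly at a threshold are non-members, and signed margins are
recorded per gene so any re-thresholding is auditable. The selective set
is exactly group I ∩ group II. Classification operates on whatever RLU
scale it is given (raw or viability-normalized); the choice is the
caller's and is preserved in the margins.

## What the synthetic screens emulate

`simulate_primary_screen()` generates
$$\mathrm{RLU} = p \cdot B \cdot \left(1 + (F - 1)\,m\right) \cdot
e^{\varepsilon}$$
per well: plate effect $p \sim \mathrm{LogNormal}(0, s)$, baseline $B$,
induction fold $F$ (1 in the vehicle column), knockdown acting only on
the induced component through the remaining fraction
$m = 1 - e\,(1 - \kappa)$ — reflecting that pathway knockdown abolishes
*stimulated* reporter activity, not basal expression — and multiplicative
log-normal well noise with $\sigma = \sqrt{\ln(1 + CV^2)}$, the natural
noise model for a strictly positive, right-skewed luminescence readout.

Defaults, chosen once as a realistic screening regime and then left
alone:

| parameter | default | rationale |
|---|---|---|
| `sirnas_per_gene` | 3 | library design |
| `prop_activator` / `prop_suppressor` | 0.10 / 0.05 | pathway-responsive minority |
| `activator_multiplier` | 0.1 | 90% induced-signal loss for an effective siRNA |
| `suppressor_multiplier` | 3 | de-repression raises induced signal |
| `p_effective` | 0.8 | typical validated-library efficacy; gives ≥ 2 of 3 effective siRNAs for ~90% of genes |
| `partial_efficacy_max` | 0.3 | ineffective siRNAs still nudge the signal |
| `baseline_rlu`, `induction_eto`, `induction_tnf` | 100, 10×, 8× | strong reporter window |
| `noise_cv` | 0.15 | well-to-well CV of a good luminescence assay |
| `plate_effect_sdlog` | 0.1 | ~10% plate-to-plate scale drift |
| `death_kill_fraction` | 0.05 | cell-death control collapses signal |
| `prop_selective` | 0.5 | half the activators are DNA-damage selective |
| `sitraf6_tnf_multiplier` | 0.8 | siTRAF6 reference just below the full TNFα response |

Under these defaults the simulated plates have Z′ ≈ 0.45–0.55 — some
below 0.5, some above — which is exactly the quality mix a large
production screen shows, and gives the QC stage a realistic workload.
Everything is deterministic given `seed`; control wells follow their
roles (vehicle column unstimulated, pathway control ≈ strong activator
knockdown, death control scaled by the kill fraction). The library is
laid out 352 siRNAs per plate with trailing wells of the final plate
EMPTY.

`simulate_counter_screen()` reuses the recorded ground truth: all
activator knockdowns suppress the etoposide arm, but only non-selective
(shared) activators also suppress the TNFα arm; references come from
simulated control wells. `evaluate_recovery()` closes the loop with
precision/recall/ranks against truth (precision is `NA` when nothing is
flagged).

What the generator does **not** emulate — and what passing tests
therefore do not establish about real screens: siRNA off-target/seed
effects, spatial row/column gradients (a `column_gradient` switch exists
for robustness testing, but the default is none and the pipeline applies
no spatial correction), imaging-based replicate
arms, autocrine TNFα secondary activation in the counter screen, and
any biological correlation structure between genes. Recovery rates on
synthetic screens are upper bounds on real-data performance.

## Problem sizes and determinism

The test-suite and acceptance runs use desk-scale screens — 2,000 genes
× 3 siRNAs (18 plates) for the power, calibration and determinism
checks, 200–500 genes elsewhere — sizes at which every stage's behavior
(plate layout wrap-around, partial final plate, replicate handling) is
fully exercised. Oracle checks run the robust-Z against an independent
sort-based median/MAD computation to 1e-12 relative on 200 random
plates, and Spearman against a rank-then-Pearson closed form. All
randomness flows from explicit seeds; re-running any stage with the same
configuration reproduces identical outputs, which the pipeline tests
assert via full equality.

## Known limitations

* The gene ranking rule (best single siRNA) is a documented assumption;
  screens wanting redundant-siRNA statistics (RSA and relatives) need a
  different aggregator.
* Group-I/II thresholds are deterministic cutoffs, not per-gene tests;
  margins are reported so users can judge borderline calls.
* Degenerate (constant) plates are excluded rather than repaired; with
  many such plates the unscored-genes side table should be inspected.
* The 0.1 Z′ cutoff accepts plates with modest windows by design;
  raising it trades coverage for per-plate reliability.
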