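---
title: "Estimating mutation effects in plant proximal promoters from TBP binding affinity"
author: "planttata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutation effects in plant proximal promoters from TBP binding affinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planttata)
```

## The problem

The TATA box is the most conserved core-promoter element, and the strength
with which the TATA-binding protein (TBP) binds a proximal promoter is
monotonically related to the expression level of the downstream gene.
Mutations within the ~90 bp upstream of a transcription start site (TSS)
can therefore raise or lower expression by changing TBP–promoter affinity.
Measuring this for every candidate mutation is slow and expensive; this
package predicts the direction and significance of the change from sequence
alone.

Predicting a mutation's expression effect directly in plants is, however,
an *ill-posed inverse problem*: the same promoter mutation measured under
different growth conditions (for example, tobacco grown in the dark versus
under light) can show uncorrelated expression effects, so a single uniform
answer need not exist. The package follows a regularization strategy:
anchor the plant problem to the analogous, well-characterized human-TBP
problem via two calibrated linear maps, and report predictions on the plant
scale derived from that anchor. Plant and human TBPs are interchangeable in
vitro, which is what justifies the anchoring.

## The affinity model

A promoter fragment is scored by a three-step physical approximation of
complex formation:

1. **Slide.** TBP first interacts non-specifically while sliding along the
   DNA. We model this as the mean, over every `window_w`-bp window of the
   fragment, of a dinucleotide "sliding" scale summed over each window's
   steps. The default scale scores the AT-rich steps TA/AT/AA/TT at +1 and
   all others at 0 — an AT-richness proxy for weak non-specific attraction.
2. **Stop.** TBP settles on the best binding site: the maximal
   position-weight-matrix (PWM) score over all windows. The default PWM is
   built from the plant TATA-box consensus `tcacTATATATAg` with a
   pseudocount of 0.25 per position, log-odds against a uniform
   background, centred in a 15-bp window (the two flanking columns are
   uninformative zeros).
3. **Bend.** The complex is fixed by DNA bending at a right angle, modelled
   by a dinucleotide bendability scale summed over the chosen window's
   steps. The shipped table (`inst/extdata/bend_dinucleotide.tsv`) is a
   strand-symmetric deformability ranking with the pyrimidine–purine steps
   TA and CA/TG most flexible.

The score is a linear combination,

$$-\ln K_D \;=\; c_0 + c_1\,\mathrm{slide} + c_2\,\mathrm{stop} +
  c_3\,\mathrm{bend},$$

in natural-log units of a dissociation constant expressed in nM, with a
fixed per-estimate standard deviation $\varepsilon$. Every ingredient —
PWM, the two 16-value scales, $c_0,\dots,c_3$, $\varepsilon$, window width,
strand handling — is *data*, loadable from a plain-text config
(`read_model_config()`), because the literature-derived coefficient values
behind the original human-promoter service are not published as reusable
tables. The shipped defaults ($c_0 = 0$, $c_1 = c_2 = c_3 = 1$,
$\varepsilon = 0.5$ ln units, 15-bp window, forward strand only) are
documented surrogates chosen to make each component contribute on a
comparable ln-unit scale; a user holding the original coefficients can
substitute them without touching code.

```{r}
m <- affinity_model()
wt <- paste0(strrep("GC", 21), "TCACTATATATAG", strrep("CT", 17), "C")
estimate_affinity(validate_promoter(wt, id = "wt"), m)
```

### Numerical choices

* **Coordinates** are 0-based half-open offsets from the 5′ end of the
  supplied fragment (position −90 relative to the TSS for a standard
  input).
* **Tie-breaking.** If several windows tie for the maximal PWM score, the
  one with the lexicographically smallest scored window string wins, then
  the lowest start, then `+` before `-`. Content-based tie-breaking is the
  deliberate design choice here: it is deterministic *and*
  strand-symmetric, so both-strand scanning gives exactly the same
  estimate for a fragment and its reverse complement even under ties,
  which a purely positional rule cannot guarantee.
* **Alphabet.** Input is uppercased, U is mapped to T, and any other
  character is rejected with its position; the affinity sums are undefined
  on IUPAC ambiguity codes. Fragments that are not 90 bp are accepted but
  flagged, since the calibration assumes the 90-bp TSS-anchored window.
* **Strands.** Forward-only by default (promoter orientation is defined by
  the TSS); `scan_both_strands = TRUE` appends reverse-complement windows,
  with the slide component averaged over all scanned windows.

## The two rescaling equations

Two linear maps connect the model to plant measurements:

$$K_D[\mathrm{nM}] = 1.1 - 0.9\,F \qquad\text{and}\qquad
  -\ln K_{D,\mathrm{plant}} = 7.0 + 0.6\,(-\ln K_{D,\mathrm{human}}),$$

where $F$ is relative transcription efficiency. Defaults are exactly these
published coefficients (`rescale_parameters()`); both maps can be
re-derived from new paired data with `calibrate_linear()` (ordinary least
squares). Logarithms are taken of the numeric $K_D$ value in nM, so
$K_D = 1$ nM corresponds to $-\ln K_D = 0$; no reference concentration is
introduced because the calibration fixes nM as the working unit. Because
the first map is linear, efficiencies at or above $a_1/b_1 \approx 1.22$
would imply a non-positive $K_D$: the package treats this as a domain
error by default, with an optional documented floor-clamp (`kd_floor`),
since the behaviour of the original calibration outside its fitted range
is unspecified. The estimate's standard deviation is propagated through
the second map by multiplying by its slope $b_2$, the exact propagation
for an affine transform of a random variable.

## The Z comparison

Two variants are compared on the plant scale:

$$Z = \frac{A_2 - A_1}{\sqrt{sd_1^2 + sd_2^2}},$$

with a two-sided standard-normal p-value and the default threshold
$\alpha = 0.05$. A significantly positive $Z$ predicts expression *excess*
for the second promoter, a significantly negative one *deficiency*,
otherwise *insignificant*. Because the plant map is affine with positive
slope and the sd is propagated consistently, $Z$ is identical whether
computed on the human or plant scale (asserted in the test suite).

```{r}
mut <- mutate_tata(wt, list(type = "substitution", pos = 48, base = "G"))
compare_promoters(wt, mut, m)
```

## Verification statistics

`verify_dataset()` recomputes plant-scale predictions for every variant of
a dataset and correlates them with the measured expression using four
association measures: Pearson's $r$, Spearman's $R$ (Pearson on
mid-ranks), Kendall's tie-corrected $\tau_b$, and the Goodman–Kruskal
$\gamma = (C - D)/(C + D)$ over concordant/discordant pairs (tied pairs
ignored). Datasets with fewer than five variants are refused — five is the
minimum family size admitted for a meaningful analysis.

Significance conventions, chosen where the field's desktop statistics
packages leave room:

* Pearson and Spearman: $t$ statistic with $n-2$ degrees of freedom,
  two-sided.
* Kendall $\tau$: normal approximation to $S = C - D$ with the standard
  tie-corrected variance.
* $\gamma$: normal approximation with the consistent null-hypothesis
  asymptotic standard error
  $\mathrm{ASE}_0 = \sqrt{\sum_i (C_i - D_i)^2 - 4S^2/n}\,/\,(C+D)$,
  where $C_i, D_i$ count observation $i$'s concordances over both pair
  directions. The simpler textbook statistic
  $\gamma\sqrt{(C+D)/(n(1-\gamma^2))}$ is markedly conservative under
  independence and would distort the null distribution of p-values; the
  ASE$_0$ form is calibrated (simulation at $n = 52$: z-sd ≈ 1.04,
  p-values uniform).
* For $n \le 8$ both rank statistics switch to the exact permutation
  distribution over all $n!$ reorderings.

Zero-variance inputs make all four coefficients undefined; they are
reported as `NA` with an explanatory note, never silently as 0.
`fit_with_ci()` adds the ordinary least-squares line with a pointwise
confidence band for the mean response ($t$, $n-2$ df), the band drawn
through prediction–measurement scatter plots.

One numerical subtlety: variants with identical sequences must yield
exactly tied predictions, but floating-point summation order can leave
differences of order $10^{-15}$ that break ties in one variable and not
the other. Predictions are therefore snapped to a $10^{-9}$ ln-unit grid
wherever they are collected for rank statistics — nine orders of magnitude
below $\varepsilon$, so nothing scientifically distinguishable is merged.

## The knowledge-base flat file

`write_kb()`/`read_kb()` handle a tab-separated, UTF-8, header-rowed,
spreadsheet-openable table of variant records grouped into datasets
(fixed column order; "." decimal separator). Embedded tabs or newlines in
fields are rejected rather than quoted — the simplest unambiguous dialect.
Malformed rows are collected into a line-numbered diagnostics table
attached to the result rather than aborting the whole load.
`summarize_kb()` reproduces compilation-table bookkeeping: distinct
promoters, genes, experimental systems, TBP species and polymerases, total
variants, and distinct references (cells citing several references count
each). `kb_table1_fixture()` builds a twelve-dataset knowledge base with
the bookkeeping shape of the published compilation of plant
promoter-variant experiments — per-dataset counts 24, 24, 8, 16, 30, 7, 7,
7, 10, 5, 52, 52, totalling 242 variants over 10 promoters, 7 reporter
genes, 6 systems, 4 TBPs, 2 polymerases and 9 references. Its sequences
and measurements are synthetic: the real 242 measured variants are not
available as plain data, so only the schema and counts are faithful, and
the fixture is documented as such.

## The synthetic generator: what it emulates, and what it does not

`generate_dataset()` produces one promoter family: a wildtype (random
background with the plant TATA consensus planted at offset 56 of 90,
placing the box ~25–35 bp upstream of the TSS) plus mutants carrying
point substitutions in or near the box and/or 1–3 bp deletions of the
spacer between the box and the TSS. Deletions re-pad the fragment at the
5′ end so the 90-bp TSS-anchored frame is preserved — the model's
machinery assumes that frame, and how the original service handles indels
is not documented, so the anchored-repad convention is this package's own
explicit choice. Expression is generated as
`intercept + slope * predicted + N(0, noise_sd)` on the plant-scale
predictions: a linear-plus-Gaussian link whose ground truth is exactly
known, which is what makes parameter-recovery and coverage experiments
possible. `noise_sd_for_target_r2()` inverts the closed form
$r^2 = s^2_{\mathrm{signal}}/(s^2_{\mathrm{signal}} + \sigma^2)$ to hit a
target explained-variance fraction, e.g. the ~10% of expression variation
that TBP affinity alone explains in vivo.

Generator defaults (24 variants — the size of the in vitro calibration
family — unit link slope, unit noise sd on the arbitrary expression scale)
are fixed once as a realistic working point; tests that need other
conditions state them explicitly.

What the generator does *not* emulate: binding sites for transcription
factors other than TBP, nucleosome context, condition-dependent (light /
dark) regulation, or the actual measured values of any published family.
Passing tests on synthetic data therefore demonstrate that the machinery
is correct and calibrated under its own assumptions — not that the model
explains real plant expression beyond the anchored-affinity component.

## Problem sizes used in the checks

The test suite and the acceptance script run entirely on synthetic data at
desk scale, matching the sizes of the compiled experimental families:
families of 5–52 variants, 200 seeded vectors for the pair-enumeration
oracle, 500 replicates for confidence-interval coverage, 100–200
replicates for the null (independent-noise) and explained-variance
experiments. These sizes give stable Monte-Carlo estimates (binomial sd
below 1 percentage point for the coverage check) while keeping a full run
in the tens of seconds.

## Known limitations

* The shipped slide/bend scales and combination coefficients are
  surrogates: directionally sensible, documented, and replaceable, but not
  the original literature-derived parameterization.
* Predictions concern the TBP-binding component of expression only; in
  vivo, that component explains a minority of variance (the ~10% design
  point above), so an *insignificant* verdict is not evidence of no
  expression effect.
* The linear efficiency map is only valid below $F \approx 1.22$ with the
  default coefficients.
* Pairwise comparison mirrors a two-input interface; there is no batch
  VCF-style annotation.
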