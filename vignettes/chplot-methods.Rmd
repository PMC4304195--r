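---
title: "Charge-hydropathy classification and data-driven hydropathy scales: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-hydropathy classification and data-driven hydropathy scales: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chplot)
```

## The model

Intrinsically disordered proteins tend to combine high net charge with low
mean hydrophobicity, while folded proteins cluster at low charge and high
hydrophobicity. The charge-hydropathy (C-H) plot turns this into a
whole-protein binary classifier with two composition-level coordinates per
protein:

* **Mean hydropathy** $\langle H \rangle = \sum_{a} c_a \, s_a$, where $c_a$
  is the composition fraction of residue $a$ and $s$ is an amino-acid
  hydropathy scale, oriented hydrophobic-positive and rescaled to $[0, 1]$ by
  $(s - \min s) / (\max s - \min s)$. $\langle H \rangle \in [0, 1]$.
* **Absolute net charge**
  $\langle R \rangle = |n_R + n_K - n_E - n_D| / L \in [0, 1]$, counting Arg
  and Lys as $+1$, Glu and Asp as $-1$, histidine as neutral, over the
  effective length $L$ (canonical residues only).

A protein is called **disordered** iff its point lies strictly above a line
$\langle R \rangle = a \langle H \rangle + b$; points exactly on the line are
called ordered (ties resolve to the majority structured class, the
conservative call for a disorder predictor). Three scales ship with published
boundary lines:

```{r}
for (nm in builtin_scale_names())
  print(builtin_boundary(nm))
```

The signed quantity $\langle R \rangle - (a\langle H \rangle + b)$ is exposed
as `decision_score()` and doubles as the ROC ranking statistic.

## Deriving a scale from labelled sequences

`derive_scale()` learns a new 20-value hydropathy scale from a corpus of
proteins labelled disordered/ordered:

1. **Windowing.** Each protein is chopped into consecutive non-overlapping
   windows of 41 residues. A trailing remainder of at least half a window is
   kept as a final full-width window anchored at the sequence end (so every
   kept feature vector averages over the same length, at the price of some
   double-counted overlap); shorter remainders are discarded as too noisy.
   Sequences shorter than one window contribute themselves whole.
2. **Features.** Every window becomes 21 numbers: its 20 composition
   fractions plus its signed net charge $(n_R + n_K - n_E - n_D)/L$. The
   signed form is the default because the classifier can learn an asymmetric
   response to acidic versus basic excess; an `charge = "absolute"` variant
   is available for sensitivity analysis.
3. **Training.** A linear soft-margin SVM (`e1071::svm`, linear kernel, no
   internal feature scaling) is fitted with targets $-1$ for disordered and
   $+1$ for ordered windows. Class weights default to the inverse class
   count $w_c = 1/n_c$: each class then carries equal *total* slack penalty
   regardless of imbalance, and exact duplication of the training rows (with
   weights recomputed) provably leaves the solution unchanged — a property
   the test suite checks. The decision sign is normalized programmatically
   against the fitted model's own predictions so that positive decision
   values always mean ordered; consequently a negative learned weight is
   disorder-promoting.
4. **Cross-validation and averaging.** Folds are assigned at the *protein*
   level (all windows of a protein stay together, so held-out windows are
   never from proteins seen in training), balancing fold window totals by a
   greedy largest-first heuristic while guaranteeing both classes in every
   fold. The default is 10 folds repeated 5 times with re-drawn assignments;
   the derived scale is the mean of the first 20 weights over all 50 fold
   models, which damps fold-to-fold solver noise.
5. **Thresholding and metrics.** Within each fold the classification
   threshold on the disorder score (the negated decision value) is chosen to
   maximize the F-score on the *training* windows — a midpoint sweep over all
   distinct score gaps, preferring the higher threshold on ties — and applied
   unchanged to the held-out windows. The full imbalanced-data suite
   (accuracy, sensitivity, specificity, balanced accuracy, PPV, NPV, F, MCC,
   AUC) is reported per fold and pooled. Metrics whose denominator is zero
   (e.g. PPV with no positive calls) are reported as `NA` rather than
   silently coerced to 0, so degenerate folds are visible.
6. **Whole-protein boundary refit.** `refit_whole_protein_boundary()` (a
   special case of `benchmark_scale()`) orients and unit-normalizes the
   derived weights, maps every protein to its C-H point, and fits the
   two-feature linear boundary within a protein-level k-fold loop. The
   returned slope and intercept are per-fold means; the attached metric
   report scores each protein with the boundary of the fold that excluded
   it. The SVM weights $(w_H, w_R, b_0)$ convert to the explicit line via
   $a = -w_H/w_R$, $b = -b_0/w_R$; near-vertical fits
   ($|w_R| \le 10^{-12}$) are rejected rather than silently represented.

A small worked example (sizes kept small so the vignette builds quickly;
realistic corpora of a few hundred proteins per class give much tighter
estimates):

```{r}
corpus <- generate_corpus(n_disordered = 25, n_ordered = 25, seed = 7)
ds <- derive_scale(corpus$seqs, corpus$labels, k = 5, repeats = 2, seed = 1)
print(ds)
bd <- refit_whole_protein_boundary(ds, corpus$seqs, corpus$labels,
                                   k = 5, seed = 1)
print(bd)
attr(bd, "heldout")
```

```{r, fig.width = 6, fig.height = 4}
plot_ch(attr(bd, "points"), bd)
```

## The synthetic generator

`generate_corpus()` provides labelled corpora with a known planted structure,
the basis of the end-to-end tests. Per protein, a composition prior is built
in log-weight space: flat base log-weights, plus $s\,\beta\,u$ where $u$ is
the planted scale oriented, mean-centered and unit-normalized and $s = +1$
(ordered) or $-1$ (disordered), plus a disordered-only charge tilt ($+\gamma$
on Glu, $+\gamma/2$ on Lys, asymmetric so the net charge moves instead of
cancelling). The softmax of these log-weights is jittered by a
Dirichlet($\alpha \cdot p$) draw and residues are sampled i.i.d.; lengths are
uniform on 82–410 so every protein yields at least two windows.

The exponential-tilt design makes the planted direction the Bayes-optimal
linear discriminant in log-composition space, giving a principled recovery
target: at the default separation $\beta = 2$ the derivation pipeline
recovers the planted scale with $|r| > 0.9$, and at $\beta = 0$ there is no
signal to recover. The default charge tilt $\gamma = 1.25$ is calibrated
(analytically, from the class composition priors) so that the disordered
class's expected absolute net charge is about 0.10 while the ordered class
stays near zero — the elevated-charge geometry the C-H model presupposes.
With a much smaller tilt the two classes barely differ in
$\langle R \rangle$, the charge coordinate carries no signal, and the fitted
boundary's orientation becomes a coin flip. Limits worth stating: residues
are i.i.d. within a protein (no sequence order structure, which is fine
because every feature used is composition-level), the charge contrast is
planted through Glu/Lys enrichment only (real disordered proteomes also use
Asp, Arg, Ser/Pro context), and compositions are unimodal per class rather
than the heavy-tailed mixtures real proteomes show.

The two-feature boundary fit still needs a reasonable number of whole
proteins per fold to be stable — with only a handful of training points per
class the fitted slope varies strongly between folds. The package's own
tests use 40 + 40 proteins with 3–5 folds for boundary-level checks and
300 + 300 with 10 folds for recovery-level checks; these sizes are the
package's own choices, small enough to run in seconds-to-minutes yet large
enough that the tested properties sit decisively inside their statistical
margins.

## Numerical and design choices

* **Unit normalization** forces the minimum and maximum of a prepared scale
  to exactly 0 and 1 (not merely within floating-point error), so
  $\langle H \rangle$ bounds are exact and normalization is idempotent and
  invariant to positive affine transforms of the input scale.
* **Scale TSV round-trips** write values with 17 significant digits, enough
  for bit-exact read-back of doubles.
* **AUC** is computed by the rank-sum identity with half-credit for ties,
  and independently checked in the tests against exhaustive pair counting.
* **Pearson r** delegates to `stats::cor` but errors on constant input
  instead of propagating `NA`; in the AAindex-style correlation analysis a
  constant index is skipped with a warning.
* **Determinism.** All stochastic steps (fold assignment, corpus generation)
  run under a seeded local RNG that saves and restores the global
  `.Random.seed`, so library calls never perturb user-level random streams
  and identical seeds give bitwise-identical results.
* **Non-canonical residues** (B, J, O, U, X, Z) are skipped from both the
  numerator and denominator of composition by default (an `"error"` policy
  is available); above 10 % non-canonical content a warning flags likely
  malformed input, and a sequence with no canonical residues at all is an
  error.

## Comparing and correlating scales

`benchmark_scale()` ranks fixed scales by cross-validated boundary F-score on
a labelled corpus. `correlate_scale_vs_collection()` computes Pearson r
between one scale and each index of a TSV collection (20 residue columns plus
`id` and `cluster`), and `cluster_summary()` aggregates the correlations per
cluster — the standard way to situate a derived scale among published
hydropathy-like indices.

```{r}
pearson_r(get_builtin_scale("idp_hydropathy")$values,
          get_builtin_scale("kyte_doolittle")$values)
```
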