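# chplot

Whole-protein order/disorder classification by charge–hydropathy (C-H)
plots, and derivation of new amino-acid hydropathy scales from labelled
sequence corpora.

## The scientific problem

Intrinsically disordered proteins (IDPs) are functional proteins without a
stable fold. At the whole-protein level they are recognizable from
composition alone: disordered sequences combine **high net charge** with
**low mean hydrophobicity**, while folded proteins sit at low charge and
high hydrophobicity. The C-H plot formalizes this: each protein becomes a
point

* ⟨H⟩ — its composition-weighted mean hydropathy under a scale oriented
  hydrophobic-positive and normalized to [0, 1], and
* ⟨R⟩ — its absolute net charge |n(Arg) + n(Lys) − n(Glu) − n(Asp)| / length,

and a straight line ⟨R⟩ = a·⟨H⟩ + b separates the two classes: points
strictly above the line are called disordered.

The quality of that separation depends on the hydropathy scale. Besides the
classic Kyte–Doolittle and Guy scales (bundled, with their published
boundary lines), this package derives *new* scales from labelled corpora:
a class-weighted linear SVM is trained on 41-residue window compositions
(+ signed net charge, 21 features), inside a protein-level 10-fold
cross-validation repeated 5 times, and the averaged weight vector *is* the
scale — a negative weight marks a disorder-promoting residue. A bundled
`idp_hydropathy` scale of that type is included. Evaluation uses the full
imbalanced-data suite (sensitivity, specificity, balanced accuracy, PPV,
NPV, F-score, MCC, ROC AUC), and scales can be correlated against
collections of published amino-acid indices.

## Worked example

Classify sequences against a bundled scale and its published boundary:

```r
library(chplot)

seqs <- c(p53_like = strrep("MEEPQSDPSVEPPLSQETFSDLWKLLPEN", 3),
          folded   = strrep("MVLSEGEWQLVLHVWAKVEA", 4))
pts <- ch_points(seqs, get_builtin_scale("idp_hydropathy"))
pts$call <- classify_ch(pts, builtin_boundary("idp_hydropathy"))
pts
#>         id     H     R       call
#> 1 p53_like 0.277 0.207 disordered
#> 2   folded 0.438 0.100    ordered
```

Derive a scale from a labelled corpus (here synthetic, with a known planted
scale, so recovery can be checked), refit the whole-protein boundary and
read the held-out performance:

```r
co <- generate_corpus(n_disordered = 50, n_ordered = 50, seed = 7)
ds <- derive_scale(co$seqs, co$labels, k = 5, repeats = 2, seed = 1)
abs(pearson_r(ds$residue_weights,
              prepare_scale(planted_scale(co))$values))
#> [1] 0.919

bd <- refit_whole_protein_boundary(ds, co$seqs, co$labels, k = 5, seed = 1)
bd
#> C-H boundary: <charge> = 3.889 <hydropathy> - 1.827
#>   disordered iff R > a*H + b
attr(bd, "heldout")$balanced_acc
#> [1] 1
```

`derive_scale()` returns a classed object with `print()`, `summary()`,
`coef()`, `plot()` and `predict()` methods; `plot_ch()` draws the C-H
scatter with a boundary. A command-line interface
(`inst/cli/ch-plot.R`, subcommands `classify`, `benchmark`, `derive-scale`,
`correlate`, `simulate`) wraps the same functions with reproducible,
config-echoing output directories.

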