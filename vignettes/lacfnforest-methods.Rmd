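---
title: "Laminar cascading flexible neural forests: model and design notes"
author: "LACFNForest"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Laminar cascading flexible neural forests: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LACFNForest)
```

# The problem

Classifying cancer subtypes (or any multi-class phenotype) from bulk or
single-cell expression matrices is a small-n, large-d problem: a few hundred
samples against thousands of genes, with missing values and noise. Deep
networks overfit here, and their hyperparameters (layer sizes, learning
rates, kernel widths) have no principled defaults at this scale. The model
implemented in this package sidesteps both issues: its base learner is a
*flexible neural tree* (FNT) whose structure is searched rather than
specified, and its ensemble architecture is determined automatically from
validation accuracy.

# The model, bottom-up

## Flexible neural trees

An FNT is a tree-shaped neural network. Leaves are input features; every
internal node is a "flexible neuron" $+M$ computing

$$ y = \sigma\!\Big(\sum_{j=1}^{M} \omega_j I_j + \theta\Big), $$

over its $M$ children, with the logistic activation
$\sigma(x) = 1/(1+e^{-x})$ throughout (Gaussian and ReLU are available as
alternatives on the `activation` argument but are not used by the ensemble).
Evaluation runs bottom-up, leaf to root; the root output lies in $(0,1)$ and
is read as a soft binary decision. Because any feature may appear at any
depth, the grammar naturally produces sparse, cross-layer-connected
networks — a structural regularizer that is one reason the model resists
overfitting at small n.

Fitness of a tree on data $(X, y)$ is the root-mean-square error
$\mathrm{Fit} = \sqrt{\tfrac1N \sum_i (y_i - \hat y_i)^2}$; smaller is
better.

## Structure search and parameter tuning

Tree structures are evolved by grammar-guided genetic programming over the
minimal grammar *Node → +m(Node, …, Node)* for $m$ in the function set, or
*Node → x_i*. Defaults: population 50, crossover probability 0.4, mutation
probability 0.01, tournament selection of size 3 with one elite. The
grammar is named but not specified in the source model description; the
production rules above are the minimal ones generating the intended tree
shapes, which is why we adopt them. Selection, tournament size and elitism
likewise have no published values; tournament-3/elite-1 is a robust default
for small populations.

Weights and biases are tuned by global-best particle swarm optimization on
the flattened parameter vector, with learning factors $c_1 = c_2 = 2$ and
velocity clamp $v_{\max} = 2$; inertia 0.7, swarm 30, and the iteration
budgets are package defaults, and all parameters are clamped to $[-5, 5]$
(the bias bound is otherwise unstated). The two processes alternate: each
generation's best individual receives a PSO pass, and a longer final pass
polishes the returned tree. Whether every individual or only elites should
be tuned is an open choice; we tune elites only, trading some search power
for a much smaller evaluation budget. Termination is `maxGenerations` plus
a no-improvement patience of 10 generations.

## DFNForest: M-ary decomposition and cascading

A single FNT is binary. An $M$-class problem is decomposed into
$B = \lceil \log_2 M \rceil$ binary tasks: class $i$ receives the $B$-bit
binary code of $i-1$, and one FNT predicts each bit. Decoding maps a raw
output vector to the nearest *valid* code (Euclidean distance, ties to the
lowest class index) — the natural extension to non-power-of-two $M$, where
unused code words can never win.

Forests of $B$ trees are stacked into a cascade: level $\ell$ consumes the
original features augmented with the outputs of levels $1..\ell-1$ (width
$d + (\ell-1)B$). Depth is chosen automatically: a stratified 20% split is
held out, validation accuracy is recorded after each level, training stops
when it fails to strictly increase, and the model keeps the depth with the
best validation accuracy (cap: 8 levels). The held-out fraction is a
package default; the source description says only that the training set is
divided in two.

## The laminar ensemble

The full model stacks $N = 4$ layers of DFNForests, *widening* as it
deepens: layer $\ell$ holds $K + \ell - 1$ forests ($K = 3$), whose
grammars cycle through the four function sets
$F_1 = \{+2,+3,+4\}$, $F_2 = \{+2,+3,+5\}$, $F_3 = \{+2,+4,+5\}$,
$F_4 = \{+3,+4,+5\}$. The widening counts are a design choice: the
published account says the model broadens layer by layer without giving
numbers, and $K + \ell - 1$ is the minimal monotone schedule; a `constant`
mode (width $K$ everywhere) is provided for ablation. A layer's output is
the per-bit mean of its forests' outputs.

Three mechanisms connect the layers:

* **Confidence gating.** After each non-final layer, samples whose every
  bit output falls in $[0, 0.1] \cup [0.9, 1]$ exit with their prediction;
  the rest continue. After layer $N$ the rule collapses to a 0.5 threshold
  so everything is classified. The published worked example is scalar
  (one-bit); for $B > 1$ we require *every* bit inside the region — the
  strictest consistent generalization.
* **Dense augmentation.** Layer $\ell$'s input is
  $[X_0 \mid \bar{o}_1 \mid \dots \mid \bar{o}_{\ell-1}]$ — the base
  features plus the mean outputs of *all* prior layers, after the
  dense-block idea. Whether each layer should contribute $B$ columns (the
  layer mean) or $B \times$ width columns (one block per forest) is
  ambiguous in the source description; the mean is the default and
  `augmentPerForest = TRUE` provides the alternative.
* **Layer weighting.** The final output is
  $y_f = \sum_i \omega_i y_i$ with triangular weights
  $\omega_i = i / (1 + 2 + \dots + N)$ — $(0.1, 0.2, 0.3, 0.4)$ for
  $N = 4$. For a sample that exits early at layer $\ell$, the weights of
  the traversed prefix $1..\ell$ are renormalized to sum to one, which
  preserves convexity and reduces to the full rule when all layers are
  traversed. A sample exiting at layer 1 is therefore scored by layer 1
  alone.

Deeper layers train only on the samples still uncertain — they specialize
on the hard cases, which is why their weights are larger.

# Preprocessing

Expression matrices are preprocessed in three steps, in order:

1. **Sample filtering.** A sample with *strictly more than* 20% missing
   cells is removed; exactly 20% is retained.
2. **KNN imputation** ($k = 5$). A missing cell (sample $i$, gene $g$) is
   the mean of $g$ over the $k$ samples nearest to $i$ among those
   observing $g$. Distance is the RMS difference over mutually observed
   genes — scaling by the number of shared genes keeps samples with
   different missingness patterns comparable. $k$, unstated in the source,
   is the standard expression-imputation default, clamped to the available
   donors. Ties in distance resolve to the lower sample index
   (deterministic).
3. **Z-score normalization** per gene: $(f - E(f))/\sqrt{\mathrm{Var}(f)}$
   with the *population* variance (divide by $n$), matching the
   $\mathrm{Var}$ notation and making tests exact. Zero-variance genes are
   set to all zeros by default (stable dimensionality across CV folds);
   `drop_gene` removes them instead.

NA tokens recognized on input: empty cell, `NA`, `NaN`, `null`
(case-insensitive). The canonical orientation is samples-in-rows (natural
when $n \ll d$ and rows are the CV unit); genes-in-rows files are declared
with `orientation = "genes"`.

# The synthetic-data generator

`generateClassificationData()` emulates the regime the model targets:
continuous expression-like values, $d \gg n$, 3–4 classes, a minority of
informative genes, injected missingness. Each class receives a distinct
$\pm 1$ pattern over the informative genes, scaled by
`effectSize` (default 2.0) noise-SDs; all other genes are
$\mathcal{N}(0, \sigma^2)$ noise; the default missing rate is 2%. Gaussian
class-conditionals (rather than negative-binomial counts) are deliberate:
the classifier consumes z-scored values, so the generator models the
post-normalization scale; a `logNormal` mode produces positive skewed
values for exercising the preprocessing path. What the generator does *not*
emulate: gene–gene correlation, batch structure, class-imbalanced
missingness, or real subtype biology — so green tests certify the
machinery, not clinical performance.

# Numerical and degenerate-input choices

* Bit threshold: a raw output of exactly 0.5 decodes toward the
  higher-valued code (ties in code distance go to the lower class index).
* Degenerate bit columns (all 0/1 in a training split) train anyway, with
  a warning.
* If fewer than two classes remain uncertain at some layer, training
  continues without stratification (warning); if no samples — or fewer
  than 10, too few to train another tier — remain uncertain, the remaining
  layers are skipped and the last trained layer classifies everything at
  prediction time.
* Crossover points violating the depth/size bounds are resampled up to 10
  times, then the parents pass through unchanged. Random tree growth
  reserves child slots up front, so `maxNodes` is a hard bound.
* One master seed drives everything: top-level entry points seed the RNG
  once and all nested stochastic steps consume the stream, making training
  bit-reproducible. (Reseeding inside nested loops would clone trees.)
* Model files and tree records serialize doubles at 17 significant digits,
  so write→read round-trips reproduce predictions exactly.

# Problem sizes used by the test suite

The suite and the acceptance script run reduced budgets chosen to exercise
every mechanism while staying desk-scale: structure checks use
$n = 120, d = 20$ with population 20 and 10 generations; the end-to-end
five-fold CV uses $n = 200, d = 50$, 10 informative genes, effect size 2.0,
population 15, 8 generations, swarm 12, and cascades capped at 2 levels.
On such well-separated data the ensemble reaches macro-F1 well above 0.9;
published full-scale runs on TCGA expression data use population 50 and the
full cascade budgets, and are out of scope here (they require the external
data sets).

# Known limitations

* Training cost grows with $K$, $N$, cascade depth and the evolution
  budgets; the defaults are tuned for hundreds of samples and moderated
  gene counts after feature selection, not whole-transcriptome input.
* Gene selection (e.g. Fisher ratio / rough-set filters used upstream in
  some published pipelines) is intentionally out of scope; apply it before
  this package if $d$ is very large.
* The per-forest augmentation variant and the max-bit confidence variant
  are implemented but not default; neither is asserted to be the published
  intent (both readings are defensible).
* Baselines (KNN, SVM, RF, gcForest, …) are not reimplemented here;
  compare against their standard R implementations.
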