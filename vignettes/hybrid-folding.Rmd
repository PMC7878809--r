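---
title: "Hybrid thermodynamic–neural RNA secondary structure prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid thermodynamic–neural RNA secondary structure prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(hybridfold)
```

## The model

An RNA secondary structure $y$ on a sequence $x$ of length $L$ is a nested
set of base pairs $(i, j)$, $1 \le i < j \le L$. Under the nearest-neighbor
model every structure decomposes uniquely into loops — hairpins, base-pair
stackings, bulges, internal loops, multibranch loops and one external loop —
and both the free energy and any loop-decomposable score are sums over this
decomposition (`decompose_loops()`).

hybridfold scores a structure as

$$f(x, y) = f_T(x, y) + f_W(x, y),$$

where $f_T = -\Delta G(x, y)$ is the negated nearest-neighbor free energy
under a reduced Turner-style parameter table, and $f_W$ is the sum, over the
same loops, of four learned *folding scores* produced by a neural network:
helix stacking $s_{ij}$, helix opening $o_{ij}$, helix closing $c_{ij}$ and
unpaired region $u_{ab}$. A stacked pair closed by $(i,j)$ contributes
$s_{ij}$; a loop closed by $(i,j)$ contributes $c_{ij}$ plus $o_{k-1,l+1}$
for each inner branch $(k,l)$ plus unpaired-region terms. Because both
terms decompose over loops, the exact maximizer of $f$ over all
pseudoknot-free structures is found by Zuker-style dynamic programming
(`fold_max_score()`), in $O(L^3)$ time with internal loops capped at
`max_internal_span` unpaired bases.

```{r}
fold_max_score("GGGAAACCC")$structure
```

### Unpaired-region scoring: spans versus single bases

Unpaired runs inside hairpin, bulge and internal loops are scored with a
single span entry $u_{a,b}$, because those span lengths are bounded inside
the DP recursion. Unpaired bases in multibranch and external loops are
scored one base at a time with diagonal entries $u_{t,t}$: those runs are
extended base-by-base by the multibranch accumulators, and a span score
there would break loop decomposability (and with it the cubic DP). The
helix-opening score of an inner branch $(k, l)$ is read one position
outside the branch, at $(k-1, l+1)$, clamped to $[1, L]$ at the sequence
ends. Hairpins receive a closing score but no opening score.

## The thermodynamic parameter table

`turner_params()` loads a plain-text fixture
(`inst/extdata/turner_reduced.txt`) containing: the 6×6 canonical
stacking table, length-indexed initiations for hairpins (3–30), bulges
(1–30) and internal loops (2–30), terminal mismatches, an affine
multibranch model $a + b\cdot\text{branches} + c\cdot\text{unpaired}$, a
terminal AU/GU helix-end penalty, and a Jacobson–Stockmayer logarithmic
extension $\Delta G(n) = \Delta G(30) + 1.0786 \ln(n/30)$ for longer
loops. All values are kcal/mol. Watson–Crick stacking values and loop
initiations transcribe published Turner 2004 measurements; wobble-pair
stacks and terminal mismatches are a smooth synthetic completion (marked
as such in the fixture header), and the length tables are smoothed to be
monotone non-decreasing. Dangling ends, coaxial stacking and the special
small-internal-loop tables are deliberately omitted: the package targets
internal consistency between scoring, decoding and training rather than
numeric parity with any particular energy implementation (which its tests
never assert).

Reference structures from databases may contain non-canonical pairs that
the energy model cannot score. Prediction never proposes them, but
training must score references as given: in *lenient* mode
(`free_energy(..., lenient = TRUE)`, used internally by `ht_train()`) any
loop touching a non-canonical pair contributes zero free energy, so such
loops are scored by the network term alone.

## The network

`nn_forward()` maps a sequence to the four $L \times L$ score matrices: a trainable embedding of width $d$; $N_1$ residual
1D-convolution blocks (kernel sizes 5 then 3, layer normalization before a
CELU activation, dropout, a residual skip around each layer); $N_2$ BiLSTM
layers with $d/2$ hidden units per direction followed by layer norm, CELU
and dropout; a pairwise concatenation in which row $i$ of one half and row
$j$ of the other half form the feature of pair $(i, j)$; $N_3$ residual
2D-convolution blocks (kernels 5×5 then 3×3); and one shared 3-layer MLP
($d \to h \to h \to 4$) emitting $(s, o, c, u)$ per pair. The full-scale
configuration ($d = 64$, $N_1 = 4$, $N_2 = 2$, $N_3 = 4$, $h = 32$) has

```{r}
count_parameters(network_config())
```

parameters, within the ±15% band of the published 803k figure; the exact
"3-layer MLP" layout, normalization placement and residual granularity are
under-specified in the source description, so exact equality is not
expected. Design choices where the description was open: one shared MLP
head with four outputs (rather than four separate heads); layer
normalization after each convolutional/recurrent layer and before the
activation; zero-padding so $L$ is preserved; an embedding vocabulary
{A, C, G, U, N, PAD} with a learned vector for N. The final MLP layer is
zero-initialized, so an untrained hybrid model reproduces the pure
thermodynamic model exactly and training learns a correction on top — a
residual-learning initialization that also makes `--thermo-only` folding
the literal epoch-0 model. Forward and backward passes are hand-written
(Rcpp/Armadillo, im2col convolutions, BPTT through the LSTM) and verified
against finite differences in the test suite.

## Training

Given references $\{(x^{(k)}, y^{(k)})\}$, `ht_train()` minimizes

$$\sum_k \Big(\max_{\hat y}\big[f(x^{(k)},\hat y) + \Delta(y^{(k)},\hat y)\big]
 - f(x^{(k)}, y^{(k)})\Big) + C_1 \big[f_W(x^{(k)}, y^{(k)})\big]^2
 + C_2 \lVert \lambda \rVert_2,$$

with the margin $\Delta = \delta^{FN}\cdot\#\text{FN} +
\delta^{FP}\cdot\#\text{FP}$ counted over base pairs. The inner max is
solved exactly by loss-augmented decoding: each candidate pair gains
$+\delta^{FP}$ if absent from the reference and $-\delta^{FN}$ if present,
plus the constant $\delta^{FN}\lvert y \rvert$, so the augmented objective
stays loop-decomposable and the same DP applies. The argmax structure is
held fixed during backpropagation (the standard structured-SVM
subgradient). The thermodynamic regularizer $C_1 f_W^2$, evaluated on the
reference structure, anchors the hybrid score to the free energy scale —
without it the network may predict structures just as well while its
scores drift away from physical energies.

Defaults: $\delta^{FN} = 0.5$, $\delta^{FP} = 0.005$ (sensitivity-biased
margins), $C_1 = 0.125$, $C_2 = 0.01$. The $\ell_2$ term is implemented as
$C_2$ times the *norm* (not its square), following the objective as
printed, and applied once per mini-batch — a literal per-example placement
would scale it by the dataset size and change the meaning of the default
$C_2$. Optimizer hyperparameters are not part of the published method
description; the package defaults (Adam, learning rate 0.01,
batch size 4, 20 epochs, dropout 0.1 for desk-scale configurations) were
fixed from pilot convergence runs on the synthetic generator below.
The 50% dropout of the full-scale architecture is excessive for
16-channel desk-scale networks, where it leaves training
signal-starved within a 20-epoch budget; `network_config()` therefore
takes dropout as an explicit argument. Sequences longer than
`max_length` (default 500, the usual dataset practice) are skipped with a
warning.

## The synthetic generator

Real curated datasets cannot be redistributed here, so
`ht_generate_dataset()` provides a fully deterministic stand-in with
controllable structure. `sample_structure()` builds nested structures by
recursive pair-or-skip decisions with helix persistence 0.85 (expected
helix runs of several pairs, as in real RNAs), occasional bifurcation into
independent domains (multibranch/external diversity), and a deficit-driven
opening probability that self-corrects toward the target
`pairing_density`. `emit_sequence()` draws paired columns jointly from a
GC-biased canonical-pair distribution and then re-randomizes each position
with probability `mutation_rate`, emulating the non-canonical pairs and
annotation noise of real references. Defaults — 200 records, lengths
40–80, density 0.55, mutation rate 0.1, seed 0 — are the package's
desk-scale study conditions. Each record derives its own RNG substream
from `(seed, record index)`, so content does not depend on generation
order.

What the generator does *not* emulate: covariance structure within RNA
families, sequence homology, pseudoknots, and the length distribution of
natural ncRNAs. Passing tests on this generator demonstrates that the
estimator, decoder and trainer work as specified — not that the trained
desk-scale model transfers to biological data.

`generate_energy_triplets()` (mutation forced to 0) attaches the model's
own free energy to each record, giving a ground truth for energy-accuracy
metrics (RMSE and Spearman's $\rho$ between reference energies and negated
folding scores of predictions, `rmse_and_spearman()`).

## Numerical choices and degenerate inputs

* DP scores are plain doubles; traceback re-evaluates candidate
  expressions so exact floating equality identifies the chosen branch, and
  ties prefer pairing, then smaller $i$, then smaller $j$ — outputs are
  bit-reproducible. Oracle comparisons in the tests allow 1e-6 relative
  tolerance for summation-order differences.
* The empty structure is always feasible; its score is the sum of external
  unpaired terms (zero free energy).
* Sequences shorter than `min_hairpin + 2` fold to the empty structure.
* Crossing pairs in reference files are resolved to a maximum-cardinality
  nested subset by interval DP (ties: lexicographically smallest retained
  set), with a warning rather than an error, because real training data
  contains pseudoknots; how the original preprocesses such references is
  unstated, so this rule is the package's own choice.
* Hairpins shorter than 3 (possible when `min_hairpin` is lowered) clamp
  to the length-3 initiation; `N` residues never pair and contribute zero
  to mismatch terms.
* Layer normalization uses $\varepsilon = 10^{-5}$; dropout is inverted
  (evaluation mode is exactly deterministic); dropout masks are drawn from
  R's RNG so whole training runs are reproducible under one seed.

## Desk-scale problem sizes

The shipped tests and the acceptance script run entirely from the
synthetic generator at sizes chosen for a single CPU: DP–oracle
equivalence on 200 random instances with $L \le 15$; learnability with the
reduced network ($d = 16$, one block of each type, $h = 8$) on 200
records for 20 epochs with 50 held-out records; and the
thermodynamic-anchoring contrast with 60-record, 10-epoch training pairs
($C_1 = 0.125$ versus $C_1 = 0$, three seeds) evaluated on 100 energy
triplets. The full-scale configuration is exercised for shape and
parameter-count contracts only.

## Interface design

Batch operations are tabular: datasets, predictions and metrics flow as
tibbles (`ht_generate_dataset() |> ht_fold() |> ht_evaluate()`), and fits
follow broom conventions (`tidy()`, `glance()`, `autoplot()`), because
multi-sequence work is naturally one-row-per-record. The domain objects
themselves — sequences, structures, score matrices, parameter tables —
are classed values with their own constructors and validators, since a
nested pair set or an $L \times L$ score tensor is not usefully a data
frame. Single-object operations (`fold_max_score()`, `free_energy()`,
`decompose_loops()`) work on those values directly.

## Known limitations

* The reduced energy table omits dangles, coaxial stacks and special
  small-loop tables; absolute energies are Turner-like, not Turner-exact.
* Pseudoknots are outside the model class, in representation and in
  prediction.
* Desk-scale trained models are demonstrations on synthetic data; training
  on curated reference datasets is required for biological use.
* `strip_pseudoknots()` is exponential-safe only for the modest crossing
  counts seen in practice (interval DP over candidate pairs), and the
  enumeration oracle is guarded at $L \le 20$.
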