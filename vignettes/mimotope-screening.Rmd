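---
title: "Screening enhanced mimotopes with a free-energy surrogate and active learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening enhanced mimotopes with a free-energy surrogate and active learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A tumour neoantigen such as the p53 R175H 9-mer HMTEVVRHC is presented
by HLA-A\*02:01, but often binds weakly. Mimotope design asks: which
single-residue substitution binds the HLA *more strongly than the
original peptide*? That is a question about the sign and size of the
relative binding free energy

$$\Delta\Delta G = \Delta G_\text{mutant} - \Delta G_\text{original},$$

with $\Delta\Delta G < 0$ the positive (improved) class. Sequence-based
immunogenicity predictors are trained on binary presented/not-presented
labels and cannot resolve differences of a kcal/mol between close
analogues; alchemical free-energy perturbation (FEP) can, at hundreds
of nanoseconds of molecular dynamics per mutant. `mimoscan` implements
the strategy of coupling the two: a fast learned surrogate proposes,
a precise oracle disposes, and each precise result is folded back into
the surrogate.

## The model

Peptides are tokenized as amino-acid symbols plus a prepended
classification token (vocabulary size exactly 21). A transformer
encoder — embedding, fixed sinusoidal positional encoding, multi-head
self-attention blocks in the post-norm arrangement with a 4x
feed-forward expansion — produces a latent vector for the
classification token, which an affine head maps to a scalar binding
free energy $\Delta G$ in kcal/mol. The default architecture —
embedding dimension 32, four heads, one attention block — is the
working optimum for allele-specific 9-mer models: allele-specific data
are scarce enough that anything larger overfits before it helps.

Binary immunogenicity data enter through the Boltzmann-motivated link:
binding probability is `plogis(-(dG + b))` with a single learnable
threshold offset $b$ and unit slope. The slope is deliberately fixed:
binary labels identify the free-energy scale only up to a monotone
transformation, so the slope is not identifiable from them, and fixing
it keeps $\Delta G$ in interpretable units once free-energy data anchor
the scale during fine-tuning.

The encoder and its exact backpropagation are implemented in
RcppArmadillo (there is no deep-learning framework among this package's
dependencies); the test suite validates every gradient against central
finite differences, which is the strongest correctness oracle available
for hand-written backprop.

## Training

**Pretraining** minimises binary cross-entropy with Adam. Records are
assigned to five balanced folds; one fold is held out and training
stops when its AUC has not improved by more than `tolerance` (default
1e-3) for `patience` (default 10) epochs, keeping the best-AUC weights.
A single model with one held-out fold is trained rather than five
refits — the fold machinery exists so the validation set is a proper
partition element, and a full five-fold refit adds nothing to the
downstream loop while quintupling cost.

**Fine-tuning** mixes the large binary set with a small set of precise
free-energy observations through the dual loss

$$\mathcal{L} = \mathcal{L}_\text{BCE}(\text{binary}) +
  k \cdot \mathcal{L}_\text{MSE}(\text{free energy}),$$

where $k$ is self-adaptive: after each epoch it is raised to the
epoch-mean BCE/MSE ratio whenever that exceeds the current value,
clamped to $[10^{-4}, 1]$. $k$ therefore starts negligible (the model
first settles on the binary task) and rises monotonically as the MSE
term shrinks. Epoch-mean losses drive the update because per-batch
ratios are too noisy at these set sizes. Every gradient step includes
the full (small) free-energy set alongside one binary minibatch, and
learning rates decay geometrically (factor 0.5) per block moving
backwards from the output head — head first, encoder blocks in reverse,
embedding last — so precise data reshape the head more than the
pretrained representations. An optional cosine annealing schedule is
available but off by default; in our experiments it improved the final
MSE slightly without changing rank quality.

FEP-style oracles report differences $\Delta\Delta G$, but the head
regresses absolute $\Delta G$. Targets are therefore anchored:
`dG_target = dG_model(parent) + ddG`, with the parent prediction frozen
at the supplied (pretrained) state so targets do not drift between
epochs.

## Acquisition and the screening loop

Given predictions over all `19 x L` single mutants, three deterministic
election rules are provided:

* **DFS** (exploitation): the unsampled mutant with the most negative
  predicted $\Delta\Delta G$; ties break canonically (position, then
  substituted residue) so elections are reproducible.
* **BFS** (exploration): per position, the best-predicted unsampled
  substitution, kept only if its prediction is negative — candidates
  must align with the optimization direction, and positions with no
  improving substitution contribute nothing. "Recommended residue" is
  read as the per-position argmin, the only reading consistent with the
  optimization objective. One candidate per position is re-elected each
  iteration, for uniformity with the other strategies.
* **DFS+Bn**: the DFS candidate plus an X-scan of its substituted
  residue at positions within `n` of it. The neighbourhood is
  two-sided and clipped at the termini; with `n = 0` the rule reduces
  exactly to DFS.

The loop iterates predict → elect → oracle → fine-tune. Each iteration
fine-tunes *from the pretrained checkpoint* on the full cumulative
observation set, rather than incrementally updating the latest model:
the final state then depends only on which mutants were sampled, not on
the order, and drift cannot compound. The loop stops when an
oracle-confirmed observation reaches the objective threshold
($-RT\ln(\text{fold})$; about $-2.84$ kcal/mol for a 100-fold affinity
gain at 310 K), when the oracle budget is spent, or when the space is
exhausted. Objective confirmation requires an oracle observation, not
merely a prediction. A failing oracle call marks the mutant
unsampleable and the loop continues.

## The synthetic data generator

All tests and benchmarks run against a synthetic ground truth with the
statistical structure the method assumes:

* Site energies decompose as `mu[residue] + delta[position, residue]`
  (defaults: both components 0.7 kcal/mol sd). The shared residue
  component reflects that substitution effects are partially consistent
  across positions — hydrophobicity, charge, proline — and it is what
  makes positional scanning informative: without it, an X-scan of one
  residue could teach a model nothing about other positions, and no
  breadth-based strategy could pay off.
* Substitutions carry a systematic +1 kcal/mol penalty, so roughly a
  quarter of mutants improve binding — the parent is already a binder,
  and improving mutations are the exception, as in real deep
  mutational scans.
* Binary labels come from thresholding the additive extension of the
  same energies over random 9-mers (threshold auto-calibrated to the
  median, giving balanced classes), then flipping 5% of labels. The
  binary task and the free-energy task share one underlying
  $\Delta G$ — the structural premise that makes fine-tuning
  meaningful.
* The surrogate oracle adds Gaussian replicate noise of 0.5 kcal/mol
  (a typical FEP-scale error) and reports the mean and spread of three
  replicas. Draws depend only on (seed, mutant code), never on call
  order, so whole campaigns are reproducible.

What the generator does **not** emulate: real HLA binding motifs and
anchor-position chemistry, peptide-length variation, experimental
assay heterogeneity, and higher-order epistasis (pairwise couplings are
available but off by default). Passing benchmarks on this generator
therefore demonstrates that the machinery works under the method's own
assumptions, not that any particular real-data accuracy is attained.

## Problem sizes and numerical choices

Production defaults target database-scale binary sets (batch 1024,
learning rate 1e-4). The package's own tests and the acceptance script
run at desk scale on one CPU and use configurations chosen for that
regime: 600-20,000 binary records, batch 128-256, learning rate 1e-3
for pretraining and 2e-3 for fine-tuning, 2-300 fine-tune epochs
depending on the check, and a 20-seed benchmark with an oracle budget
of 12 per run. Larger learning rates at smaller batches reach the same
optima as the production settings in far fewer steps at these data
sizes; the strategy-contrast benchmark deliberately disables the
objective early-stop (fold increase set absurdly high) so that
precision/recall trajectories can be compared at matched oracle-call
counts across strategies, aligned by last-observation-carried-forward
and averaged over seeds.

Other numerical details: Adam (0.9/0.999, eps 1e-8); layer-norm epsilon
1e-5; Gaussian(0, 0.02) weight initialisation seeded from the
configuration; probabilities clamped to [1e-12, 1-1e-12] inside the
BCE; `update_k` leaves k unchanged when the MSE is exactly zero (the
degenerate perfect-fit case); checkpoints serialise to JSON at full
double precision.

## Known limitations

* The one-block, 32-dimensional encoder cannot represent the additive
  energy of a peptide exactly; on noiseless median-split binary tasks
  its validation AUC saturates near 0.95 (with a class margin it
  exceeds it). This is a property of the deliberately small
  architecture, not an optimisation failure.
* Desk-scale strategy contrasts are noisy: per-iteration fine-tunes on
  a handful of noisy observations move the global prediction surface
  stochastically, and that fine-tuning noise is of the same order as
  the difference between acquisition strategies at small oracle
  budgets. The benchmark harness therefore reports 20-seed averages at
  matched oracle-call counts, and the exploit-vs-explore
  precision/recall contrast should not be expected to resolve reliably
  below a few dozen oracle calls per run.
* Only single-site mutants are enumerated; multi-site mimotopes and
  TCR-recognition effects are out of scope.
* The FEP layer is bookkeeping only: manifests out, results in. No
  molecular dynamics is run or emulated beyond the noise model.
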