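---
title: "Probabilistic site-of-metabolism prediction from topological fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic site-of-metabolism prediction from topological fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cytochrome P450 enzymes initiate most phase-I biotransformations of drug-like
molecules. Knowing *where* on a substrate an isoform will attack — the site of
metabolism (SoM) — guides metabolite identification and early toxicity
assessment. somkit predicts SoMs from 2D structure alone: each candidate atom
is described by a topological circular fingerprint, and probabilistic
classifiers trained on molecules with experimentally assigned SoMs rank the
atoms of a query molecule by their probability of being a SoM.

```{r setup}
library(somkit)
```

## The descriptor

The fingerprint of an atomic site is a layered count vector. For bond depth
$d$ and an ordered alphabet of $A$ SYBYL atom types, position $(k, t)$ holds
the number of atoms of type $t$ at topological distance exactly $k$ from the
centre, $k = 0, \dots, d$, giving length $L = (d + 1)A$. The layout is
layer-major (all types at distance 0, then distance 1, ...). Distance is the
minimum number of bonds on any path, so the layer-0 block is a one-hot
encoding of the centre's own type and layer $k$ sums to the size of the
$k$-th distance shell. Hydrogens always contribute counts inside the layers;
whether they are *candidate* (rankable) sites is a separate switch, off by
default because curated CYP SoM sets assign hydrogen abstraction to the
attached heavy atom.

```{r}
mol <- som_molecule("ethanol-heavy",
  atoms = tibble::tibble(index = 1:3, sybyl_type = c("C.3", "C.3", "O.3")),
  bonds = tibble::tibble(from = c(1, 2), to = c(2, 3)))
circular_fingerprint(mol, 2, depth = 2, alphabet = c("C.3", "O.3"))
```

## The classifiers

All three estimate the class-conditional density $p(\mathbf{x} \mid
\omega_\alpha)$ of a fingerprint subvector for the two classes $\omega_0$
(SoM) and $\omega_1$ (non-SoM) and form the posterior with equal priors:
$p(\omega_\alpha \mid \mathbf{x}) = p(\mathbf{x} \mid \omega_\alpha) /
\sum_{\beta} p(\mathbf{x} \mid \omega_\beta)$.

* **Naive Bayes (NB).** Features are treated as independent; the per-feature
  probability is the value-match frequency with a pseudo-count correction,
  $(C_l + 1)/(N_\alpha + 2)$, where $C_l$ counts training vectors of the
  class whose feature $l$ equals the query's value. The correction keeps
  every factor strictly inside $(0, 1)$, so NB conditionals are never zero.
* **Parzen–Rosenblatt window (PRW).** A Gaussian kernel density estimate:
  the mean over the class's training vectors of
  $(h\sqrt{2\pi})^{-q} \exp(-\lVert \mathbf{x}_i - \mathbf{x}_k \rVert^2 / 2h^2)$.
  The bandwidth default is $h = 0.1$ *on the raw integer counts*, with no
  feature scaling — at integer spacing this makes the kernel sharply peaked,
  a soft exact-match with a distance-graded fallback.
* **RASCAL.** The same mean-kernel form with a Dirac kernel (1 only for an
  exact subvector match): the class-conditional is the exact-match fraction,
  turning classification into frequency-ratio data mining over subvectors.

### Numerical choices

A product of up to 175 per-feature probabilities underflows double precision,
so all conditionals live in the log domain and classes are compared by log
values; densities are exponentiated only for reporting. The PRW mean uses
log-sum-exp, so even very distant vectors retain a finite, ordered
conditional. When *both* Dirac conditionals are exactly zero (no training
subvector of either class matches) the posterior is undetermined: the
subclassifier contributes half a vote to each class, preserving the vote
total without biasing either class. An exact nonzero tie is broken by a
deterministic policy, "prefer non-SoM" by default — the conservative choice
for SoM calls — and is configurable.

## The ensemble

Sparse integer descriptors make single density estimates fragile, so each
classifier runs as a random-subspace ensemble: $j$ subclassifiers each see
$q$ of the $L$ features (drawn without replacement within a subclassifier,
independently across subclassifiers), and the SoM probability of a site is
the fraction of $\omega_0$ votes. Probabilities therefore live on the grid
$\{0, \tfrac{1}{2}, 1, \dots\}/j$. One subsample set is drawn per trained
ensemble and shared across all test sites; in cross-validation each fold
derives its seed deterministically from the master seed plus the fold index.
Defaults follow the method's published operating range: $j = 201$ (vote
fractions plateau well before that; the examples here use smaller $j$ for
speed), $q$ scanned from 5 to $L$ in steps of 5. For PRW and NB subsampling
brings no accuracy benefit, so `q = "full"` runs one subclassifier on all
features; RASCAL *requires* moderate $q$ — an exact match on a long subvector
almost never occurs across molecules, which is visible in `scan_q()` as an
MCC collapse towards 0 as $q \to L$.

## Evaluation protocol

`evaluate_som()` runs molecule-level leave-one-out cross-validation: every
site of the held-out molecule is excluded from training, so nothing about the
test molecule leaks into its own predictions. Reported metrics:

* **MCC** at the majority-vote operating point (site called SoM when more
  than half the votes say so; an exact half split is called non-SoM). A zero
  factor in the MCC denominator — e.g. everything predicted into one class —
  yields 0 by the usual convention.
* **ROC/AUC** pooled over all sites of all folds, sweeping thresholds over
  the achievable vote-fraction grid; the trapezoidal area equals the
  Mann–Whitney U statistic with half credit for ties.
* **top-k**: the percentage of molecules with at least one true SoM among the
  k highest-ranked predictions. Before ranking, symmetry-equivalent sites —
  atoms with identical whole-molecule fingerprints, computed at depth equal
  to the graph diameter so the fingerprint spans the entire ligand — are
  collapsed to a single entry represented by the lowest atom index; rank ties
  are broken by ascending representative index. Equivalent sites are retained
  as separate records in *training*, where they carry frequency information.

`similarity_split()` probes the applicability domain: a random 20% test set
(TS1), with its least-similar half (TS2) identified by each molecule's
maximum Tanimoto similarity to the training set over canonical linear-path
type strings up to four bonds — a deliberately simple whole-molecule
fingerprint adequate for ordering similarity.

## The synthetic corpus

Real curated CYP substrate sets are third-party supplementary data and ship
with neither this package nor its tests, so all development-time evidence
comes from `generate_corpus()`. It emulates the *structure* of the problem:
small connected typed graphs (uniform-attachment spanning tree plus a few
chords, degree capped at 4, 8–16 atoms), and a local-motif label mechanism —
one planted instance per molecule of a motif requiring an `N.3` at distance 1
and an `O.3` at distance 2 of an (unconstrained) centre; motif atoms are
SoM with probability 0.95, all others with probability 0.01. Those two rates
were fixed by design, before any evaluation: high enough fidelity that the
planted signal dominates the labels, with a little label noise so that
nothing is exactly separable. Leaving the centre type unconstrained keeps
the centres type-balanced: a depth-0 fingerprint (the centre's own type)
carries no label information, so depth-0 models must perform at chance, while
any model at depth ≥ 2 can in principle recover the rule — the
depth-dependence control. What the generator does *not* emulate: valence
chemistry, aromatic systems, realistic SYBYL type frequencies, correlated
SoM chemotypes, or class imbalance as extreme as real isoform sets. Passing
on synthetic data therefore demonstrates the machinery end to end, not
chemical accuracy on real substrates.

Problem sizes in the shipped checks were chosen to keep the full suite at
desk scale: 60-molecule corpora with $j = 51$ for the signal-recovery and
q-scan evaluations, 100-seed micro-corpora for equation-level oracle
comparisons, and 20 paired seeds for the permuted-label contrast.

## Known limitations

* Fingerprints and similarity are purely topological; stereochemistry,
  conjugation beyond SYBYL typing, and 3D accessibility are invisible.
* The alphabet is corpus-derived; a prediction-time type unseen in training
  raises an error rather than silently extending the feature space.
* An ensemble's vote grid quantises probabilities at $1/(2j)$; with small $j$,
  ranking ties are common and resolved by atom index.
* Disconnected mol2 entries (salts) are handled, but a fingerprint only sees
  the centre atom's component — counter-ions contribute nothing.
* Reported numbers on synthetic corpora are single-seed runs by default;
  subsampling makes them stochastic, and scans over seeds are the caller's
  responsibility.
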