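---
title: "protiso: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{protiso: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Why isoform-level inference is hard

Bottom-up proteomics detects peptides; proteins are inferred. Two sources of
technical noise dominate at isoform resolution. First, isoforms of a gene
share most of their sequence, so a typical detected peptide is compatible
with several isoforms and its abundance must be *allocated* among them.
Second, peptide identification is itself error-prone: each peptide carries a
posterior error probability (PEP) and a q-value (FDR) from the upstream
search engine. protiso treats both as part of the probability model rather
than as preprocessing.

## The model

With P analyzed isoforms, the sample's total protein abundance n is assumed
multinomial over isoforms,

$$X \mid \pi \sim \mathrm{MN}(\pi, n), \qquad \textstyle\sum_p \pi_p = 1,$$

but X is never observed — only peptide abundances $Y_i$ are. Inference
proceeds by data augmentation, alternating:

1. **Error indicators** (PEP mode only):
   $\varepsilon_i \sim \mathrm{Bern}(\mathrm{PEP}_i)$, drawn independently
   and anew each iteration. A peptide with $\varepsilon_i = 1$ contributes
   nothing that iteration, so detection uncertainty propagates into every
   posterior summary. In FDR mode $\varepsilon_i \equiv 0$ and unreliable
   peptides are removed up front instead.
2. **Allocation**: each retained peptide's abundance is spread over its
   compatible set $\psi_i$ by
   $\mathrm{MN}\!\big(\tilde\pi^{(i)},\, Y_i(1-\varepsilon_i)\big)$ with
   $\tilde\pi^{(i)}_p \propto (\pi_p / M_p)\,\mathbb{1}(p \in \psi_i)$.
   $M_p$, the number of detected peptides compatible with isoform p,
   normalizes for how many peptides feed each isoform's total. Summing
   allocations over peptides yields X, and
   $\sum_p X_p = \sum_i Y_i (1-\varepsilon_i)$ holds exactly at every
   iteration (the C++ core asserts it).
3. **Conjugate update**:
   $\pi \mid X \sim \mathrm{Dir}(x_1+\delta_1,\dots,x_P+\delta_P)$.

Only isoforms compatible with at least one detected peptide are analyzed
(the "trivial filter"); everything else is undetectable in the dataset at
hand, and the filter also guarantees $M_p \ge 1$.

A subtlety worth recording: steps 2 and 3 are the natural conditional
updates, but because the normalizing denominator of $\tilde\pi^{(i)}$
depends on $\pi$, they are not in general the conditionals of a single joint
density — the sampler is a pseudo-Gibbs chain with a well-defined stationary
law of its own. The test suite therefore validates the sampler against the
*exact stationary distribution of its transition kernel*, computed
independently on tiny instances: all latent allocation states are
enumerated, the transition matrix is obtained by Gauss–Legendre quadrature
of the allocation probabilities over the Dirichlet simplex, and the
stationary law is the eigenvector at eigenvalue 1. On instances where the
two updates are mutually consistent (all-unique peptides) the usual
conjugate closed form applies and is additionally checked by
Kolmogorov–Smirnov tests on the $\pi$ marginals.

## The transcript-informed prior

Without RNA-seq data the prior is weakly informative, $\delta_p = 1$. With
transcript abundances (TPM or similar), relative transcript abundances are
computed over the analyzed isoforms, floored by a small constant
$\epsilon = 10^{-5}$ (so isoforms without detected transcripts keep a
nonzero prior weight), renormalized to $\tilde\pi^T$, and scaled:

$$\delta_p = \tilde\pi^T_p \cdot c \cdot \textstyle\sum_{p'} X_{p'},
  \qquad c = 0.1 .$$

Thus $\sum_p \delta_p = 0.1 \sum_p X_p$: the proteomics data carry ten times
the weight of the mRNA prior. The total $\sum X$ in this formula is taken as
the total *observed* post-filter peptide abundance, fixed across iterations
— in PEP mode the retained total varies per iteration, and a prior that
moved with it would break conjugacy. The prior mainly improves the
allocation of shared peptides, which is why its benefit concentrates on
isoforms without unique peptides; `c` is exposed (`prior_strength_c`) for
sensitivity analyses over, say, 0–1.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `mode` | `"fdr"` | error handling: q-value filter vs. sampled indicators |
| `fdr_threshold` | 0.01 | q-value cut in FDR mode (inclusive boundary, so q = 0.01 passes) |
| `pep_mode_max_fdr` | 0.1 | weak filter in PEP mode; beyond it PEPs are near 1 and peptides carry almost no signal |
| `iterations`, `burn_in` | 2000, 1000 | chain length; increase for small credible-interval tail probabilities |
| `prior_strength_c` | 0.1 | prior pseudo-abundance per unit of observed abundance |
| `epsilon_mrna` | 1e-5 | zero-avoidance floor on transcript relative abundances |
| `kappa_fc` | 1.5e-6 | stabilizer in the protein-vs-transcript log2 fold change |
| `ci_level` | 0.95 | HPD credibility level |
| `threads` | 1 | block-level parallelism; never changes results |

## Numerical and implementation choices

* **Initialization**: $\pi$ is drawn from the prior $\mathrm{Dir}(\delta)$;
  any initialization is forgotten within burn-in. Update order within an
  iteration is $\varepsilon \to X \to \pi$.
* **Blocks**: isoforms are partitioned into connected components of the
  peptide–protein graph. Each block is sampled on an RNG stream derived
  from the master seed and the block index, so sequential and parallel
  execution are bit-identical. Rather than normalizing $\pi$ within blocks,
  each block draws the unnormalized Gamma variables of the Dirichlet; the
  allocation weights $\pi_p/M_p$ are scale-invariant ratios, and the global
  $\pi$ chain is recovered by normalizing the concatenated Gammas per
  iteration — exactly the global Dirichlet draw.
* **Intensities** are rounded half-away-from-zero, deterministically across
  platforms. Peptides rounding to 0 remain "detected" (they count toward
  the trivial filter and $M_p$) but allocate nothing.
* **$M_p$** is counted after the mode-specific filter: only peptides that
  enter the sampler contribute to multiplicity.
* **Degenerate allocation**: if every $\pi_p$ on $\psi_i$ underflows to 0,
  allocation falls back to uniform over $\psi_i$.
* **Multinomial draws** are exact integer draws even for very large Y,
  preserving the conservation identity; no normal approximation.
* **HPD intervals** use the shortest-sorted-window method: among windows of
  $\lceil \text{level}\cdot n\rceil$ consecutive order statistics, the
  narrowest (ties: smallest lower bound).
* **log2 fold change** is computed on the posterior mean of $\pi_p$,
  $\log_2\!\big((\bar\pi_p+\kappa)/(\pi^T_p+\kappa)\big)$, for consistency
  with the reported point estimate; $\Pr(\pi_p > \pi^T_p)$ uses the strict
  inequality (ties have probability zero for continuous draws).
* **Gene aggregation** sums member isoforms within each iteration before
  summarizing, so gene intervals reflect within-gene posterior correlation;
  a gene's mean equals the sum of its isoforms' means by linearity.
* Peptides referencing a protein id absent from the declared search
  database raise an error rather than being silently dropped — that
  situation indicates upstream inconsistency, not ignorable data.

## What the synthetic-data generator does and does not emulate

`simulate_dataset()` provides a ground-truthed test bed: log-normal true
isoform abundances (meanlog 1.5, sdlog 1 — mean abundance of present
isoforms around 8, matching the scale of deep PSM-count datasets) with a
configurable absent fraction (default 0.25); genes of 1–4 isoforms; each
isoform owning 1 + Poisson(2) peptides. Sharing is calibrated so that about
47% of abundance mass lands on shared peptides, split 85/15 between within-
and between-gene sharing — the sharing profile of deep multi-protease
searches. True abundance is allocated to each isoform's compatible peptides
by an equal-probability multinomial, so peptide totals conserve protein
totals exactly. Transcript tables are generated to a target log10 Pearson
correlation with the truth (default 0.65). Synthetic PEP/FDR scores (Beta
PEPs near 0 for true peptides, optional decoys near 1, q-values as running
means of sorted PEPs) exist purely so the PEP mode can be exercised without
a search engine.

Not emulated: peptide detectability differences, missing peptides, protease
digestion chemistry, retention time or charge states, intensity-dependent
noise, or database incompleteness. Equal-probability allocation to peptides
also differs mildly from the model's $\pi/M$-weighted allocation, which
makes recovery metrics conservative rather than circular. Passing tests
therefore demonstrate correct inference under controlled sharing and error
structure — not performance guarantees on any particular real dataset.

## Problem sizes used in the checks

Calibration runs use five simulated datasets of 1000 isoforms with the
default 2000/1000 chain; the prior-benefit comparison uses ten replicates of
500 isoforms with a 1000/500 chain; oracle comparisons use instances of at
most 3 peptides and total abundance 6, where exhaustive enumeration is
exact. These sizes give stable metrics (coverage and AUC move by well under
a point between seeds) while keeping the whole suite fast.

## Known limitations

* Single-sample model: no hierarchical sharing across biological
  replicates, hence no differential testing across conditions.
* PEP mode costs several times the FDR mode's runtime on large datasets,
  since every peptide is revisited each iteration.
* Presence probabilities are reported raw, per isoform; no multiplicity
  control across isoforms is applied.
* The error indicators are drawn from the upstream PEPs as given; poorly
  calibrated search-engine PEPs propagate directly into presence estimates.
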