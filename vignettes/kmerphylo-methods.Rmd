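---
title: "Alignment-free phylogenies from k-mer presence/absence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free phylogenies from k-mer presence/absence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kmerphylo)
```

## The problem

Alignment-based phylogenetics needs homologous sites, which whole genomes —
rearranged, partially assembled, or only skimmed — rarely provide. A family
of alignment-free methods instead summarizes each genome by its k-mer
content. Most of those methods reduce k-mer content to pairwise distances
and build a tree with a distance method. `kmerphylo` follows the
model-based alternative: it treats the *presence or absence* of each k-mer
across taxa as one binary character and estimates the tree by maximum
likelihood under an explicit substitution model, keeping the statistical
machinery (likelihoods, bootstrap support) that distance methods give up.

The pipeline has four stages:

1. **k-mer sets.** Every taxon's genome (one FASTA file, possibly many
   contigs) is reduced to its set of distinct k-mers. By default a k-mer
   and its reverse complement are identified (*canonical* counting),
   because an assembled sequence may represent either strand. Counting is
   presence-only: multiplicities are discarded. Windows containing
   ambiguity codes are skipped, and windows never span contig junctions.
2. **Binary matrix.** For each odd k in a grid (default 9–31) the union of
   observed k-mers defines matrix rows; `X[i, j] = 1` iff k-mer *i* occurs
   in taxon *j*. Rows are ordered by the k-mer's 2-bit integer code, so
   matrices are bit-reproducible.
3. **k selection by entropy.** Each matrix is scored by the cumulative
   Shannon entropy of q sampled rows (below); the k with the highest score
   — `k_entropy` — is carried forward.
4. **Tree estimation.** The selected matrix is analysed under a two-state
   substitution model with gamma rate heterogeneity: Felsenstein-pruning
   likelihood, branch-length and shape optimization, NNI topology search
   from a neighbor-joining start, and optionally a nonparametric bootstrap
   with majority-rule consensus.

## Choosing k: cumulative entropy

A k-mer present in (almost) every taxon, or in only one, says little about
relationships; rows with intermediate presence frequencies are the
informative ones. For a row $r$ observed across $m$ taxa with empirical
state frequencies $p_r(x)$, $x \in \{0, 1\}$, the row entropy is
$-\sum_x p_r(x)\log p_r(x)$. The matrix score is the sum over $q$ rows
sampled uniformly without replacement,

$$C^{\mathrm{entropy}} = -\sum_{i=1}^{q} \sum_{x\in\{0,1\}}
  p_{r_i}(x)\, \log p_{r_i}(x),$$

and `k_entropy` is the k maximizing it. Numerical conventions:

* **Logarithm base.** Natural log. The only downstream use of the score is
  the argmax over k, which any base change rescales uniformly (this
  invariance is tested).
* **$0 \log 0 = 0$** — the standard entropy convention; constant rows
  score 0.
* **Sampling.** `q = 5000` rows by default, drawn as the prefix of a
  seeded shuffle (default seed 42). The prefix construction means
  enlarging q under the same seed only adds non-negative terms, and a
  matrix with at most q rows is scored exhaustively and
  seed-independently. Sampling is drawn independently per k.
* **Degenerate k values.** A matrix that is all ones (every k-mer in every
  taxon — typical when k is small relative to the genome) has zero entropy
  and is recorded as degenerate and skipped rather than aborting the run;
  similarly for matrix-build failures. The run fails only if no k is
  usable.
* **Ties** break toward the smallest (cheapest) k.

## The substitution model

Each matrix row is one independent binary character evolving on the tree
under a reversible two-state continuous-time Markov chain with stationary
frequencies $(\pi_0, \pi_1)$. With $\beta = 1/(2\pi_0\pi_1)$ the chain is
normalized to one expected substitution per unit branch length, and the
transition probabilities over a branch of length $t$ at rate multiplier
$r$ have the closed form

$$P_{00} = \pi_0 + \pi_1 e^{-\beta r t}, \qquad
  P_{01} = \pi_1 (1 - e^{-\beta r t}),$$

and symmetrically for state 1. Rate heterogeneity across sites follows a
mean-1 gamma distribution with shape $\alpha$, discretized into `ncat = 4`
equal-probability categories represented by their conditional means
(computed in closed form from the incomplete-gamma identity, so the
weighted mean is exactly 1). Note the discretization is exact but the
limit $\alpha \to \infty$ approaches all-equal rates only at rate
$\approx 1.271/\sqrt{\alpha}$ in the outer categories — at $\alpha = 10^6$
the extreme rates still deviate from 1 by $1.27\times 10^{-3}$.

Estimation choices:

* $\pi$ is set to the empirical frequency of 1s in the matrix, not
  ML-estimated: deterministic, standard for binary models, and removes one
  optimization dimension.
* $\alpha$ is optimized by bounded Brent search on $[0.02, 100]$,
  alternated with branch-length sweeps until the joint improvement falls
  below $10^{-6}$ log-units (at most 10 alternations; in practice 2–4).
  An all-constant matrix leaves $\alpha$ unidentifiable: it is fixed at 1
  with a warning.
* No ascertainment-bias correction is applied for the unobservable
  all-zero row. The matrix is built as the union of observed k-mers, so
  the all-zero pattern cannot occur; correcting for it is a known
  refinement that the presence/absence formulation here deliberately
  omits, matching the method's original formulation.

## Likelihood, optimization and search

Site likelihoods come from Felsenstein pruning over the two states,
mixed over rate categories, with the root marginalized against
$(\pi_0, \pi_1)$; time reversibility makes the root placement irrelevant
(tested). Identical rows are collapsed to unique site patterns with
integer weights — with $m$ taxa there are at most $2^m$ patterns, so even
multi-hundred-thousand-row matrices reduce to at most 1024 patterns for 10
taxa; the collapsed log-likelihood is mathematically identical to the
uncollapsed sum (tested). The pattern kernel is implemented in C++.

Branch lengths are optimized by coordinate ascent: one bounded Brent
search per branch on $\log t$, $t \in [10^{-8}, 100]$, sweeping all
branches until the sweep improves the log-likelihood by less than the
tolerance. Each branch's one-dimensional profile is evaluated through
inside/outside partial vectors, so a candidate length costs O(patterns)
rather than a full tree traversal. A final pair of fine-tolerance sweeps
(Brent tolerance $10^{-7}$ on $\log t$) polishes the returned lengths; a
branch whose profile is maximized at the lower bound is snapped to it,
so identical taxa are joined by the minimum length rather than a rounded
Brent endpoint.

The topology search is NNI hill climbing from the neighbor-joining tree on
normalized Hamming distances (negative NJ branch lengths clamped to the
lower bound). Both NNI rearrangements of every internal edge are scored
with one or two cheap branch-length sweeps; the best candidate is fully
re-optimized and accepted if it improves the log-likelihood by more than
$10^{-6}$. Accepted moves therefore form a strictly increasing
log-likelihood trajectory, and the search is deterministic: no random
restarts, ties resolve to the incumbent. Hill climbing over NNI moves is a
deliberate trade — adequate and fast at the package's design scale of at
most ~30 taxa, but it can stop in local optima on larger or
low-signal problems where SPR-based searches would do better.

Branch lengths are reported but should be read with caution: adjacent
k-mers overlap on the genome, so a single nucleotide substitution creates
and destroys up to k characters at once. The characters are therefore not
independent in the way the model assumes, which inflates apparent change;
the topology is the supported output.

## Bootstrap and consensus

Support values come from a standard nonparametric bootstrap: each
replicate resamples matrix rows with replacement (seeded), re-fits the
model and re-runs the search from the replicate's own NJ tree. Two
summaries are produced: the strict majority-rule consensus (splits in
>50% of replicates — a split at exactly 50% is excluded — labelled with
their percentages) and the full-data ML tree annotated with each internal
edge's replicate frequency.

## The simulators, and what passing tests show

Three generators provide ground truth without any external data:

* `random_tree()` grows a topology by sequential random leaf attachment
  with branch lengths uniform on $[0.02, 0.4]$ substitutions/site by
  default — a simple, roughly uniform tree prior that is adequate for
  recovery testing, not a birth–death model.
* `simulate_binary_matrix()` draws characters exactly under the two-state
  + gamma model. Tests built on it (e.g. 8-taxon, 2000-site recovery with
  internal branches ≥ 0.05) validate the ML engine under its own
  assumptions.
* `simulate_dna()` evolves an i.i.d.-uniform root sequence under a
  single-rate uniform 4-state chain (substitution probability
  $\tfrac34(1 - e^{-4t/3})$ per branch). It exercises the whole pipeline,
  including the model misspecification inherent in deriving overlapping
  k-mer characters from point substitutions.

The end-to-end validation simulates 10 taxa × 50 kb at shallow,
strain-to-congener divergence (branch lengths uniform on $[0.02, 0.15]$).
The scale matters: k-mer presence/absence is a shallow-divergence signal.
On deep trees (total paths beyond ~1 substitution/site) the probability
that a k-mer survives a path decays like $e^{-O(kt)}$, deep splits
saturate, and their placements become likelihood-flat — the method's
documented failure mode on distant species, observable here as interior
branch estimates pinned at the bounds. Within the shallow regime the
pipeline recovers the generating topology in the large majority of
replicates, and the entropy rule picks a k on the matching plateau.

A related limitation deserves emphasis. When the genome is short relative
to the k-mer space — tens of kilobases against $4^9/2 \approx 131{,}000$
canonical 9-mers — a substantial fraction of all possible k-mers occurs in
every genome *by chance*, and the matrix picks up many rows whose presence
pattern is essentially independent noise. Because the model is applied
without an ascertainment correction for the unobservable all-zero row,
such noise-heavy matrices can give an "all taxa are independent draws from
stationarity" fit — every branch saturated — a likelihood competitive
with, and sometimes exceeding, the structured tree's. In that regime the
maximum-likelihood tree is not meaningful no matter how good the search
is. Practical guidance: work at k where the per-genome density of the
k-mer space is low (real genomes are either small enough that k = 9 is
sparse, like organelles, or large enough that the entropy rule selects a
much longer k), and treat bootstrap supports as the diagnostic — in the
degenerate regime they collapse.

What passing these tests does **not** show: robustness to real-genome
features the simulators omit — repeats and low-complexity sequence
(which make k-mer presence non-independent in structured ways), indels,
rearrangements (canonical counting absorbs inversions except at their
breakpoints, which the inversion test demonstrates), horizontal transfer,
assembly gaps and sequencing error. FASTQ/read input is out of scope.

## Reproducibility

Every stochastic step — entropy row sampling, simulators, bootstrap
resampling — takes an explicit seed (default 42) and restores the caller's
RNG state. Matrix rows, PHYLIP exports and the JSON run report are fully
ordered, so identical configuration + seed gives byte-identical artifacts;
this is asserted by test. `run_pipeline()` caches per-k matrices on disk
(matrix construction dominates runtime) and logs every default it actually
used: q, seeds, tie-breaks, and skipped k values with reasons.
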