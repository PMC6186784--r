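---
title: "Mapping endoribonuclease cleavage motifs from coverage profiles and ranking transcripts by motif burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping endoribonuclease cleavage motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazfscan)
```

## The problem

MazF-family toxin endoribonucleases cleave single-stranded RNA at short
specific motifs (three to seven bases). Determining that motif, and then
predicting which transcripts a given enzyme will degrade fastest, are the
two computations this package implements.

The experimental signal comes from 5'-end-enriched sequencing of digested
RNA: every cleavage event creates a fragment whose 5' end sits exactly at
the cut, so when reads are mapped back to the reference, coverage jumps at
true cleavage boundaries. The motif is recovered from the sequence context
of the strongest jumps; transcript susceptibility is then scored by asking
how surprising each coding sequence's motif count is under its own base
composition.

## Cleavage-site detection: the RCI statistic

For a reference of length $L$ with per-position coverage $c_0, \dots,
c_{L-1}$, the relative coverage increase at boundary position $n$ (0-based,
$1 \le n \le L-1$) is

$$\mathrm{RCI}(n) = \frac{c_n}{c_{n-1}},$$

with zero coverage on either side replaced by a pseudo-count before the
ratio is taken, so every value is finite and positive. A sharp RCI spike
marks a fragment 5' boundary.

Detection proceeds in three steps, each with a tunable in
`detection_params()`:

* **Coverage floor** (`min_coverage`, default 100 reads). Boundaries whose
  downstream (coverage-increase) position carries raw coverage below the
  floor are excluded: a spike supported by a handful of reads is noise.
  The floor is applied to the *downstream* position by default because
  coverage upstream of a genuine cut is legitimately low; `coverage_filter`
  can move it to the upstream position or both.
* **Top-k pooling** (`top_k`, default 50). Eligible boundaries from all
  references are pooled and the 50 largest RCI values kept. Only genuine
  increases (RCI > 1) qualify: a flat or falling boundary marks no fragment
  end, which also guarantees that an idealised two-plateau step profile
  yields exactly one candidate, at the step, with RCI equal to the plateau
  ratio. Ties are broken deterministically (RCI descending, downstream
  coverage descending, reference id ascending, position ascending); the
  ordering is a package convention chosen for reproducibility.
* **Window extraction** (`flank`, default 5). The $2\cdot\mathrm{flank}+1 =
  11$ bases centred on each candidate are extracted and aligned; positions
  falling outside the reference are padded with `N` rather than discarded,
  so the candidate count is preserved, and `N`s are excluded from all
  downstream frequency counts.

The pseudo-count (`pseudo_count`, default 1) is the conventional minimal
choice. Its value never affects which candidates are reported: a boundary
whose coverage needed the substitution cannot pass the coverage floor.

## Consensus calling

Aligned windows are tallied into a $4 \times 11$ frequency matrix with
column labels $-5..+5$; label 0 is the coverage-increase nucleotide, and
the cleavage boundary sits 5' of it (for a UGG cutter, between the U at
$-1$ and the first G at 0). Per-column information content is

$$IC_j = 2 - H_j, \qquad H_j = -\sum_b f_{bj}\log_2 f_{bj},$$

so 2 bits is perfect conservation and 0 bits a uniform column. A column is
called as base $b$ when $f_{bj} \ge$ `min_frequency` (default 0.5) *and*
$IC_j \ge$ `min_ic` (default 1 bit); everything else renders `N`. Logo
tools visualise these frequencies but call nothing; the thresholds are
introduced here so the motif is a testable string rather than a picture.
Both defaults are deliberately conservative: a majority base in a column
carrying at least half the maximum information. An optional small-sample
correction ($3/(2\ln 2\, n)$, subtracted and floored at 0) is available
for parity with logo software; with ~50 windows it is minor and defaults
off.

```{r consensus-demo}
sim <- simulate_cleavage_experiment(sim_config(seed = 7))
cand <- detect_cleavage_sites(sim$references, sim$profiles)
call_consensus(build_frequency_matrix(cand), alphabet = "RNA")$consensus
```

## Motif burden: the (p, E, K, P) statistic

For each coding sequence of length $L$, with motif length $m$ (trials
$n = L - m + 1$; $L-2$ for a triplet):

* $p$ — probability of the motif at any position under the sequence's own
  base composition: the product over motif letters of that letter's
  frequency (for TGG, $f_T f_G^2$). Composition is per-gene, not
  genome-wide: genes of identical length can carry different expected
  counts precisely because their compositions differ. "U frequency" is
  read as the T frequency of the coding-strand DNA.
* $E = p\,(L-2)$ — expected motif count.
* $K$ — observed overlapping count on the coding strand (windows
  containing `N` never match; `N`s are likewise excluded from composition
  tallies).
* $P = \Pr(X \ge K)$, $X \sim \mathrm{Binomial}(L-2,\,p)$ — the upper-tail
  probability that composition alone produces at least the observed count.

Small $P$ flags transcripts carrying far more cleavage sites than their
composition predicts — the predicted prime targets. Ranking is by raw $P$
ascending (ties: $K$ descending, then id ascending); no multiple-testing
correction is applied because the statistic is used as a ranking score,
not a hypothesis test.

`binomial_tail()` sums the binomial mass directly in log space
(log-sum-exp over `lchoose` terms), which keeps tails down to $10^{-15}$
accurate; the test suite cross-checks it against the regularized
incomplete-beta route to $10^{-9}$ relative error. `burden_from_params()`
replays published per-gene summary rows — recovering $p = E/(L-2)$ from a
printed table — without needing the underlying sequences, which sidesteps
annotation-version questions such as whether a printed length includes the
stop codon.

```{r burden-demo}
burden_from_params(1713, 23.91, 52)   # hydroxylamine oxidoreductase row
```

## What the simulator emulates — and what it does not

`simulate_cleavage_experiment()` stands in for the bench experiment: eight
uniform-composition references of 500–2000 nt are digested by a
motif-specific enzyme and sequenced from fragment 5' ends. Per-position
5'-end counts are independent Poisson draws — mean
`signal_rate * cleavage_probability` (default $500 \times 0.9$) at true
sites, `background_rate` (default 2) elsewhere, plus `Poisson(signal_rate)`
intact-molecule ends at position 0 — and read depth is the end-count
vector convolved with a `read_length` (default 150) box, truncated at the
reference end. The defaults are chosen so that background depth
(~`background_rate * read_length` = 300) clears the coverage floor while a
true site roughly doubles it, a regime comparable to a small bench-scale
sequencing run.

Every motif occurrence in a generated reference is recorded as a
ground-truth site at the motif's second base (the first G of UGG), the
same boundary convention the detector reports, and a round-trip test
enforces the agreement. Uniform 500–2000 nt sequences carry $\approx L/64$
spontaneous motif occurrences (8–30 per reference), so no extra planting
is needed to emulate natural-composition substrates. The intact-end mass
at position 0 deliberately reproduces the reference-start coverage jump
seen in real mappings; position 0 has no boundary and can never become a
candidate.

The model summarises reads as independent Poisson end counts: it has no
sequencing errors, no mapping ambiguity, no barcode or adapter artefacts,
no fragment-length distribution, and no inter-site dependence (a molecule
cut twice is two independent events here). Passing tests therefore show
that the statistics recover signal of the shape the experiment produces,
not that the pipeline is robust to every artefact of real libraries.
`generate_cds_set()` similarly plants motif insertions into uniform
sequences; real CDS have codon structure and skewed composition that it
does not model.

## Numerical and design choices

* Coordinates are 0-based with half-open intervals throughout; the
  coverage-increase nucleotide is window centre index `flank` (label 0).
* Storage alphabet is DNA (`U` mapped to `T` on input); RNA appears only
  at presentation, so the burden scan (TGG in CDS) and the consensus
  report (UGG) share one bookkeeping.
* Coverage TSV is sparse with default 0, keeping simulator output small.
* Column probabilities are exact ratios of integer counts; normalisation
  is asserted to $10^{-12}$.
* Degenerate inputs: profiles shorter than 2 positions, empty window sets,
  zero-ACGT sequences and out-of-range table positions are rejected with
  named errors; $K = 0$ gives $P = 1$ exactly.
* Every stochastic routine runs under a private seeded RNG stream and
  restores the caller's state; identical config and seed give
  byte-identical output files.

Problem sizes used by the checked examples — 8 references of 500–2000 nt,
50 windows, 500-record CDS sets, binomial grids up to $n = 200$ with
published rows up to $n = 9193$ — keep every analysis under a minute on a
single core while leaving the statistics well inside their asymptotic
regimes.

## Known limitations

* The coverage floor's placement (downstream position) is an
  interpretation; the alternative placements are exposed via
  `coverage_filter` but change which marginal boundaries survive.
* Consensus-call thresholds are conventions; a motif with a weakly
  conserved flank would need `min_ic` lowered.
* The burden null model is zeroth-order (independent bases); codon-aware
  or dinucleotide nulls would sharpen $P$ for real CDS but are out of
  scope.
* Tie order among CDS with identical $(P, K)$ is deterministic
  (id-ascending) but arbitrary.
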