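---
title: "Profile HMM-HMM alignment with hydrophobicity and secondary structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile HMM-HMM alignment with hydrophobicity and secondary structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alignhush)
```

## The problem

Remote homology — common ancestry between protein families whose sequences
have diverged beyond recognisable pairwise similarity — is most sensitively
detected by comparing family *profiles* rather than individual sequences.
`alignhush` aligns two profile hidden Markov models (the plan7 architecture
used by HMMER2, with per-node match, insert and delete states) directly
against each other. Beyond per-column residue conservation it scores two
sequence-derivable correlates of structure: the predicted secondary
structure of the underlying alignment columns and their hydrophobicity,
each summed over a short window of adjacent columns. The windowing reflects
the observation that conservation in homologous proteins comes in stretches,
so neighbouring column pairs reinforce a true match while averaging out in a
spurious one.

## Profile re-encoding

A plan7 model stores integer scores `s = 1000 * log2(p / p_null)`. The
reader recovers probabilities (`scores_to_probs()`), discards the insert
emission line — only the *probability* of an insertion matters for
profile-profile alignment, not its composition — renormalises the match
emissions, and stores per match state:

* `e(a) = p(a) / sqrt(b_a)`, the emission odds against the square root of
  the background. The conservation score of two columns,
  `log2(sum_a P(a) Q(a) / b_a)`, then reduces to the log of a plain dot
  product of stored vectors.
* the column hydrophobicity `H = sum_a p(a) * kd(a)` (Kyte–Doolittle
  units, positive = hydrophobic),
* a 3-vector of secondary-structure frequencies over helix/sheet/loop,
  obtained by counting PSIPRED-style 3-state predictions of the aligned
  sequences per match column (confidences ignored, `H`→helix, `E`→sheet,
  anything else→loop). Profiles without predictions carry a uniform
  placeholder flagged *unannotated*, which switches the SS term off rather
  than letting an uninformative vector bias scores.
* the seven plan7 transition probabilities, whose logs become
  position-specific gap penalties.

The background distribution comes from the model's NULE line (renormalised),
falling back to uniform (1/20) when absent. Transition triplets are clamped
to [0, 1] and renormalised after integer-score conversion so that log
transition terms are always penalties. All log terms in the package are base
2 and floored at −50 in place of −∞, so sentinel ("impossible") scores in
real files disable a move without producing non-finite arithmetic.

## Column match score

For column pair (i, j) of profiles P (length n) and Q (length m):

```
M(i,j) = Wc * sum_{k=-wc..wc} S_cons(i+k, j+k)
       + Wh * sum_{k=-wh..wh} S_hyd(i+k, j+k)
       + Ws * sum_{k=-ws..ws} S_ss(i+k, j+k)
```

with windows truncated at profile ends (offsets that run off either profile
contribute nothing; truncation is the only scheme that never invents
columns). The terms are

* conservation: `S_cons = log2(e_P(i) . e_Q(j))`, 0 bits when both columns
  equal the background, `log2(1/b_a)` for identical point masses;
* hydrophobicity: `S_hyd = c0 - |H_i - H_j|`. The functional form here is a
  design choice: it is symmetric, monotone-decreasing in hydropathy
  mismatch, and its zero crossing is set by the offset `c0`. The default
  `c0 = 1.5` KD units makes the mean score over randomly paired columns
  roughly zero, so the term rewards agreement rather than inflating every
  score. The form is isolated behind `hydrophobic_score()` so alternatives
  (e.g. a product form) can be swapped without touching anything else;
* secondary structure: the bilinear form `f_i' L f_j` over a symmetric 3×3
  log-odds substitution table `L`.

Defaults are `Wc = 1`, `Wh = 0.3`, `Ws = 0.3` and all three windows 5
columns wide. The conservation window of 5 is the empirically best-performing
width for this family of methods; the hydrophobic and SS windows default to
the same value and are independently configurable. Setting `Wh = 0`,
`Ws = 0` or all windows to 1 reproduces the `no_hyd`, `no_sec` and
`no_neigh` scoring variants exactly (this is asserted term-for-term in the
test suite), and `tune_parameters()` offers a sensitivity-maximising grid
search for users with labelled data. Windowed sums are raw sums (not means)
with uniform weight across the window.

## The SS substitution table

`estimate_ss_table()` fits `L(s,s') = log2(P(s,s') / (P(s) P(s')))` from
joint counts over aligned 3-state string pairs, symmetrised and
pseudocounted (default 1 per cell, guaranteeing finite entries on sparse
input). The package ships a **synthetic** default table
(`inst/extdata/ss_substitution_synthetic.tsv`), estimated from
SS-conserving alignments produced by the package's own world generator at a
fixed seed; it is a stand-in for a table fitted to curated structural
alignments, which cannot be derived without external data. Its qualitative
structure — positive diagonal, negative off-diagonal, sheet and loop
self-substitution strongest — is what the score needs; users with real
structural alignments should estimate and supply their own.

## Alignment model

Alignment is local, by Viterbi dynamic programming over the five pair-HMM
states MM, MI, IM, DG and GD (the five-state reduction of the nine-state
pair HMM that suffices for profile-profile alignment). `MM` consumes a
column of both profiles and adds `M(i,j)`; `MI`/`DG` advance only P
(through Q's insert transitions and P's delete transitions respectively);
`IM`/`GD` mirror them. Every log transition term — including the MM→MM
continuation — is multiplied by the gap weight `Wg` (default 1), which
keeps the windowed, multi-term `M(i,j)` from overwhelming the gap
penalties and producing overlong alignments of unrelated profiles.

Local behaviour comes from two rules: the MM recurrence takes a max with 0
(an alignment may start fresh at any cell), and traceback starts at the
global maximum of the MM matrix, which is also the reported score. Gap
states can only be entered from MM and left into MM, so alignments begin
and end in MM and gap runs are homogeneous. Numerical conventions: ties in
the max are broken by a fixed precedence (local start, MM, MI, IM, DG, GD)
and a tied traceback start takes the smallest (i, j), so tracebacks are
deterministic; an all-non-positive MM matrix yields the empty alignment
with score 0.

The test suite validates the DP against an independent oracle that
*enumerates every legal local path*: because gap runs are homogeneous, each
path is a chain of MM cells whose consecutive cells differ by (1,1), (k,1)
or (1,k) with a two-way gap-type choice, which makes full enumeration
feasible for profiles up to six states. DP and enumeration agree exactly on
hundreds of seeded random pairs.

## E-values

Scores of a query against unrelated profiles are modelled with a Gumbel
(type-I extreme value) distribution, the standard for optimal local
alignment scores. Calibration is per query — per-family fits avoid the
length and composition bias of database-wide parameters — by aligning the
query against a random profile database (`make_random_db()`, seeded
sampling, optionally column-shuffled to destroy residual homology) and
maximum-likelihood fitting (λ, μ) with moment-based initialisation. By
default the top 1% of calibration scores is treated as right-censored
(type-2 censoring), which protects the tail fit when a genuinely related
profile contaminates a "random" database. `E = N (1 − exp(−exp(−λ(s−μ))))`
with `N` defaulting to the size of the database actually searched. Fits on
fewer than 50 scores are flagged unreliable.

## Benchmarking

Labels follow the SCOP hierarchy (class/fold/superfamily/family). A pair of
distinct families in the same superfamily is a true relation; families in
different classes are false-positive material; same fold but different
superfamily, different folds within a class, and same-family pairs are
ignored (such intermediate relationships may still be homologous, so they
are excluded from both numerator and denominator). Sensitivity is
`TP/(TP+FN)` and error rate `FP/(FP+TP)`, swept over the ranked hit list
with ignored hits skipped. Relations are counted over *unordered* family
pairs, and `classify_hits()` deduplicates an all-vs-all search to its
best-scoring direction per unordered pair so numerator and denominator
agree.

Alignment accuracy against a gold-standard reference uses the developer
score (correct residue pairs / test pairs within the reference's covered
region, where "covered region" is the span of the reference on both
sequences) and the modeller score (correct pairs / reference length).
Residue-level test alignments are produced by transitive composition
(`compose_alignments()`) of sequence→profile, profile→profile and
profile→sequence maps. An empty test alignment scores (0, 0) by documented
convention.

## The synthetic world generator

`generate_world()` builds desk-scale benchmarks with no external data: per
superfamily an ancestral sequence and SS string (geometric segment lengths,
mean 8/5/4 for helix/sheet/loop), families diverged from the ancestor at a
between-family substitution rate of 0.35 with SS segments flipped with
probability 0.1, sequences within a family diverged at rate 0.08 with
indels at 0.02 per site, lengths 60–90, 5 superfamilies × 2 families × 8
sequences by default. Substitutions are drawn from SS-state-specific
residue pools (helix-, sheet- and loop-favouring residues), so the SS and
hydrophobicity signals survive sequence divergence — precisely the regime
the method targets. Every superfamily sits in its own fold *and* class, so
cross-superfamily pairs are eligible false positives rather than ignored.
These defaults were chosen once as a caricature of remote homology (within
a family sequences are clearly similar; between families conservation is
marginal but structure-correlated signal persists) and are not tuned
thereafter.

What the generator does *not* emulate: phylogenetic tree structure,
site-rate heterogeneity, realistic amino-acid substitution matrices,
PSIPRED's error profile, or the size and redundancy structure of real
classification databases. Passing the end-to-end tests therefore shows the
machinery is wired correctly and the signals it exploits are recoverable
when present — not that headline sensitivities on curated benchmarks would
be reproduced; those require the real profile databases and reference
alignments.

`build_profile_from_msa()` is a deliberately simple count-based model
builder (background-pseudocounted emissions, Laplace-smoothed transition
counts; Dirichlet mixture priors are out of scope): enough to exercise
every downstream component, including plan7 serialisation, which is checked
to round-trip within the `2^(1/1000)` integer-score quantisation.

## Problem sizes and runtime

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which each property is meaningfully exercised:
200 random profile pairs (up to 6 states each) for the DP-vs-enumeration
oracle; 20 replicates of 5000 draws for Gumbel parameter recovery; the
default 10-profile world (45 pairwise alignments, plus per-query
calibration against 60 shuffled profiles) for end-to-end discrimination.
The full suite completes in well under a minute on one CPU.

## Design decisions and known limitations

* Emissions are renormalised after the insert line is discarded; whether
  the original pipeline did so is unknowable from the method description,
  and this is the assumption that keeps `sum_a p(a) = 1` exactly.
* Begin/end special transitions of plan7 files are parsed but unused: local
  start/stop is handled entirely by the max-with-zero rule and the MM-matrix
  traceback start.
* The amino-acid order is the alphabetical one-letter order (A, C, D, …, Y)
  everywhere; sequence weighting is not applied when counting SS
  frequencies (plain frequency of occurrence).
* Only the single best (Viterbi) alignment is reported; forward/backward
  posterior decoding, suboptimal alignments and profile–sequence search are
  out of scope.
* The match-column rule when building profiles from raw MSAs is the
  classical gap-fraction ≤ 0.5 heuristic; profiles converted from plan7
  files keep their own node structure.
* Core containers (profiles, alignments, calibration fits) are plain S3
  objects; every result-like surface (hits, curves, accuracy, tuning
  grids) is a tibble, with `tidy()`/`glance()`/`autoplot()` methods, so
  downstream analysis composes with the tidyverse while the numerical core
  stays matrix-shaped.

## A minimal session

```{r example, eval = FALSE}
world <- generate_world(fixture_spec(seed = 42))
profiles <- world_profiles(world)

aln <- viterbi_align(profiles[[1]], profiles[[2]], hush_params())
aln
tidy(aln)

rdb <- make_random_db(profiles, size = 60, seed = 7, shuffle = TRUE)
fit <- calibrate(profiles[[1]], rdb)
hits <- align_all(profiles[[1]], profiles[-1], fit = fit)

classified <- classify_hits(hits, world$labels)
curve <- sensitivity_error_curve(classified,
                                 count_true_relations(world$labels),
                                 by = "evalue")
autoplot(curve)
```
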