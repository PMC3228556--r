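# alignhush

Remote homology detection by **profile HMM–HMM alignment** with
hydrophobicity and predicted secondary-structure scoring.

In the "midnight zone" of sequence similarity, residue conservation alone
no longer identifies common ancestry, but structure-correlated signals —
the pattern of helices, sheets and loops, and the hydrophobicity profile
that approximates core packing — persist. `alignhush` aligns two profile
hidden Markov models (plan7/HMMER2 models of protein families) directly
against each other, scoring each column pair by

```
M(i,j) = Wc Σ_w log2( Σ_a P(i+k, a) Q(j+k, a) / b_a )      conservation
       + Wh Σ_w ( c0 − |H_{i+k} − H_{j+k}| )               hydrophobicity
       + Ws Σ_w f(i+k)' L f(j+k)                           secondary structure
```

where the sums run over a diagonal window of adjacent column pairs
(default width 5), `b_a` is the background frequency, `H` the
Kyte–Doolittle column hydrophobicity, `f` the 3-state secondary-structure
frequency vector and `L` a symmetric 3×3 log-odds substitution table over
helix/sheet/loop. Alignment is local Viterbi dynamic programming over the
five pair-HMM states MM, MI, IM, DG, GD, with the plan7 transition
probabilities supplying position-specific gap penalties (weighted by
`Wg`). Statistical significance comes from per-query Gumbel (extreme
value) calibration against a random profile database:
`E = N (1 − exp(−exp(−λ(s − μ))))`.

The package also ships the surrounding benchmark machinery —
SCOP-style relation classes, sensitivity/error-rate curves, developer and
modeller alignment accuracy via transitive alignment composition,
parameter tuning — and a seeded synthetic world generator so that every
component is testable without any external database. See the methods
vignette (`vignettes/alignhush-methods.Rmd`) for the model, parameter
meanings and design decisions.

## Worked example

```r
library(alignhush)

# a synthetic benchmark world: 5 superfamilies x 2 diverged families
world    <- generate_world(fixture_spec(seed = 42))
profiles <- world_profiles(world)

# align two families of the same superfamily
aln <- viterbi_align(profiles[["sf01_fam1"]], profiles[["sf01_fam2"]])
aln
#> <hush_alignment> sf01_fam1[1-75] vs sf01_fam2[1-77]: 45 aligned pairs, score 261.528 bits

# calibrate E-values against a column-shuffled random database and search
rdb  <- make_random_db(profiles, size = 60, seed = 7, shuffle = TRUE)
fit  <- calibrate(profiles[["sf01_fam1"]], rdb)
fit
#> <hush_evalue_fit> lambda=0.0858 mu=29.480 (n=60)

hits <- align_all(profiles[["sf01_fam1"]],
                  profiles[names(profiles) != "sf01_fam1"], fit = fit)
hits[1:3, 1:5]
#> # A tibble: 3 x 5
#>   query     target    score       evalue n_pairs
#> 1 sf01_fam1 sf01_fam2 262.  0.0000000204      45
#> 2 sf01_fam1 sf05_fam2 150.  0.000294          30
#> 3 sf01_fam1 sf04_fam2  82.2 0.0974            13
```

The self-superfamily partner is found at E ≈ 2e-8 with 45 of 75 query
columns aligned; the best cross-class decoy trails it by more than 100
bits. Hit tables, sensitivity/error curves (`sensitivity_error_curve()`)
and accuracy summaries are tibbles; fitted objects have `tidy()` /
`glance()` methods and curves/fits have `autoplot()`.

A thin command-line front end is installed with the package (at
`system.file("exec", "alignhush", package = "alignhush")`; symlink it onto
your PATH or call it through `Rscript`):

```sh
alignhush fixtures  --out fx --seed 42        # write a synthetic world
alignhush align     fx/sf01_fam1.ah fx/sf01_fam2.ah
alignhush calibrate fx/sf01_fam1.ah fx --shuffle --out q.cal
alignhush search    fx/sf01_fam1.ah fx --calibration q.cal
```

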