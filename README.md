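# MusicDNA

Evolutionary consequences of bidirectional inheritance, explored with an
artificial system in which synthetic DNA is the genotype and a monophonic
musical score is the phenotype.

In biology, information flows one way: DNA → protein, never back. DNA
digital data storage quietly breaks that rule — edits to a file can be
written back into DNA — so a read/write DNA system is effectively
*Lamarckian*: phenotype-level changes become heritable. `MusicDNA`
implements such a system end to end and measures what bidirectionality
costs.

The core is an artificial redundant genetic code: 256 four-letter codons
over {A,C,G,T} encode 64 musical elements (16 MIDI notes × 4 durations;
four synonymous codons per element, differing only at a wobble
position). **Translation** (DNA → music) is deterministic;
**reverse translation** (music → DNA) draws each element's codon
uniformly at random from its four synonyms, with no memory of earlier
codon usage. Two results follow and are what the package reproduces
computationally:

1. **Synonymous mutations are erased.** A silent DNA change never reaches
   the phenotype, and the next reverse translation regenerates the
   genotype from the phenotype alone. Over 20 generations, a regime
   injecting one synonymous mutation per generation is statistically
   indistinguishable from a zero-mutation control (Hamming distance to
   the ancestor, Welch two-tailed t-test).
2. **Bidirectional transmission carries ~2× the nonsynonymous load.**
   Nonsynonymous mutations can arise during reverse translation *and*
   during translation: one event per generation at each level gives 40
   events in 20 generations versus 20 for the unidirectional maximum,
   and a significantly higher generation-20 divergence.

The package also includes the surrounding apparatus: homopolymer
screening/recoding (no runs ≥ 7, for synthesisability), a bespoke
Needleman–Wunsch aligner for music scores (exact match 5, near match 3,
mismatch 0, gap −2), needle-style global DNA alignment (match 5,
mismatch −4, gap open 10, extend 0.5, via Biostrings), square-wave WAV
and format-0 MIDI rendering, a parameterised noisy capture channel
standing in for the play/record loop, and a four-round selection
experiment contrasting a purifying panel-proxy (pick the variant most
similar to the ancestor) against random selection.

## Worked example

```r
library(MusicDNA)

ct  <- buildDefaultCodeTable()    # 256 codons -> 64 elements
anc <- odeToJoyFixture()          # 62-element Ode to Joy reconstruction
anc
#> MusicScore: 62 elements, 100 bpm, -20 dBFS
#>   note : 64 64 65 67 67 65 64 62 ...
#>   beats: 0.5 0.5 0.5 0.5 0.5 0.5 0.5 0.5 ...

dna <- reverseTranslate(anc, ct, seed = 42)
substr(dna, 1, 60)
#> "AGCAAGCAATCACACACACCATCTAGCCACCCAACAAACTACCGAGCTAGCGACGTACAA"
nchar(dna); longestHomopolymer(dna)
#> 248      # 4 bases per element
#> 6        # homopolymer screen guarantees < 7

identical(noteNumbers(translateDna(dna, ct)), noteNumbers(anc))
#> TRUE     # translation inverts reverse translation exactly
```

Twenty generations under the maximal bidirectional regime (one
nonsynonymous DNA mutation *and* one nonsynonymous music mutation per
generation), ten replicates:

```r
tr <- runSimulation(anc, regime = 6, generations = 20, replicates = 10,
                    table = ct, seed = 42)
tail(summarizeTraces(tr), 3)
#>    regime generation mean_hamming
#> 18      6         18        105.6
#> 19      6         19        105.4
#> 20      6         20        108.6
```

For comparison, the zero-mutation control plateaus at ≈ 46.5 (= 0.75 ×
62: each of the 62 codons is re-drawn every generation and disagrees with
the ancestor's draw with probability 3/4) — the synonymous-scatter floor
that all regimes share. Regime 6 sits far above it; regime 3
(unidirectional maximum) about halfway between.

Four rounds of noisy-channel evolution with panel-proxy selection:

```r
runRounds(anc, rounds = 4, strategy = "purifying", table = ct, seed = 42)
#>   round  strategy winner delta_dna music_score_vs_ancestor
#> 1     1 purifying      1       441                     296
#> 2     2 purifying      1       510                     282
#> 3     3 purifying      1       643                     241
#> 4     4 purifying      1       419                     229
```

The purifying arm always picks the least-mutated variant (winner 1 in
the chained series), and its music similarity to the ancestor (maximum
310 = 62 × 5) decays far more slowly than under `strategy = "random"`.
The DNA `delta_dna` column includes the synonymous scatter of fresh
reverse translation each round, which is why it is large even when the
melody is nearly intact — genotype churns while phenotype is conserved.

A thin command-line interface over the same functions is included:

```sh
Rscript inst/cli/musicdna.R encode --midi anc.mid --out dna.fasta --seed 7
Rscript inst/cli/musicdna.R simulate --regime 6 --generations 20 \
    --replicates 10 --seed 7 --out trace.tsv
```

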