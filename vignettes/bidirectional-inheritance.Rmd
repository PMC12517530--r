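---
title: "Bidirectional inheritance between DNA and music: model and methods"
author: "MusicDNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional inheritance between DNA and music: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MusicDNA)
```

## The system

All known biology transmits information one way: DNA determines protein,
never the reverse. `MusicDNA` implements an artificial inheritance system
in which that barrier is deliberately removed. The genotype is a synthetic
DNA string; the phenotype is a monophonic musical score; and an artificial
genetic code lets information flow in *both* directions:

* **Translation** (genotype to phenotype) reads the DNA codon by codon and
  is deterministic.
* **Reverse translation** (phenotype to genotype) writes each musical
  element back to DNA by drawing one of its synonymous codons *uniformly
  at random*. Nothing links the draw to the codons of any earlier
  sequence: the system has no codon memory.

That single design fact drives everything the package measures. A
synonymous DNA mutation changes the genotype without changing the
phenotype — and because the next generation's genotype is regenerated from
the phenotype alone, the mutation is erased. Conversely, every mutation
that *does* survive a generation is nonsynonymous, and nonsynonymous
mutations can now arise at two levels (during reverse translation into
DNA, and during translation into music), so a bidirectional system carries
roughly twice the transmissible mutational load of a unidirectional one.

## The genetic code

The code maps 256 four-letter codons (alphabet A/C/G/T) onto 64 elements,
the Cartesian product of 16 MIDI notes and 4 durations (1, 1/2, 1/4, 1/8
beat). It is total and grammarless — no start or stop codons — with exact
four-fold redundancy.

The packaged default table is built deterministically: elements are
indexed 0–63 (note-major, duration-minor), the index is base-4 encoded
into codon positions 1–3 (0→A, 1→C, 2→G, 3→T), and position 4 — the
wobble position — takes all four bases. Two consequences follow by
construction and are enforced by the class validity method:

* the four synonymous codons of an element differ pairwise at exactly one
  nucleotide (the wobble position), so a synonymous swap is always a
  single point mutation;
* codons of different elements always differ somewhere in their first
  three positions.

The 16-note subset defaults to the C-major diatonic pitches from middle C
(MIDI 60) up to D6 (MIDI 86). This spans the packaged melody and the
octaves that element snapping can reach, and it is configurable: any
16-note subset can be passed to `buildDefaultCodeTable()`, and whole
tables round-trip through a four-column TSV (`writeCodeTable()` /
`readCodeTable()`), so an externally specified assignment can be dropped
in unchanged.

```{r code-table}
ct <- buildDefaultCodeTable()
ct
synonyms(ct, 60, 1/2)
```

## The codec

`reverseTranslate()` draws codons left to right, one per element, from
the element's synonym set (alphabetical order, so draws are reproducible
under a seed). The output is screened for homopolymeric tracts: runs of 7
or more identical bases are a practical obstacle to chemical synthesis
and Sanger sequencing, so any such run triggers `recodeHomopolymers()`,
which re-draws the synonymous codon of each codon overlapping the run,
left to right, re-checking after each re-draw (budget: 100 passes per
run, then an error naming the stuck interval). Recoding only ever touches
codons overlapping an offending run and never changes the encoded
elements. Under the default wobble code a run can always be broken — at
worst a repeated `AAA`-prefix element yields `AAAxAAAx…`, whose maximal
runs have length 3 once wobble bases are non-A — and a property test
confirms that 1,000 random scores reverse-translate with no run over 6.

`translateDna()` validates frame (length divisible by 4, with the offset
reported) and alphabet (1-based position reported) and decodes
deterministically; translated scores get the system defaults of 100 bpm
and −20 dBFS.

`snapToCode()` is the bridge from arbitrary MIDI input to the code's
domain: a note keeps its pitch class whenever some in-code note shares
it, moving to the nearest in-code octave, and otherwise moves to the
nearest in-code note by MIDI-number distance; durations move to the
nearest of the four code durations. Note and duration are snapped
independently. Ties are resolved by a fixed rule — lower octave, lower
note, shorter duration — chosen so that snapping is deterministic; the
direction of the tie-break is otherwise arbitrary.

## Mutational regimes and the simulator

`runSimulation()` iterates the full cycle: each generation reverse
translates the current score, applies the regime's DNA-level action,
translates back to a score, and applies the regime's music-level action.
The six regimes pair the actions as follows:

| id | DNA action (after reverse translation) | music action (after translation) |
|----|----------------------------------------|----------------------------------|
| 1  | none                                   | none |
| 2  | one synonymous codon swap              | none |
| 3  | one nonsynonymous codon swap           | none |
| 4  | one random point mutation              | none |
| 5  | none                                   | one element swap |
| 6  | one nonsynonymous codon swap           | one element swap |

Choices the regime definitions leave open are resolved as follows. The
single mutated codon slot is chosen uniformly *after* the full random
re-assignment, keeping the two steps composable. Nonsynonymous draws are
uniform over the 252 foreign codons (DNA level) or the 63 foreign
elements (music level) — the maximum-entropy default. A point mutation
picks a position and one of the three alternative bases uniformly; under
the wobble code it is synonymous exactly when it hits codon position 4,
i.e. with probability 1/4.

Divergence is tracked as the raw Hamming distance between each
generation's DNA and the replicate's ancestor DNA (a single reverse
translation of the unmutated score, made once per replicate). No
saturation correction is applied. Because every generation re-draws every
codon, even the zero-mutation regime 1 sits at an expected distance of
3/4 per codon — 46.5 for the 62-element ancestor — from generation 1
onward; regimes differ in what accumulates *on top of* that scatter.
Generation-20 contrasts use Welch's two-tailed t-test on the 10 replicate
distances: the regime descriptions say "two-tailed t-test" without a
variance assumption, and Welch is the safer default. Two of the headline
contrasts assert *non-rejection* (regimes 1 vs 2; regime 2 at generations
1 vs 20); their null is true by construction, so any given seed has an
irreducible ~5% chance of rejecting — the assertions are about the
distributional property, not about reproducing a particular p-value.

Seeding: every stochastic operation takes an optional `seed` and restores
the caller's RNG state; `runSimulation()` spawns one sub-seed per
replicate from its master seed so replicates are independently
reproducible.

```{r simulate}
anc <- odeToJoyFixture()
tr <- runSimulation(anc, regime = 6, generations = 5, replicates = 3,
                    table = ct, seed = 1)
summarizeTraces(tr)
```

## Alignment

Two aligners serve different comparisons. For *music scores* (which can
differ in length once the capture channel introduces indels) the package
implements Needleman–Wunsch global alignment over note/duration elements
with linear gaps and the scoring scheme exact = 5 (same note, same
duration), near = 3 (same note, different duration), mismatch = 0
(different note, regardless of duration), gap = −2. A score aligned
against itself therefore attains 5 × length — 310 for the 62-element
ancestor — which is the self-comparison baseline used throughout.
Traceback ties are broken deterministically (diagonal, then gap in the
right score, then gap in the left); only the optimal score, which is
unique, is asserted in tests, where the aligner is checked against an
exhaustive enumeration oracle on all small inputs.

For *DNA*, alignment is delegated to `Biostrings::pairwiseAlignment()`
with match +5, mismatch −4, gap opening 10 and gap extension 0.5 — the
needle-style nucleotide defaults, under which a gap of length L costs
`10 + 0.5·L` and terminal gaps are penalised. `deltaScore()` reports the
drop of a winner's alignment score against its progenitor relative to
the progenitor's self-alignment; one substitution costs 9. The raw
alignment score plays the role of a similarity "bitscore"; no
bit-normalisation is applied since the global aligner defines none.

## Audio and the capture channel

`renderWav()` synthesises each element as a square wave at its
equal-temperament frequency `f = 2^((d−69)/12) × 440` Hz for
`beats × 60/tempo` seconds, at 44100 Hz, 16-bit PCM mono, with linear
amplitude `10^(dBFS/20)` (−20 dBFS → 0.1 of full scale). MIDI output is
format 0, single track, 480 ticks per beat, one note_on/note_off pair per
element and a tempo meta-event; the parser accepts exactly this dialect
(plus running status) and rejects polyphony and multi-track files.

The physical loop — loudspeakers, room, microphone, pitch capture — is
replaced by `noisyCapture()`, a stochastic edit process at the element
level: per element a deletion (`pDel`) or substitution (`pSub`), and
after each position an insertion (`pIns`). With probability
`octaveScatter` a substitution produces an arbitrary MIDI note/duration,
which is then snapped into the code, so channel output is always
in-code. The `"noisy"` preset (pSub 0.05, pDel 0.02, pIns 0.02,
octaveScatter 0.1) gives a few edits per pass over a 62-element score —
enough that five chained passes degrade audibly, which is the property
the selection experiment needs. These rates are modelling choices, not
measurements of any particular room, and are fully exposed. No waveform
analysis (onset detection, pitch tracking) is performed: mutations are
defined and scored at the symbolic element level, which is also where
the selection experiment operates.

## Selection experiment

`runRounds()` repeats for four rounds: build five chained variants of the
progenitor through the channel (variant k is one more pass over variant
k−1, so later variants carry successively more mutation), select a
winner, and carry it forward. The listener panel is modelled as
`selectPurifying()` — argmax of the music alignment score against the
ancestor, ties to the lowest index — the executable proxy for a panel
that consistently prefers the least mutated version. The control arm
`selectRandom()` picks uniformly. Per-round DNA is produced by fresh
reverse translation of progenitor and winner, as in the live system where
each round's winner is re-encoded before synthesis; consequently
synonymous codon scatter contributes a substantial baseline to every DNA
delta-score — even a noiseless round has a positive delta — while the
music-score track is scatter-free. The headline contrast is therefore
asserted on the music track: over 20 paired seeded runs, the purifying
arm's round-4 score against the ancestor stochastically dominates the
random arm's (one-sided paired Wilcoxon test at α = 0.05).

```{r rounds}
rr <- runRounds(anc, rounds = 2, strategy = "purifying", table = ct,
                seed = 1)
rr
```

## The packaged ancestor

`odeToJoyFixture()` returns a 62-element monophonic reconstruction of the
Ode to Joy theme (Beethoven, Symphony No. 9), built from the standard
tune under the convention crotchet = 1/2 beat and constrained so that
every element lies in the default code (no snapping needed). Its length
fixes the self-alignment maximum at 310 = 62 × 5 and the regime-1 plateau
at 46.5 = 0.75 × 62. It is a synthetic reconstruction, not a transcription
of any particular published arrangement; any in-code MIDI file can be
substituted as ancestor everywhere the fixture is accepted.

## What the synthetic conditions do and do not show

The simulator and channel reproduce the *structure* of the physical
system — memoryless reverse translation, regime actions, chained variant
generation, panel selection — under clean, parameterised randomness. They
do not model synthesis/sequencing error (the physical steps returned
error-free data and are bypassed digitally), real room acoustics, or
human aesthetic judgement beyond the least-mutated proxy. Passing tests
therefore establish the system's evolutionary properties (synonymous
masking, two-fold nonsynonymous load, purifying selection under an
ancestor-similarity criterion), not quantitative fidelity to any
particular recording environment.

## Problem sizes and numerical choices

Simulations use the study-scale conditions — the 62-element ancestor, 20
generations, 10 replicates, five variants, four rounds, 20 paired
selection runs — which complete in seconds to a couple of minutes.
Property tests use 300–1,000 random scores and brute-force oracles on
inputs of up to 4 elements/bases, where exhaustive enumeration (321
alignment paths at 4×4) is exact. All stochastic assertions use fixed
seeds; binomial tolerances are stated at roughly 4 standard deviations of
the estimator.

## Known limitations

* The code covers 16 notes × 4 durations only; it is a reduced code
  sufficient for the packaged melody, not a general MIDI-to-DNA codec.
* Scores are strictly monophonic: no chords, rests, velocity dynamics or
  multi-track MIDI.
* The capture channel is symbolic; no acoustics are simulated.
* Hamming distances are reported raw and saturate near the scatter
  plateau; regimes are compared within the 20-generation window, not
  corrected for multiple hits.
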