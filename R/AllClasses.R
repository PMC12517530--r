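#' @import methods
NULL

DNA_BASES <- c("A", "C", "G", "T")
CODE_DURATIONS <- c(1, 1/2, 1/4, 1/8)

## 16 diatonic C-major pitches from middle C upward; spans the fixture
## melody plus the octaves reachable by element snapping.
DEFAULT_NOTE_SET <- c(60L, 62L, 64L, 65L, 67L, 69L, 71L, 72L,
                      74L, 76L, 77L, 79L, 81L, 83L, 84L, 86L)

#' CodeTable: an artificial redundant genetic code
#'
#' A `CodeTable` maps 256 four-letter codons (alphabet A/C/G/T) onto 64
#' musical elements, the Cartesian product of 16 MIDI notes and 4 durations
#' (1, 1/2, 1/4, 1/8 beat). The code is total and grammarless (no
#' start/stop codons) with exact four-fold redundancy: every element has 4
#' synonymous codons, and any two codons of the same element differ at
#' exactly one nucleotide (the wobble position).
#'
#' @slot codon character vector of length 256, the codons.
#' @slot note integer vector of length 256, the MIDI note encoded by each
#'   codon.
#' @slot beats numeric vector of length 256, the duration in beats encoded
#'   by each codon.
#'
#' @seealso [buildDefaultCodeTable()], [decodeCodon()], [synonyms()]
#' @exportClass CodeTable
setClass("CodeTable",
         representation(codon = "character",
                        note = "integer",
                        beats = "numeric"))

setValidity("CodeTable", function(object) {
  msg <- character()
  n <- length(object@codon)
  if (n != 256L)
    msg <- c(msg, sprintf("code table must have 256 codons, has %d", n))
  if (length(object@note) != n || length(object@beats) != n)
    msg <- c(msg, "codon, note and beats slots must have equal length")
  if (length(msg)) return(msg)
  if (anyDuplicated(object@codon))
    msg <- c(msg, "codons must be unique")
  if (!all(nchar(object@codon) == 4L))
    msg <- c(msg, "every codon must have length 4")
  if (!all(strsplit(paste(object@codon, collapse = ""), "")[[1]] %in% DNA_BASES))
    msg <- c(msg, "codon alphabet must be {A,C,G,T}")
  key <- paste(object@note, object@beats)
  tab <- table(key)
  if (length(tab) != 64L)
    msg <- c(msg, sprintf("code must have 64 distinct elements, has %d",
                          length(tab)))
  if (!all(tab == 4L))
    msg <- c(msg, "every element must have exactly 4 synonymous codons")
  if (length(unique(object@note)) != 16L)
    msg <- c(msg, "code must use exactly 16 distinct notes")
  if (!setequal(unique(object@beats), CODE_DURATIONS))
    msg <- c(msg, "durations must be exactly {1, 1/2, 1/4, 1/8} beats")
  ## within-element pairwise Hamming distance must be exactly 1
  if (!length(msg)) {
    for (k in unique(key)) {
      cods <- object@codon[key == k]
      m <- do.call(rbind, strsplit(cods, ""))
      for (i in 1:3) for (j in (i + 1):4)
        if (sum(m[i, ] != m[j, ]) != 1L) {
          msg <- c(msg, sprintf(
            "synonymous codons %s and %s differ at %d positions (must be 1)",
            cods[i], cods[j], sum(m[i, ] != m[j, ])))
        }
      if (length(msg)) break
    }
  }
  if (length(msg)) msg else TRUE
})

#' MusicScore: a monophonic musical phenotype
#'
#' An ordered sequence of note/duration elements with playback metadata.
#' Notes are MIDI note numbers (0-127); durations are in beats. Elements
#' need not lie inside a particular [CodeTable]'s domain (use
#' [snapToCode()] before [reverseTranslate()]).
#'
#' @slot note integer vector, MIDI note numbers.
#' @slot beats numeric vector, durations in beats (positive).
#' @slot tempo numeric scalar, beats per minute (> 0; default 100).
#' @slot volume numeric scalar, playback level in dBFS (<= 0; default -20).
#'
#' @seealso [MusicScore()], [translateDna()], [reverseTranslate()]
#' @exportClass MusicScore
setClass("MusicScore",
         representation(note = "integer",
                        beats = "numeric",
                        tempo = "numeric",
                        volume = "numeric"),
         prototype(tempo = 100, volume = -20))

setValidity("MusicScore", function(object) {
  msg <- character()
  if (length(object@note) != length(object@beats))
    msg <- c(msg, "note and beats must have equal length")
  if (length(object@note) && (anyNA(object@note) ||
      any(object@note < 0L | object@note > 127L)))
    msg <- c(msg, "notes must be MIDI note numbers in 0..127")
  if (length(object@beats) && (anyNA(object@beats) || any(object@beats <= 0)))
    msg <- c(msg, "durations must be positive")
  if (length(object@tempo) != 1L || is.na(object@tempo) || object@tempo <= 0)
    msg <- c(msg, "tempo must be a single positive bpm value")
  if (length(object@volume) != 1L || is.na(object@volume) || object@volume > 0)
    msg <- c(msg, "volume must be a single dBFS value <= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a MusicScore
#'
#' @param note integer vector of MIDI note numbers (0-127).
#' @param beats numeric vector of durations in beats, same length as `note`.
#' @param tempo beats per minute (default 100).
#' @param volume playback level in dBFS (default -20; 0 is full scale).
#' @return A [MusicScore-class] object.
#' @examples
#' s <- MusicScore(c(64L, 62L, 60L), c(1/2, 1/2, 1))
#' length(s)
#' @export
MusicScore <- function(note, beats, tempo = 100, volume = -20) {
  new("MusicScore", note = as.integer(note), beats = as.numeric(beats),
      tempo = as.numeric(tempo), volume = as.numeric(volume))
}

#' NoiseModel: parameterised noisy-capture channel
#'
#' Stand-in for a physical play-through-loudspeakers / record / convert
#' loop: a stochastic edit process on score elements. Per element, a
#' substitution (probability `pSub`) or deletion (`pDel`) may occur, and a
#' random element may be inserted after each position (`pIns`).
#' `octaveScatter` is the probability that a substitution produces an
#' arbitrary MIDI note outside the code's note set, exercising element
#' snapping.
#'
#' @slot pSub,pDel,pIns,octaveScatter numeric probabilities in \[0, 1\];
#'   `pSub + pDel <= 1`.
#' @seealso [noiseModel()], [noisePreset()], [noisyCapture()]
#' @exportClass NoiseModel
setClass("NoiseModel",
         representation(pSub = "numeric", pDel = "numeric",
                        pIns = "numeric", octaveScatter = "numeric"))

setValidity("NoiseModel", function(object) {
  p <- c(object@pSub, object@pDel, object@pIns, object@octaveScatter)
  if (length(p) != 4L || anyNA(p) || any(p < 0) || any(p > 1))
    return("all channel probabilities must lie in [0, 1]")
  if (object@pSub + object@pDel > 1)
    return("pSub + pDel must not exceed 1")
  TRUE
})

#' AlignmentResult: a pairwise global alignment
#'
#' Holds the optimal global alignment of two sequences (musical scores or
#' DNA): the total score, the aligned index pairs (NA marks a gap), and a
#' per-column state label.
#'
#' @slot score numeric scalar, total alignment score.
#' @slot pairs two-column integer matrix; row k gives the index into the
#'   left and right sequence aligned in column k (NA for a gap).
#' @slot states character vector, per-column state: `"exact"`, `"near"`,
#'   `"mismatch"` or `"gap"` for music; `"match"`, `"mismatch"` or `"gap"`
#'   for DNA.
#' @seealso [alignMusic()], [alignDna()]
#' @exportClass AlignmentResult
setClass("AlignmentResult",
         representation(score = "numeric",
                        pairs = "matrix",
                        states = "character"))

#' EvolutionTrace: one replicate of a mutation-accumulation run
#'
#' Per-generation record of a simulated lineage: the DNA sequence after the
#' generation's reverse translation (and DNA-level regime action), the
#' translated score, the Hamming distance to the replicate's ancestor DNA,
#' and the tally of mutation events applied.
#'
#' @slot regime integer, regime id 1-6.
#' @slot replicate integer, replicate index.
#' @slot ancestorDna character, the replicate's ancestral DNA (the initial
#'   reverse translation of the unmutated score).
#' @slot dna character vector, one sequence per generation.
#' @slot scores list of [MusicScore-class], one per generation (after any
#'   music-level action).
#' @slot hamming integer vector, Hamming distance of each generation's DNA
#'   to `ancestorDna`.
#' @slot events integer matrix (generations x 4) with columns
#'   `synonymous`, `nonsynonymous_dna`, `nonsynonymous_music`, `point`.
#' @seealso [runSimulation()], [summarizeTraces()]
#' @exportClass EvolutionTrace
setClass("EvolutionTrace",
         representation(regime = "integer",
                        replicate = "integer",
                        ancestorDna = "character",
                        dna = "character",
                        scores = "list",
                        hamming = "integer",
                        events = "matrix"))

## ---- basic methods ----

#' @describeIn MusicScore-class number of elements in the score.
#' @param x a `MusicScore`.
#' @export
setMethod("length", "MusicScore", function(x) length(x@note))

#' Accessors for MusicScore
#'
#' `noteNumbers()` returns the MIDI note numbers, `durations()` the
#' per-element durations in beats, `tempo()` the bpm and `volume()` the
#' dBFS level.
#'
#' @param x a [MusicScore-class].
#' @return numeric/integer vectors or scalars.
#' @examples
#' s <- odeToJoyFixture()
#' head(noteNumbers(s)); head(durations(s)); tempo(s); volume(s)
#' @name score-accessors
NULL

#' @rdname score-accessors
#' @export
setGeneric("noteNumbers", function(x) standardGeneric("noteNumbers"))
#' @rdname score-accessors
#' @export
setMethod("noteNumbers", "MusicScore", function(x) x@note)

#' @rdname score-accessors
#' @export
setGeneric("durations", function(x) standardGeneric("durations"))
#' @rdname score-accessors
#' @export
setMethod("durations", "MusicScore", function(x) x@beats)

#' @rdname score-accessors
#' @export
setGeneric("tempo", function(x) standardGeneric("tempo"))
#' @rdname score-accessors
#' @export
setMethod("tempo", "MusicScore", function(x) x@tempo)

#' @rdname score-accessors
#' @export
setGeneric("volume", function(x) standardGeneric("volume"))
#' @rdname score-accessors
#' @export
setMethod("volume", "MusicScore", function(x) x@volume)

#' Accessors for CodeTable
#'
#' `codons()` returns all 256 codons; `codeElements()` the 64 distinct
#' note/duration elements (one row each, in code order); `noteSet()` the
#' 16 notes; `durationSet()` the 4 durations.
#'
#' @param x a [CodeTable-class].
#' @return character vector, data.frame, integer vector or numeric vector.
#' @examples
#' ct <- buildDefaultCodeTable()
#' length(codons(ct)); nrow(codeElements(ct)); noteSet(ct); durationSet(ct)
#' @name codetable-accessors
NULL

#' @rdname codetable-accessors
#' @export
setGeneric("codons", function(x) standardGeneric("codons"))
#' @rdname codetable-accessors
#' @export
setMethod("codons", "CodeTable", function(x) x@codon)

#' @rdname codetable-accessors
#' @export
setGeneric("codeElements", function(x) standardGeneric("codeElements"))
#' @rdname codetable-accessors
#' @export
setMethod("codeElements", "CodeTable", function(x) {
  u <- !duplicated(paste(x@note, x@beats))
  data.frame(note = x@note[u], beats = x@beats[u])
})

#' @rdname codetable-accessors
#' @export
setGeneric("noteSet", function(x) standardGeneric("noteSet"))
#' @rdname codetable-accessors
#' @export
setMethod("noteSet", "CodeTable", function(x) sort(unique(x@note)))

#' @rdname codetable-accessors
#' @export
setGeneric("durationSet", function(x) standardGeneric("durationSet"))
#' @rdname codetable-accessors
#' @export
setMethod("durationSet", "CodeTable",
          function(x) sort(unique(x@beats), decreasing = TRUE))

setMethod("show", "CodeTable", function(object) {
  cat("CodeTable: 256 codons -> 64 note/duration elements",
      "(4-fold redundant)\n")
  cat("  notes:    ", paste(noteSet(object), collapse = " "), "\n")
  cat("  durations:", paste(format(durationSet(object)), collapse = " "),
      "beats\n")
})

setMethod("show", "MusicScore", function(object) {
  n <- length(object)
  cat(sprintf("MusicScore: %d element%s, %g bpm, %g dBFS\n",
              n, if (n == 1) "" else "s", object@tempo, object@volume))
  if (n) {
    k <- min(n, 8L)
    cat("  note :", paste(object@note[seq_len(k)], collapse = " "),
        if (n > k) "..." else "", "\n")
    cat("  beats:", paste(format(object@beats[seq_len(k)]), collapse = " "),
        if (n > k) "..." else "", "\n")
  }
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(
    "NoiseModel: pSub=%g pDel=%g pIns=%g octaveScatter=%g\n",
    object@pSub, object@pDel, object@pIns, object@octaveScatter))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: score %g over %d columns\n",
              object@score, nrow(object@pairs)))
  st <- table(factor(object@states,
                     levels = unique(c(object@states))))
  cat("  columns:", paste(sprintf("%s=%d", names(st), st), collapse = " "),
      "\n")
})

setMethod("show", "EvolutionTrace", function(object) {
  g <- length(object@hamming)
  cat(sprintf(
    "EvolutionTrace: regime %d, replicate %d, %d generations\n",
    object@regime, object@replicate, g))
  cat(sprintf("  ancestor DNA length %d; final Hamming distance %d\n",
              nchar(object@ancestorDna), object@hamming[g]))
})

#' Alignment score accessors
#'
#' @param x an [AlignmentResult-class].
#' @return `alignmentScore()` the numeric score; `alignmentStates()` the
#'   per-column state labels; `alignedPairs()` the two-column index matrix.
#' @name alignment-accessors
NULL

#' @rdname alignment-accessors
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @rdname alignment-accessors
#' @export
setMethod("alignmentScore", "AlignmentResult", function(x) x@score)

#' @rdname alignment-accessors
#' @export
setGeneric("alignmentStates", function(x) standardGeneric("alignmentStates"))
#' @rdname alignment-accessors
#' @export
setMethod("alignmentStates", "AlignmentResult", function(x) x@states)

#' @rdname alignment-accessors
#' @export
setGeneric("alignedPairs", function(x) standardGeneric("alignedPairs"))
#' @rdname alignment-accessors
#' @export
setMethod("alignedPairs", "AlignmentResult", function(x) x@pairs)

#' EvolutionTrace accessors
#'
#' @param x an [EvolutionTrace-class].
#' @return `hammingTrajectory()` the per-generation Hamming distances to
#'   the ancestor; `eventTally()` the generations-by-type event matrix;
#'   `ancestorDna()` the replicate's ancestral DNA string.
#' @name trace-accessors
NULL

#' @rdname trace-accessors
#' @export
setGeneric("hammingTrajectory",
           function(x) standardGeneric("hammingTrajectory"))
#' @rdname trace-accessors
#' @export
setMethod("hammingTrajectory", "EvolutionTrace", function(x) x@hamming)

#' @rdname trace-accessors
#' @export
setGeneric("eventTally", function(x) standardGeneric("eventTally"))
#' @rdname trace-accessors
#' @export
setMethod("eventTally", "EvolutionTrace", function(x) x@events)

#' @rdname trace-accessors
#' @export
setGeneric("ancestorDna", function(x) standardGeneric("ancestorDna"))
#' @rdname trace-accessors
#' @export
setMethod("ancestorDna", "EvolutionTrace", function(x) x@ancestorDna)
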