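#' Reverse translation: music score to DNA
#'
#' Converts each note/duration element to a 4-letter codon drawn uniformly
#' at random from the element's 4 synonymous codons (left to right, one
#' draw per element). Codon usage of any earlier DNA sequence plays no
#' role: reverse translation is memoryless, which is what erases
#' synonymous mutations across generations. The output is screened for
#' homopolymeric tracts and recoded so that no run of 7 or more identical
#' bases remains (see [recodeHomopolymers()]).
#'
#' @param score a [MusicScore-class] whose elements are all in the code
#'   (use [snapToCode()] first otherwise).
#' @param table a [CodeTable-class].
#' @param seed optional integer; if given, the draw is made under this
#'   seed and the caller's RNG state is untouched.
#' @return A DNA string of length `4 * length(score)` over A/C/G/T.
#' @examples
#' ct <- buildDefaultCodeTable()
#' s <- odeToJoyFixture()
#' dna <- reverseTranslate(s, ct, seed = 1)
#' nchar(dna)  # 248 = 4 * 62
#' @seealso [translateDna()] for the inverse direction.
#' @export
reverseTranslate <- function(score, table, seed = NULL) {
  stopifnot(is(score, "MusicScore"), is(table, "CodeTable"))
  n <- length(score)
  if (n == 0L) return("")
  synMat <- synonymMatrix(table)
  ei <- scoreElementIndex(score, table)
  withSeed(seed, {
    wob <- sample.int(4L, n, replace = TRUE)
    dna <- paste(synMat[cbind(ei, wob)], collapse = "")
    recodeHomopolymers(dna, table)
  })
}

## 64 x 4 matrix of synonymous codons, elements in code order, columns in
## alphabetical (wobble) order.
synonymMatrix <- function(table) {
  key <- paste(table@note, table@beats)
  ekey <- unique(key)
  m <- matrix("", 64L, 4L)
  for (e in seq_along(ekey))
    m[e, ] <- sort(table@codon[key == ekey[e]])
  m
}

## Map each score element to its 1-based element index in the code;
## error naming the first out-of-code element.
scoreElementIndex <- function(score, table) {
  key <- paste(table@note, table@beats)
  ekey <- unique(key)
  skey <- paste(score@note, score@beats)
  ei <- match(skey, ekey)
  if (anyNA(ei)) {
    k <- which(is.na(ei))[1]
    stop(sprintf(
      "element %d (note %d, %s beats) is not in the code; snap it first",
      k, score@note[k], format(score@beats[k])))
  }
  ei
}

#' Longest homopolymeric tract
#'
#' Length of the longest run of identical consecutive bases.
#'
#' @param dna a DNA string.
#' @return Integer run length (0 for the empty string).
#' @examples
#' longestHomopolymer("AACCCGGGGT")  # 4
#' @export
longestHomopolymer <- function(dna) {
  if (is(dna, "XString")) dna <- as.character(dna)
  stopifnot(is.character(dna), length(dna) == 1L)
  if (nchar(dna) == 0L) return(0L)
  max(rle(strsplit(dna, "")[[1]])$lengths)
}

#' Recode homopolymeric tracts
#'
#' DNA with long single-base runs is hard to synthesise and sequence; any
#' run of 7 or more identical bases triggers recoding. For each offending
#' maximal run, the synonymous codon of every codon overlapping the run is
#' re-drawn (uniformly over the element's 4 synonyms), left to right,
#' re-checking after each re-draw. Codons not overlapping an offending run
#' are left unchanged, so the encoded element sequence is preserved
#' exactly.
#'
#' @param dna a framed DNA string that decodes under `table`.
#' @param table a [CodeTable-class].
#' @param seed optional integer seed for the re-draws.
#' @param maxPasses re-draw budget per offending run before giving up.
#' @return A DNA string encoding the same elements with
#'   `longestHomopolymer() < 7`.
#' @export
recodeHomopolymers <- function(dna, table, seed = NULL, maxPasses = 100L) {
  dna <- checkDna(dna, requireFrame = TRUE)
  stopifnot(is(table, "CodeTable"))
  if (longestHomopolymer(dna) < 7L) return(dna)
  synMat <- synonymMatrix(table)
  withSeed(seed, {
    cods <- splitCodons(dna)
    ei <- codonElementIndex(table, cods)
    if (anyNA(ei))
      stop("sequence does not decode under the code table")
    repeat {
      chars <- strsplit(paste(cods, collapse = ""), "")[[1]]
      r <- rle(chars)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      off <- which(r$lengths >= 7L)
      if (!length(off)) break
      lo <- starts[off[1]]; hi <- ends[off[1]]
      slots <- unique(((lo - 1L) %/% 4L):((hi - 1L) %/% 4L)) + 1L
      fixed <- FALSE
      for (pass in seq_len(maxPasses)) {
        for (s in slots) {
          cods[s] <- synMat[ei[s], sample.int(4L, 1L)]
          run <- max(rle(strsplit(paste(
            cods[slots], collapse = ""), "")[[1]])$lengths)
          if (run < 7L) { fixed <- TRUE; break }
        }
        if (fixed) break
      }
      if (!fixed)
        stop(sprintf(
          "could not recode homopolymeric tract at bases %d-%d within %d passes",
          lo, hi, maxPasses))
    }
    paste(cods, collapse = "")
  })
}

#' Translation: DNA to music score
#'
#' Decodes a DNA sequence codon by codon into a [MusicScore-class].
#' Translation is deterministic and total over framed sequences: every
#' codon maps to exactly one element (the code is grammarless, with no
#' start/stop codons). Tempo and volume are set to the system defaults
#' (100 bpm, -20 dBFS).
#'
#' @param dna a DNA string over A/C/G/T with length divisible by 4 (also
#'   accepts a `Biostrings::DNAString`).
#' @param table a [CodeTable-class].
#' @param tempo,volume playback metadata for the resulting score.
#' @return A [MusicScore-class].
#' @examples
#' ct <- buildDefaultCodeTable()
#' s <- translateDna("AAAAAAAC", ct)  # two synonymous codons: same element
#' noteNumbers(s)
#' @export
translateDna <- function(dna, table, tempo = 100, volume = -20) {
  dna <- checkDna(dna, requireFrame = TRUE)
  stopifnot(is(table, "CodeTable"))
  if (nchar(dna) == 0L)
    return(MusicScore(integer(), numeric(), tempo, volume))
  el <- decodeCodon(table, splitCodons(dna))
  MusicScore(el$note, el$beats, tempo, volume)
}

#' Snap an element onto the code's domain
#'
#' Maps arbitrary note/duration pairs to the nearest element of the code,
#' the rule used when a noisy capture produces out-of-code elements. The
#' note keeps its pitch class whenever some in-code note shares it, shifted
#' to the nearest in-code octave (ties go to the lower octave); otherwise
#' the nearest in-code note by MIDI-number distance is used (ties go to the
#' lower note). The duration is moved to the nearest of 1, 1/2, 1/4 and
#' 1/8 beats (ties go to the shorter duration). Note and duration are
#' snapped independently. Vectorised.
#'
#' @param note integer vector of MIDI note numbers (0-127).
#' @param beats numeric vector of positive durations in beats.
#' @param table a [CodeTable-class].
#' @return A data.frame with columns `note` and `beats`, all rows in-code.
#' @examples
#' ct <- buildDefaultCodeTable()
#' snapToCode(48, 0.6, ct)   # C3 -> C4 (nearest in-code octave), 0.6 -> 1/2
#' @export
snapToCode <- function(note, beats, table) {
  stopifnot(is(table, "CodeTable"))
  note <- as.integer(note)
  beats <- as.numeric(beats)
  stopifnot(length(note) == length(beats))
  if (anyNA(note) || any(note < 0L | note > 127L))
    stop("notes must be MIDI note numbers in 0..127")
  if (anyNA(beats) || any(beats <= 0))
    stop("durations must be positive")
  inNotes <- noteSet(table)
  durs <- durationSet(table)  # decreasing: 1, 1/2, 1/4, 1/8
  snapNote <- function(d) {
    cand <- inNotes[inNotes %% 12L == d %% 12L]
    if (!length(cand)) cand <- inNotes
    dist <- abs(cand - d)
    cand <- cand[dist == min(dist)]
    min(cand)  # tie: lower note / lower octave
  }
  snapBeats <- function(b) {
    dist <- abs(durs - b)
    hit <- durs[dist == min(dist)]
    min(hit)  # tie: shorter duration
  }
  data.frame(note = vapply(note, snapNote, integer(1)),
             beats = vapply(beats, snapBeats, numeric(1)))
}

#' Snap every element of a score onto the code
#'
#' Convenience wrapper around [snapToCode()] preserving tempo and volume.
#'
#' @param score a [MusicScore-class].
#' @param table a [CodeTable-class].
#' @return A [MusicScore-class] whose elements are all in the code.
#' @export
snapScore <- function(score, table) {
  stopifnot(is(score, "MusicScore"))
  sn <- snapToCode(score@note, score@beats, table)
  MusicScore(sn$note, sn$beats, score@tempo, score@volume)
}
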