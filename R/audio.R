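#' MIDI note number to frequency
#'
#' Equal-temperament pitch: `f = 2^((d - 69)/12) * 440` Hz, so note 69
#' (A4) is 440 Hz and each 12 semitones double the frequency.
#'
#' @param d MIDI note number(s) in 0..127.
#' @return Frequency in Hz (vectorised).
#' @examples
#' noteToFrequency(69)  # 440
#' noteToFrequency(81)  # 880
#' @export
noteToFrequency <- function(d) {
  if (anyNA(d) || any(d < 0 | d > 127))
    stop("MIDI note numbers must lie in 0..127")
  2^((d - 69) / 12) * 440
}

## ---- minimal format-0 MIDI writer/parser (monophonic) ----

## big-endian unsigned integer encoders
uintBE <- function(x, nbytes) {
  as.raw((x %/% 256^((nbytes - 1):0)) %% 256)
}

## MIDI variable-length quantity
vlq <- function(x) {
  x <- as.integer(x)
  stopifnot(x >= 0L)
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(x %% 128L, bytes)
    x <- x %/% 128L
  }
  if (length(bytes) > 1L)
    bytes[-length(bytes)] <- bytes[-length(bytes)] + 128L
  as.raw(bytes)
}

#' Serialise a score as a standard MIDI file
#'
#' Writes a format-0, single-track MIDI byte stream: a tempo meta-event
#' encoding the score's bpm, then one note_on/note_off pair per element
#' (channel 0, fixed velocity 64) with tick duration
#' `beats * ticksPerBeat`. Re-parsing with [midiToScore()] yields the
#' identical element sequence and tempo. The dBFS volume applies to WAV
#' rendering only and is not stored in the MIDI stream.
#'
#' @param score a [MusicScore-class].
#' @param ticksPerBeat MIDI division (default 480).
#' @return A raw vector holding the complete MIDI file.
#' @seealso [writeMidi()], [readMidi()], [midiToScore()]
#' @export
scoreToMidi <- function(score, ticksPerBeat = 480L) {
  stopifnot(is(score, "MusicScore"))
  ticksPerBeat <- as.integer(ticksPerBeat)
  stopifnot(ticksPerBeat > 0L)
  mpqn <- round(60e6 / score@tempo)  # microseconds per beat
  track <- c(as.raw(c(0x00, 0xFF, 0x51, 0x03)), uintBE(mpqn, 3L))
  for (k in seq_len(length(score))) {
    ticks <- as.integer(round(score@beats[k] * ticksPerBeat))
    track <- c(track,
               vlq(0L), as.raw(c(0x90, score@note[k], 64L)),
               vlq(ticks), as.raw(c(0x80, score@note[k], 0L)))
  }
  track <- c(track, as.raw(c(0x00, 0xFF, 0x2F, 0x00)))
  c(charToRaw("MThd"), uintBE(6L, 4L), uintBE(0L, 2L), uintBE(1L, 2L),
    uintBE(ticksPerBeat, 2L),
    charToRaw("MTrk"), uintBE(length(track), 4L), track)
}

#' Parse a monophonic MIDI byte stream into a score
#'
#' Reads a single-track (format 0) standard MIDI file: note_on/note_off
#' pairs become elements with durations in beats (`ticks / division`), and
#' a tempo meta-event sets the bpm (default 100 when absent). Running
#' status is handled; other channel and meta events are skipped. Polyphony
#' and multi-track files are unsupported.
#'
#' @param bytes raw vector with the MIDI file contents.
#' @param volume dBFS volume to attach to the resulting score (MIDI does
#'   not carry one).
#' @return A [MusicScore-class].
#' @export
midiToScore <- function(bytes, volume = -20) {
  stopifnot(is.raw(bytes))
  if (length(bytes) < 14L || rawToChar(bytes[1:4]) != "MThd")
    stop("not a standard MIDI file (missing MThd header)")
  be <- function(r) sum(as.integer(r) * 256^((length(r) - 1):0))
  ntrk <- be(bytes[11:12])
  if (ntrk != 1L)
    stop(sprintf("unsupported MIDI file: %d tracks (monophonic format-0 expected)",
                 ntrk))
  division <- be(bytes[13:14])
  if (division >= 32768L)
    stop("SMPTE time division is not supported")
  p <- 15L
  if (rawToChar(bytes[p:(p + 3L)]) != "MTrk")
    stop("missing MTrk chunk")
  trackLen <- be(bytes[(p + 4L):(p + 7L)])
  p <- p + 8L
  end <- p + trackLen - 1L
  readVlq <- function() {
    v <- 0L
    repeat {
      b <- as.integer(bytes[p]); p <<- p + 1L
      v <- v * 128L + (b %% 128L)
      if (b < 128L) break
    }
    v
  }
  tick <- 0
  tempoBpm <- 100
  status <- 0L
  notes <- integer(); beats <- numeric(); onTick <- numeric()
  pendingNote <- NA_integer_; pendingOn <- NA_real_
  while (p <= end) {
    tick <- tick + readVlq()
    b <- as.integer(bytes[p])
    if (b >= 128L) { status <- b; p <- p + 1L } # else running status
    if (status == 255L) {  # meta event
      type <- as.integer(bytes[p]); p <- p + 1L
      len <- readVlq()
      if (type == 0x51L && len == 3L)
        tempoBpm <- 60e6 / be(bytes[p:(p + 2L)])
      p <- p + len
      if (type == 0x2FL) break
    } else if (status %in% c(240L, 247L)) {  # sysex
      len <- readVlq(); p <- p + len
    } else {
      hi <- status %/% 16L
      ndata <- if (hi %in% c(12L, 13L)) 1L else 2L
      d1 <- as.integer(bytes[p])
      d2 <- if (ndata == 2L) as.integer(bytes[p + 1L]) else NA_integer_
      p <- p + ndata
      if (hi == 9L && d2 > 0L) {          # note_on
        if (!is.na(pendingNote))
          stop("polyphonic MIDI input is not supported")
        pendingNote <- d1; pendingOn <- tick
      } else if (hi == 8L || (hi == 9L && d2 == 0L)) {  # note_off
        if (is.na(pendingNote) || pendingNote != d1)
          stop("unmatched note_off event in MIDI stream")
        notes <- c(notes, d1)
        beats <- c(beats, (tick - pendingOn) / division)
        pendingNote <- NA_integer_
      }
    }
  }
  MusicScore(notes, beats, tempo = tempoBpm, volume = volume)
}

#' Read and write MIDI files
#'
#' Thin file wrappers around [scoreToMidi()] and [midiToScore()].
#'
#' @param score a [MusicScore-class].
#' @param path file path.
#' @param ... passed on to the underlying converter.
#' @return `readMidi()` a [MusicScore-class]; `writeMidi()` the path,
#'   invisibly.
#' @export
writeMidi <- function(score, path, ...) {
  writeBin(scoreToMidi(score, ...), path)
  invisible(path)
}

#' @rdname writeMidi
#' @export
readMidi <- function(path, ...) {
  midiToScore(readBin(path, "raw", n = file.size(path)), ...)
}

## ---- WAV rendering ----

## little-endian unsigned integer encoder
uintLE <- function(x, nbytes) {
  as.raw((x %/% 256^(0:(nbytes - 1))) %% 256)
}

#' Generate the PCM samples for a score
#'
#' Each element is synthesised as a square wave at its equal-temperament
#' frequency for `beats * 60 / tempo` seconds; amplitude is
#' `10^(dBFS/20)` of full scale.
#'
#' @param score a [MusicScore-class].
#' @param sampleRate samples per second (default 44100).
#' @return Numeric vector of samples in \[-1, 1\].
#' @export
squareWaveSamples <- function(score, sampleRate = 44100L) {
  stopifnot(is(score, "MusicScore"))
  amp <- 10^(score@volume / 20)
  secPerBeat <- 60 / score@tempo
  out <- vector("list", length(score))
  for (k in seq_len(length(score))) {
    n <- round(score@beats[k] * secPerBeat * sampleRate)
    f <- noteToFrequency(score@note[k])
    t <- seq_len(n) - 1L
    out[[k]] <- amp * ifelse(((t * f / sampleRate) %% 1) < 0.5, 1, -1)
  }
  unlist(out)
}

#' Render a score as a WAV byte stream
#'
#' 16-bit PCM mono RIFF/WAVE holding the square-wave synthesis of the
#' score (see [squareWaveSamples()]). Total duration equals the sum of
#' element durations at the score's tempo.
#'
#' @param score a [MusicScore-class].
#' @param sampleRate samples per second (default 44100).
#' @return A raw vector holding the complete WAV file.
#' @seealso [writeWav()]
#' @export
renderWav <- function(score, sampleRate = 44100L) {
  sampleRate <- as.integer(sampleRate)
  stopifnot(sampleRate > 0L)
  samples <- squareWaveSamples(score, sampleRate)
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  dataLen <- 2L * length(pcm)
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw("RIFF"), con)
  writeBin(uintLE(36L + dataLen, 4L), con)
  writeBin(charToRaw("WAVE"), con)
  writeBin(charToRaw("fmt "), con)
  writeBin(uintLE(16L, 4L), con)          # chunk size
  writeBin(uintLE(1L, 2L), con)           # PCM
  writeBin(uintLE(1L, 2L), con)           # mono
  writeBin(uintLE(sampleRate, 4L), con)
  writeBin(uintLE(sampleRate * 2L, 4L), con)  # byte rate
  writeBin(uintLE(2L, 2L), con)           # block align
  writeBin(uintLE(16L, 2L), con)          # bits per sample
  writeBin(charToRaw("data"), con)
  writeBin(uintLE(dataLen, 4L), con)
  if (length(pcm)) writeBin(pcm, con, size = 2L, endian = "little")
  rawConnectionValue(con)
}

#' @rdname renderWav
#' @param path output file path.
#' @export
writeWav <- function(score, path, sampleRate = 44100L) {
  writeBin(renderWav(score, sampleRate), path)
  invisible(path)
}

## ---- noisy capture channel ----

#' Construct a noise model
#'
#' @param pSub probability an element is replaced by a different element.
#' @param pDel probability an element is deleted.
#' @param pIns probability a random element is inserted after a position.
#' @param octaveScatter probability a substitution produces an arbitrary
#'   MIDI note/duration outside the code, exercising [snapToCode()].
#' @return A [NoiseModel-class].
#' @export
noiseModel <- function(pSub = 0, pDel = 0, pIns = 0, octaveScatter = 0) {
  new("NoiseModel", pSub = as.numeric(pSub), pDel = as.numeric(pDel),
      pIns = as.numeric(pIns), octaveScatter = as.numeric(octaveScatter))
}

#' Preset noise models
#'
#' `"noisy"` emulates capture in a high-noise room (pSub 0.05, pDel 0.02,
#' pIns 0.02, octaveScatter 0.1); `"quiet"` is the identity channel (all
#' probabilities 0).
#'
#' @param name `"noisy"` or `"quiet"`.
#' @return A [NoiseModel-class].
#' @export
noisePreset <- function(name = c("noisy", "quiet")) {
  name <- match.arg(name)
  if (name == "noisy") noiseModel(0.05, 0.02, 0.02, 0.1)
  else noiseModel(0, 0, 0, 0)
}

#' Simulate the audio capture channel
#'
#' Stochastic stand-in for playing a rendered score through loudspeakers
#' and re-capturing it: per element, a deletion (`pDel`) or substitution
#' (`pSub`) may occur, and after each position a random element may be
#' inserted (`pIns`). Substitutions draw a different in-code element,
#' except with probability `octaveScatter` they draw an arbitrary MIDI
#' note and duration; every out-of-code element is passed through
#' [snapToCode()], so the output is always fully in-code. A zero-noise
#' model returns the input unchanged.
#'
#' @param score an in-code [MusicScore-class].
#' @param noise a [NoiseModel-class].
#' @param table a [CodeTable-class].
#' @param seed optional integer seed.
#' @return A [MusicScore-class] (possibly of different length).
#' @export
noisyCapture <- function(score, noise, table, seed = NULL) {
  stopifnot(is(score, "MusicScore"), is(noise, "NoiseModel"),
            is(table, "CodeTable"))
  el <- codeElements(table)
  withSeed(seed, {
    notes <- integer(); beats <- numeric()
    scatterDurations <- c(CODE_DURATIONS, 3/4, 3/8, 2)
    for (k in seq_len(length(score))) {
      u <- stats::runif(1)
      if (u < noise@pDel) {
        ## element lost
      } else if (u < noise@pDel + noise@pSub) {
        if (stats::runif(1) < noise@octaveScatter) {
          notes <- c(notes, sample(0:127, 1L))
          beats <- c(beats, sample(scatterDurations, 1L))
        } else {
          cur <- which(el$note == score@note[k] &
                         el$beats == score@beats[k])
          pick <- sample(setdiff(seq_len(64L), cur), 1L)
          notes <- c(notes, el$note[pick])
          beats <- c(beats, el$beats[pick])
        }
      } else {
        notes <- c(notes, score@note[k])
        beats <- c(beats, score@beats[k])
      }
      if (stats::runif(1) < noise@pIns) {
        pick <- sample.int(64L, 1L)
        notes <- c(notes, el$note[pick])
        beats <- c(beats, el$beats[pick])
      }
    }
    if (length(notes)) {
      sn <- snapToCode(notes, beats, table)
      MusicScore(sn$note, sn$beats, score@tempo, score@volume)
    } else {
      MusicScore(integer(), numeric(), score@tempo, score@volume)
    }
  })
}
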