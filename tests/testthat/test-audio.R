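test_that("MIDI note numbers convert to equal-temperament frequencies", {
  expect_equal(noteToFrequency(69), 440)
  expect_equal(noteToFrequency(81), 880)
  expect_equal(noteToFrequency(60), 261.6256, tolerance = 1e-3)
  expect_error(noteToFrequency(128), "0..127")
  expect_error(noteToFrequency(-1), "0..127")
})

test_that("score to MIDI round trip preserves elements and tempo", {
  s <- odeToJoyFixture()
  bytes <- scoreToMidi(s)
  s2 <- midiToScore(bytes)
  expect_identical(noteNumbers(s2), noteNumbers(s))
  expect_equal(durations(s2), durations(s))
  expect_equal(tempo(s2), 100)
  ## one note_on per element (0x90 status bytes in the stream)
  expect_identical(sum(bytes == as.raw(0x90)), length(s))
  ## files on disk too
  tf <- withr::local_tempfile(fileext = ".mid")
  writeMidi(s, tf)
  s3 <- readMidi(tf)
  expect_identical(noteNumbers(s3), noteNumbers(s))
  ## non-default tempo survives
  fast <- MusicScore(c(60L, 67L), c(1, 1/2), tempo = 150)
  expect_equal(tempo(midiToScore(scoreToMidi(fast))), 150)
})

test_that("note durations map to ticks at the configured division", {
  s <- MusicScore(60L, 1)  # one 1-beat note at 480 ticks per beat
  bytes <- scoreToMidi(s, ticksPerBeat = 480L)
  ## the delta before note_off must encode 480 = VLQ 0x83 0x60
  off <- which(bytes == as.raw(0x80))[1]
  expect_identical(bytes[(off - 2L):(off - 1L)], as.raw(c(0x83, 0x60)))
  expect_equal(durations(midiToScore(bytes)), 1)
})

test_that("malformed or unsupported MIDI input is rejected", {
  expect_error(midiToScore(charToRaw("not midi at all")), "MThd")
  s <- MusicScore(c(60L, 62L), c(1, 1))
  bytes <- scoreToMidi(s)
  bytes[12] <- as.raw(2)  # claim 2 tracks
  expect_error(midiToScore(bytes), "2 tracks")
})

test_that("WAV rendering has the right duration, level and spectrum", {
  s <- MusicScore(69L, 1/2, tempo = 120, volume = -20)  # 0.25 s of A4
  wav <- renderWav(s, sampleRate = 44100L)
  expect_identical(rawToChar(wav[1:4]), "RIFF")
  expect_identical(rawToChar(wav[9:12]), "WAVE")
  pcm <- readBin(wav[-(1:44)], "integer", n = (length(wav) - 44) / 2,
                 size = 2, signed = TRUE, endian = "little")
  expect_identical(length(pcm), as.integer(round(0.25 * 44100)))
  ## -20 dBFS -> amplitude 0.1 of full scale
  expect_equal(max(abs(pcm)) / 32767, 0.1, tolerance = 1e-3)
  ## dominant FFT peak at the fundamental (440 Hz)
  spec <- Mod(stats::fft(pcm))[1:(length(pcm) %/% 2)]
  peakHz <- (which.max(spec) - 1) * 44100 / length(pcm)
  expect_lt(abs(peakHz - 440), 5)
  ## total duration is the sum of element durations at the tempo
  s2 <- odeToJoyFixture()
  n2 <- length(squareWaveSamples(s2, 8000L))
  expect_equal(n2 / 8000, sum(durations(s2)) * 60 / tempo(s2),
               tolerance = 1e-2)
})

test_that("the zero-noise channel is the identity and full deletion empties", {
  s <- odeToJoyFixture()
  quiet <- noisePreset("quiet")
  out <- noisyCapture(s, quiet, defaultTable, seed = 1)
  expect_identical(noteNumbers(out), noteNumbers(s))
  expect_equal(durations(out), durations(s))
  allDel <- noiseModel(pDel = 1)
  expect_identical(length(noisyCapture(s, allDel, defaultTable, seed = 1)),
                   0L)
})

test_that("channel output is always in-code and element counts follow the rates", {
  s <- odeToJoyFixture()
  scatter <- noiseModel(pSub = 1, pDel = 0, pIns = 0, octaveScatter = 1)
  el <- codeElements(defaultTable)
  key <- paste(el$note, el$beats)
  set.seed(41)
  for (k in 1:10) {
    out <- noisyCapture(s, scatter, defaultTable)
    expect_true(all(paste(noteNumbers(out), durations(out)) %in% key))
  }
  noisy <- noiseModel(pSub = 0.05, pDel = 0.1, pIns = 0.05)
  lens <- replicate(200, length(noisyCapture(s, noisy, defaultTable)))
  expected <- length(s) * (1 - 0.1 + 0.05)
  expect_lt(abs(mean(lens) - expected), 1.5)  # ~4 sd of the mean
  expect_error(noiseModel(pSub = 0.7, pDel = 0.5), "exceed 1")
})
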