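test_that("translate after reverse translate is the identity on scores", {
  set.seed(11)
  for (k in 1:25) {
    s <- randomScore(sample(1:60, 1))
    dna <- reverseTranslate(s, defaultTable)
    expect_identical(nchar(dna), 4L * length(s))
    s2 <- translateDna(dna, defaultTable)
    expect_identical(noteNumbers(s2), noteNumbers(s))
    expect_equal(durations(s2), durations(s))
  }
  expect_identical(nchar(reverseTranslate(odeToJoyFixture(),
                                          defaultTable, seed = 1)), 248L)
})

test_that("codon choice is uniform over the four synonyms", {
  ## one score of 10,000 copies of a single element: elements are drawn
  ## independently left to right, so this tallies 10,000 seeded draws.
  ## (62, 1/4) has synonyms ACGA/ACGC/ACGG/ACGT, which cannot form
  ## homopolymeric tracts, so no recoding perturbs the tally.
  s <- MusicScore(rep(62L, 10000L), rep(1/4, 10000L))
  dna <- reverseTranslate(s, defaultTable, seed = 7)
  freq <- table(substring(dna, seq(1, nchar(dna), 4),
                          seq(4, nchar(dna), 4))) / 10000
  expect_length(freq, 4L)
  expect_true(all(abs(freq - 0.25) < 0.02))
})

test_that("two reverse translations agree on elements but scatter codons", {
  s <- randomScore(50)
  d1 <- reverseTranslate(s, defaultTable, seed = 1)
  d2 <- reverseTranslate(s, defaultTable, seed = 2)
  s1 <- translateDna(d1, defaultTable)
  s2 <- translateDna(d2, defaultTable)
  expect_identical(noteNumbers(s1), noteNumbers(s2))
  ## expected per-codon disagreement 3/4 under independent uniform draws
  c1 <- substring(d1, seq(1, 200, 4), seq(4, 200, 4))
  c2 <- substring(d2, seq(1, 200, 4), seq(4, 200, 4))
  expect_gt(sum(c1 != c2), 50 * 0.45)
})

test_that("homopolymer run lengths are measured correctly", {
  expect_identical(longestHomopolymer("AAAAAAA"), 7L)
  expect_identical(longestHomopolymer("ACGTACGT"), 1L)
  expect_identical(longestHomopolymer("AACCCGGGGT"), 4L)
  expect_identical(longestHomopolymer(""), 0L)
})

test_that("homopolymer recoding preserves elements and breaks runs", {
  ct <- defaultTable
  ## element with prefix AAA: codons AAAA/AAAC/AAAG/AAAT; two AAAA codons
  ## in a row form an 8-base run
  el <- decodeCodon(ct, "AAAA")
  dna <- paste0("AAAA", "AAAA", "CGCG")
  expect_gte(longestHomopolymer(dna), 7L)
  out <- recodeHomopolymers(dna, ct, seed = 3)
  expect_lt(longestHomopolymer(out), 7L)
  ## same translation
  a <- translateDna(dna, ct); b <- translateDna(out, ct)
  expect_identical(noteNumbers(a), noteNumbers(b))
  expect_equal(durations(a), durations(b))
  ## codon outside the offending run untouched
  expect_identical(substr(out, 9, 12), "CGCG")
  ## no-op on clean input
  expect_identical(recodeHomopolymers("ACGTACGT", ct), "ACGTACGT")
})

test_that("reverse translation never emits homopolymeric tracts of 7+", {
  set.seed(99)
  worst <- 0L
  for (k in 1:300) {
    s <- randomScore(sample(5:70, 1))
    worst <- max(worst, longestHomopolymer(reverseTranslate(s, defaultTable)))
  }
  ## also stress with a run-prone score: many copies of the AAA-prefix element
  el <- decodeCodon(defaultTable, "AAAA")
  s <- MusicScore(rep(el$note, 40), rep(el$beats, 40))
  for (k in 1:20)
    worst <- max(worst, longestHomopolymer(reverseTranslate(s, defaultTable)))
  expect_lte(worst, 6L)
})

test_that("translation reports frame and alphabet errors with positions", {
  expect_error(translateDna(strrep("A", 249), defaultTable), "frame")
  expect_error(translateDna("ACGX", defaultTable), "position 4")
  expect_error(reverseTranslate(MusicScore(61L, 1), defaultTable),
               "not in the code")
})

test_that("element snapping keeps pitch class and picks nearest duration", {
  ct <- defaultTable
  ## in-code element is a fixed point
  expect_equal(snapToCode(60, 1, ct), data.frame(note = 60L, beats = 1))
  ## C3 (48): nearest in-code octave of pitch class 0 is C4 (60)
  expect_identical(snapToCode(48, 1, ct)$note, 60L)
  ## C7 (96): above the code; nearest same-pitch-class is C6 (84)
  expect_identical(snapToCode(96, 1, ct)$note, 84L)
  ## pitch class absent from the code (C#): nearest note, tie to lower
  expect_identical(snapToCode(61, 1, ct)$note, 60L)
  ## durations: nearest of the four, ties to the shorter
  expect_identical(snapToCode(60, 0.6, ct)$beats, 0.5)
  expect_identical(snapToCode(60, 0.75, ct)$beats, 0.5)
  expect_identical(snapToCode(60, 5, ct)$beats, 1)
  expect_identical(snapToCode(60, 0.01, ct)$beats, 0.125)
  ## snapped scores reverse translate without error
  s <- MusicScore(c(40L, 61L, 100L), c(0.3, 0.7, 2))
  sn <- snapScore(s, ct)
  expect_silent(reverseTranslate(sn, ct, seed = 1))
})
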