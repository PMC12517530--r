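test_that("music self-alignment attains exact-match times length", {
  s <- odeToJoyFixture()
  res <- alignMusic(s, s)
  expect_identical(alignmentScore(res), 310)
  expect_true(all(alignmentStates(res) == "exact"))
  set.seed(31)
  for (k in 1:5) {
    r <- randomScore(sample(1:30, 1))
    expect_identical(alignmentScore(alignMusic(r, r)), 5 * length(r))
  }
})

test_that("music column states score exact, near, mismatch and gap correctly", {
  one <- function(note, beats) MusicScore(note, beats)
  expect_identical(alignmentScore(alignMusic(one(69L, 1), one(69L, 1))), 5)
  expect_identical(alignmentScore(alignMusic(one(69L, 1), one(69L, 1/2))), 3)
  empty <- MusicScore(integer(), numeric())
  expect_identical(alignmentScore(alignMusic(one(69L, 1), empty)), -2)
  expect_identical(alignmentScore(alignMusic(empty, empty)), 0)
  ## one exact plus one note mismatch: no gapped path beats 5 + 0
  a <- MusicScore(c(60L, 64L), c(1, 1))
  b <- MusicScore(c(60L, 67L), c(1, 1))
  res <- alignMusic(a, b)
  expect_identical(alignmentScore(res), 5)
  expect_identical(alignmentStates(res), c("exact", "mismatch"))
})

test_that("music aligner equals the exhaustive-enumeration oracle on small scores", {
  set.seed(32)
  for (k in 1:40) {
    a <- randomScore(sample(0:4, 1))
    b <- randomScore(sample(0:4, 1))
    expect_identical(alignmentScore(alignMusic(a, b)),
                     bruteMusicScore(a, b))
  }
})

test_that("music alignment score is symmetric and reversal-invariant", {
  revScore <- function(s) MusicScore(rev(noteNumbers(s)), rev(durations(s)))
  set.seed(33)
  for (k in 1:10) {
    a <- randomScore(sample(1:15, 1))
    b <- randomScore(sample(1:15, 1))
    sc <- alignmentScore(alignMusic(a, b))
    expect_identical(alignmentScore(alignMusic(b, a)), sc)
    expect_identical(alignmentScore(alignMusic(revScore(a), revScore(b))), sc)
  }
})

test_that("a single note substitution costs at most exact minus mismatch", {
  set.seed(34)
  for (k in 1:10) {
    a <- randomScore(sample(3:20, 1))
    b <- mutateMusic(a, defaultTable)
    drop <- alignmentScore(alignMusic(a, a)) -
      alignmentScore(alignMusic(a, b))
    expect_lte(drop, 5)
    expect_gte(drop, 0)
  }
})

test_that("DNA alignment reproduces needle-default scores", {
  expect_identical(alignmentScore(alignDna("ACGT", "ACGA")), 11)
  L <- 30
  a <- randomDna(L)
  expect_identical(alignmentScore(alignDna(a, a)), 5 * L)
  b <- randomDna(25)
  expect_identical(alignmentScore(alignDna(a, b)),
                   alignmentScore(alignDna(b, a)))
  expect_error(alignDna("ACGU", "ACGT"), "position 4")
})

test_that("DNA aligner equals the affine-gap enumeration oracle on small inputs", {
  set.seed(35)
  for (k in 1:40) {
    a <- randomDna(sample(1:4, 1))
    b <- randomDna(sample(1:4, 1))
    expect_equal(alignmentScore(alignDna(a, b)), bruteDnaScore(a, b))
  }
})

test_that("delta-score is zero on identity and nine per substitution", {
  a <- randomDna(40)
  expect_identical(deltaScore(a, a), 0)
  b <- a
  substr(b, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                               substr(a, 10, 10))[1]
  expect_identical(deltaScore(a, b), 9)
  ## non-negative for any equal-length winner
  set.seed(36)
  for (k in 1:10) {
    w <- randomDna(40)
    expect_gte(deltaScore(a, w), 0)
  }
})

test_that("alignment rendering produces three aligned rows", {
  a <- MusicScore(c(60L, 64L), c(1, 1))
  b <- MusicScore(c(60L, 67L), c(1, 1))
  rows <- renderAlignment(alignMusic(a, b), a, b)
  expect_length(rows, 3L)
  dres <- alignDna("ACGT", "ACGA")
  rows <- renderAlignment(dres, "ACGT", "ACGA")
  expect_length(rows, 3L)
})
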