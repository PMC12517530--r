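test_that("Hamming distance counts differing positions and checks lengths", {
  expect_identical(hammingDistance("ACGT", "ACGT"), 0L)
  expect_identical(hammingDistance("AAAA", "AAAT"), 1L)
  expect_identical(hammingDistance("ACGT", "TGCA"), 4L)
  expect_error(hammingDistance("ACGT", "ACG"), "different lengths")
})

test_that("synonymous DNA mutation is a single silent point change at the wobble site", {
  set.seed(5)
  for (k in 1:20) {
    s <- randomScore(sample(3:40, 1))
    dna <- reverseTranslate(s, defaultTable)
    out <- mutateSynonymousDna(dna, defaultTable)
    expect_identical(hammingDistance(dna, out), 1L)
    a <- translateDna(dna, defaultTable); b <- translateDna(out, defaultTable)
    expect_identical(noteNumbers(a), noteNumbers(b))
    expect_equal(durations(a), durations(b))
    pos <- which(strsplit(dna, "")[[1]] != strsplit(out, "")[[1]])
    expect_identical(pos %% 4L, 0L)  # wobble = codon position 4
  }
})

test_that("nonsynonymous DNA mutation changes exactly one codon and one element", {
  set.seed(6)
  for (k in 1:20) {
    s <- randomScore(sample(3:40, 1))
    dna <- reverseTranslate(s, defaultTable)
    out <- mutateNonsynonymousDna(dna, defaultTable)
    d <- hammingDistance(dna, out)
    expect_true(d >= 1L && d <= 4L)
    n <- nchar(dna)
    c1 <- substring(dna, seq(1, n, 4), seq(4, n, 4))
    c2 <- substring(out, seq(1, n, 4), seq(4, n, 4))
    expect_identical(sum(c1 != c2), 1L)
    a <- translateDna(dna, defaultTable); b <- translateDna(out, defaultTable)
    expect_identical(
      sum(noteNumbers(a) != noteNumbers(b) | durations(a) != durations(b)),
      1L)
  }
})

test_that("point mutation hits one base and is synonymous a quarter of the time", {
  set.seed(7)
  dna <- reverseTranslate(randomScore(30), defaultTable)
  syn <- 0L; n <- 4000L
  for (k in seq_len(n)) {
    out <- mutatePointDna(dna)
    expect_identical(hammingDistance(dna, out), 1L)
    a <- translateDna(dna, defaultTable); b <- translateDna(out, defaultTable)
    if (all(noteNumbers(a) == noteNumbers(b)) &&
        all(durations(a) == durations(b))) syn <- syn + 1L
  }
  ## only wobble-position hits (prob 1/4) are synonymous under this code
  expect_lt(abs(syn / n - 0.25), 0.02)
})

test_that("music mutation swaps exactly one element for a different one", {
  set.seed(8)
  for (k in 1:20) {
    s <- randomScore(sample(2:40, 1))
    out <- mutateMusic(s, defaultTable)
    expect_identical(length(out), length(s))
    expect_identical(
      sum(noteNumbers(s) != noteNumbers(out) |
            durations(s) != durations(out)), 1L)
  }
})

test_that("regime specifications match the six-regime design", {
  expect_identical(regimeSpec(1)[c("dnaAction", "musicAction")],
                   list(dnaAction = "none", musicAction = "none"))
  expect_identical(regimeSpec(2)$dnaAction, "synonymous")
  expect_identical(regimeSpec(3)$dnaAction, "nonsynonymous")
  expect_identical(regimeSpec(4)$dnaAction, "random_point")
  expect_identical(regimeSpec(5)[c("dnaAction", "musicAction")],
                   list(dnaAction = "none", musicAction = "nonsynonymous"))
  expect_identical(regimeSpec(6)[c("dnaAction", "musicAction")],
                   list(dnaAction = "nonsynonymous",
                        musicAction = "nonsynonymous"))
  expect_error(regimeSpec(7), "1..6")
})

test_that("simulations tally events exactly and conserve lengths", {
  anc <- odeToJoyFixture()
  for (rg in c(2L, 3L, 6L)) {
    tr <- runSimulation(anc, rg, generations = 5, replicates = 2,
                        table = defaultTable, seed = 20 + rg)
    for (t in tr) {
      ev <- eventTally(t)
      totals <- colSums(ev)
      expected <- c(synonymous = 0, nonsynonymous_dna = 0,
                    nonsynonymous_music = 0, point = 0)
      if (rg == 2L) expected["synonymous"] <- 5
      if (rg %in% c(3L, 6L)) expected["nonsynonymous_dna"] <- 5
      if (rg == 6L) expected["nonsynonymous_music"] <- 5
      expect_identical(totals, expected)
      expect_true(all(nchar(t@dna) == nchar(ancestorDna(t))))
      expect_true(all(vapply(t@scores, length, integer(1)) == length(anc)))
      expect_identical(hammingTrajectory(t),
                       vapply(t@dna, hammingDistance, integer(1),
                              x = ancestorDna(t), USE.NAMES = FALSE))
    }
  }
})

test_that("simulations are reproducible from the master seed", {
  anc <- odeToJoyFixture()
  a <- runSimulation(anc, 4, generations = 4, replicates = 3,
                     table = defaultTable, seed = 77)
  b <- runSimulation(anc, 4, generations = 4, replicates = 3,
                     table = defaultTable, seed = 77)
  expect_identical(lapply(a, function(t) t@dna),
                   lapply(b, function(t) t@dna))
  expect_identical(tracesToTable(a), tracesToTable(b))
})

test_that("trace summaries average over replicates and reject ragged input", {
  anc <- odeToJoyFixture()
  tr <- runSimulation(anc, 1, generations = 3, replicates = 4,
                      table = defaultTable, seed = 2)
  sm <- summarizeTraces(tr)
  expect_identical(names(sm), c("regime", "generation", "mean_hamming"))
  expect_identical(sm$mean_hamming,
                   colMeans(do.call(rbind, lapply(tr, hammingTrajectory))))
  expect_identical(summarizeTraces(tr[[1]])$mean_hamming,
                   as.numeric(hammingTrajectory(tr[[1]])))
  short <- runSimulation(anc, 1, generations = 2, replicates = 1,
                         table = defaultTable, seed = 3)
  expect_error(summarizeTraces(c(tr, short)), "ragged")
})

test_that("regime 1 plateaus at three quarters of the codon count", {
  anc <- odeToJoyFixture()
  tr <- runSimulation(anc, 1, generations = 5, replicates = 10,
                      table = defaultTable, seed = 123)
  sm <- summarizeTraces(tr)
  ## each generation re-draws all 62 codons: E[hamming] = 0.75 * 62
  expect_true(all(abs(sm$mean_hamming - 46.5) < 5))
})
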