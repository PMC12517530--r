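#' Hamming distance between equal-length DNA sequences
#'
#' Counts the positions at which two sequences carry different bases.
#' Suitable for the mutational regimes here because none of them generate
#' indels, so sequence length is constant across generations.
#'
#' @param x,y DNA strings of equal length.
#' @return Integer count of differing positions.
#' @examples
#' hammingDistance("ACGT", "TGCA")  # 4
#' @export
hammingDistance <- function(x, y) {
  x <- checkDna(x); y <- checkDna(y)
  if (nchar(x) != nchar(y))
    stop(sprintf("sequences have different lengths (%d vs %d)",
                 nchar(x), nchar(y)))
  if (nchar(x) == 0L) return(0L)
  sum(utf8ToInt(x) != utf8ToInt(y))
}

#' Single-site mutation operators
#'
#' Each operator applies exactly one mutational event to a sequence or
#' score, drawing uniformly at random:
#'
#' * `mutateSynonymousDna()` replaces one randomly chosen codon by one of
#'   its 3 synonymous alternatives. Because synonymous codons differ at
#'   exactly one nucleotide, this introduces a single synonymous point
#'   mutation; the translated score is unchanged.
#' * `mutateNonsynonymousDna()` replaces one randomly chosen codon by a
#'   codon of a different element (uniform over the 252 foreign codons);
#'   the translated score changes at exactly one element.
#' * `mutatePointDna()` changes one randomly chosen nucleotide to one of
#'   the 3 alternative bases; under the wobble code this is synonymous
#'   with probability 1/4 (a hit at codon position 4) and nonsynonymous
#'   otherwise.
#' * `mutateMusic()` replaces one randomly chosen score element by a
#'   different element (uniform over the other 63) — a nonsynonymous
#'   phenotype-level mutation.
#'
#' @param dna a framed DNA string decoding under `table`.
#' @param score a non-empty in-code [MusicScore-class].
#' @param table a [CodeTable-class].
#' @param seed optional integer seed (caller's RNG state preserved).
#' @return The mutated DNA string or [MusicScore-class].
#' @name mutation-operators
#' @examples
#' ct <- buildDefaultCodeTable()
#' dna <- reverseTranslate(odeToJoyFixture(), ct, seed = 1)
#' hammingDistance(dna, mutateSynonymousDna(dna, ct, seed = 2))  # 1
NULL

#' @rdname mutation-operators
#' @export
mutateSynonymousDna <- function(dna, table, seed = NULL) {
  dna <- checkDna(dna, requireFrame = TRUE)
  stopifnot(is(table, "CodeTable"), nchar(dna) > 0L)
  synMat <- synonymMatrix(table)
  cods <- splitCodons(dna)
  ei <- codonElementIndex(table, cods)
  if (anyNA(ei)) stop("sequence does not decode under the code table")
  withSeed(seed, {
    s <- sample.int(length(cods), 1L)
    alt <- setdiff(synMat[ei[s], ], cods[s])
    cods[s] <- alt[sample.int(length(alt), 1L)]
    paste(cods, collapse = "")
  })
}

#' @rdname mutation-operators
#' @export
mutateNonsynonymousDna <- function(dna, table, seed = NULL) {
  dna <- checkDna(dna, requireFrame = TRUE)
  stopifnot(is(table, "CodeTable"), nchar(dna) > 0L)
  cods <- splitCodons(dna)
  ei <- codonElementIndex(table, cods)
  if (anyNA(ei)) stop("sequence does not decode under the code table")
  allEi <- codonElementIndex(table, table@codon)
  withSeed(seed, {
    s <- sample.int(length(cods), 1L)
    foreign <- table@codon[allEi != ei[s]]
    cods[s] <- foreign[sample.int(length(foreign), 1L)]
    paste(cods, collapse = "")
  })
}

#' @rdname mutation-operators
#' @export
mutatePointDna <- function(dna, seed = NULL) {
  dna <- checkDna(dna)
  stopifnot(nchar(dna) > 0L)
  withSeed(seed, {
    pos <- sample.int(nchar(dna), 1L)
    cur <- substr(dna, pos, pos)
    alt <- setdiff(DNA_BASES, cur)
    substr(dna, pos, pos) <- alt[sample.int(3L, 1L)]
    dna
  })
}

#' @rdname mutation-operators
#' @export
mutateMusic <- function(score, table, seed = NULL) {
  stopifnot(is(score, "MusicScore"), is(table, "CodeTable"),
            length(score) > 0L)
  ei <- scoreElementIndex(score, table)
  el <- codeElements(table)
  withSeed(seed, {
    s <- sample.int(length(score), 1L)
    other <- setdiff(seq_len(64L), ei[s])
    pick <- other[sample.int(63L, 1L)]
    score@note[s] <- el$note[pick]
    score@beats[s] <- el$beats[pick]
    validObject(score)
    score
  })
}

#' Mutational regime specifications
#'
#' The six regimes pair a DNA-level action (applied after each
#' generation's reverse translation) with a music-level action (applied
#' after each generation's translation):
#'
#' | id | name | DNA action | music action |
#' |----|------|-----------|--------------|
#' | 1 | zero mutation | none | none |
#' | 2 | synonymous DNA-level | one synonymous codon swap | none |
#' | 3 | nonsynonymous DNA-level | one nonsynonymous codon swap | none |
#' | 4 | random DNA-level | one random point mutation | none |
#' | 5 | nonsynonymous music-level | none | one element swap |
#' | 6 | nonsynonymous DNA + music | one nonsynonymous codon swap | one element swap |
#'
#' @param id integer regime id, 1-6.
#' @return A list with components `id`, `name`, `dnaAction`
#'   (`"none"`, `"synonymous"`, `"nonsynonymous"` or `"random_point"`) and
#'   `musicAction` (`"none"` or `"nonsynonymous"`).
#' @export
regimeSpec <- function(id) {
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 1L || id > 6L)
    stop("regime id must be an integer in 1..6")
  specs <- list(
    list(id = 1L, name = "zero mutation",
         dnaAction = "none", musicAction = "none"),
    list(id = 2L, name = "synonymous DNA-level mutation",
         dnaAction = "synonymous", musicAction = "none"),
    list(id = 3L, name = "nonsynonymous DNA-level mutation",
         dnaAction = "nonsynonymous", musicAction = "none"),
    list(id = 4L, name = "random DNA-level mutation",
         dnaAction = "random_point", musicAction = "none"),
    list(id = 5L, name = "nonsynonymous music-level mutation",
         dnaAction = "none", musicAction = "nonsynonymous"),
    list(id = 6L, name = "nonsynonymous DNA-level plus music-level mutation",
         dnaAction = "nonsynonymous", musicAction = "nonsynonymous"))
  specs[[id]]
}

#' Simulate mutation accumulation under a regime
#'
#' Runs replicate lineages of the bidirectional inheritance cycle for a
#' fixed number of generations. Per replicate, the ancestor DNA is a
#' single reverse translation of the unmutated ancestor score. Each
#' generation then performs, in order: reverse translation of the current
#' score (fresh random synonymous codons — no codon memory), the regime's
#' DNA-level action, translation back to a score, and the regime's
#' music-level action. The Hamming distance between the generation's DNA
#' and the ancestor DNA is recorded, together with a tally of mutation
#' events.
#'
#' Because reverse translation re-draws every codon, synonymous DNA
#' mutations leave no trace in the next generation, while nonsynonymous
#' changes (at either level) accumulate.
#'
#' @param ancestorScore the ancestral [MusicScore-class] (all elements
#'   in-code).
#' @param regime a regime id 1-6 or a [regimeSpec()] list.
#' @param generations number of generations per replicate (default 20).
#' @param replicates number of independent replicate lineages (default 10).
#' @param table a [CodeTable-class].
#' @param seed optional master seed; per-replicate streams are spawned
#'   from it so each replicate is independently reproducible.
#' @return A list of [EvolutionTrace-class], one per replicate.
#' @examples
#' ct <- buildDefaultCodeTable()
#' tr <- runSimulation(odeToJoyFixture(), 3, generations = 5,
#'                     replicates = 2, table = ct, seed = 1)
#' hammingTrajectory(tr[[1]])
#' @export
runSimulation <- function(ancestorScore, regime, generations = 20L,
                          replicates = 10L,
                          table = buildDefaultCodeTable(), seed = NULL) {
  stopifnot(is(ancestorScore, "MusicScore"), is(table, "CodeTable"))
  generations <- as.integer(generations)
  replicates <- as.integer(replicates)
  stopifnot(generations >= 1L, replicates >= 1L)
  if (!is.list(regime)) regime <- regimeSpec(regime)
  evTypes <- c("synonymous", "nonsynonymous_dna", "nonsynonymous_music",
               "point")
  withSeed(seed, {
    subseeds <- spawnSeeds(replicates)
    lapply(seq_len(replicates), function(r) {
      set.seed(subseeds[r])
      anc <- reverseTranslate(ancestorScore, table)
      score <- ancestorScore
      dnaG <- character(generations)
      hamG <- integer(generations)
      scoresG <- vector("list", generations)
      ev <- matrix(0L, generations, 4L, dimnames = list(NULL, evTypes))
      for (g in seq_len(generations)) {
        dna <- reverseTranslate(score, table)
        if (regime$dnaAction == "synonymous") {
          dna <- mutateSynonymousDna(dna, table)
          ev[g, "synonymous"] <- 1L
        } else if (regime$dnaAction == "nonsynonymous") {
          dna <- mutateNonsynonymousDna(dna, table)
          ev[g, "nonsynonymous_dna"] <- 1L
        } else if (regime$dnaAction == "random_point") {
          dna <- mutatePointDna(dna)
          ev[g, "point"] <- 1L
        }
        score <- translateDna(dna, table,
                              tempo = ancestorScore@tempo,
                              volume = ancestorScore@volume)
        if (regime$musicAction == "nonsynonymous") {
          score <- mutateMusic(score, table)
          ev[g, "nonsynonymous_music"] <- 1L
        }
        dnaG[g] <- dna
        hamG[g] <- hammingDistance(anc, dna)
        scoresG[[g]] <- score
      }
      new("EvolutionTrace", regime = regime$id, replicate = r,
          ancestorDna = anc, dna = dnaG, scores = scoresG,
          hamming = hamG, events = ev)
    })
  })
}

#' Summarise replicate traces
#'
#' Mean Hamming distance to the ancestor at each generation, averaged over
#' replicates (long-format table, one row per regime x generation).
#'
#' @param traces a list of [EvolutionTrace-class] of equal length
#'   (generations), e.g. from [runSimulation()].
#' @return A data.frame with columns `regime`, `generation`,
#'   `mean_hamming`.
#' @export
summarizeTraces <- function(traces) {
  if (is(traces, "EvolutionTrace")) traces <- list(traces)
  stopifnot(is.list(traces), length(traces) > 0L,
            all(vapply(traces, is, logical(1), "EvolutionTrace")))
  gens <- vapply(traces, function(tr) length(tr@hamming), integer(1))
  if (length(unique(gens)) != 1L)
    stop("traces have unequal generation counts (ragged input)")
  regs <- vapply(traces, function(tr) tr@regime, integer(1))
  out <- do.call(rbind, lapply(sort(unique(regs)), function(rg) {
    m <- do.call(rbind, lapply(traces[regs == rg],
                               function(tr) tr@hamming))
    data.frame(regime = rg, generation = seq_len(ncol(m)),
               mean_hamming = colMeans(m))
  }))
  rownames(out) <- NULL
  out
}

#' Generation-g Hamming distances across replicates
#'
#' @param traces a list of [EvolutionTrace-class].
#' @param generation which generation to extract (default: the last).
#' @return Numeric vector, one distance per replicate.
#' @export
generationHamming <- function(traces, generation = NULL) {
  if (is(traces, "EvolutionTrace")) traces <- list(traces)
  vapply(traces, function(tr) {
    g <- if (is.null(generation)) length(tr@hamming) else generation
    as.numeric(tr@hamming[g])
  }, numeric(1))
}

#' Export traces as a long-format table
#'
#' One row per replicate x generation with the Hamming distance and the
#' per-generation event tallies; the TSV layout used by the command-line
#' `simulate` subcommand.
#'
#' @param traces a list of [EvolutionTrace-class].
#' @return A data.frame with columns `regime`, `replicate`, `generation`,
#'   `hamming`, `events_syn`, `events_nonsyn_dna`, `events_nonsyn_music`,
#'   `events_point`.
#' @export
tracesToTable <- function(traces) {
  if (is(traces, "EvolutionTrace")) traces <- list(traces)
  out <- do.call(rbind, lapply(traces, function(tr) {
    g <- length(tr@hamming)
    data.frame(regime = tr@regime, replicate = tr@replicate,
               generation = seq_len(g), hamming = tr@hamming,
               events_syn = tr@events[, "synonymous"],
               events_nonsyn_dna = tr@events[, "nonsynonymous_dna"],
               events_nonsyn_music = tr@events[, "nonsynonymous_music"],
               events_point = tr@events[, "point"])
  }))
  rownames(out) <- NULL
  out
}
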