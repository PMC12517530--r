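#' Generate a chained series of noisy variants
#'
#' Variant 1 is one pass of the capture channel over the progenitor;
#' variant k is one pass over variant k-1. Because each pass adds edits,
#' the series carries successively more mutation — the construction used
#' to offer a selection panel versions with different mutational loads.
#'
#' @param progenitor an in-code [MusicScore-class].
#' @param n number of variants (default 5).
#' @param noise a [NoiseModel-class].
#' @param table a [CodeTable-class].
#' @param seed optional integer seed.
#' @return A list of `n` [MusicScore-class] objects.
#' @export
generateVariantSeries <- function(progenitor, n = 5L, noise, table,
                                  seed = NULL) {
  stopifnot(is(progenitor, "MusicScore"), n >= 1L)
  withSeed(seed, {
    out <- vector("list", n)
    cur <- progenitor
    for (k in seq_len(n)) {
      cur <- noisyCapture(cur, noise, table)
      out[[k]] <- cur
    }
    out
  })
}

#' Purifying (panel-proxy) selection
#'
#' Selects the variant most similar to the ancestor under the music
#' alignment score — the executable proxy for a listener panel that
#' consistently prefers the least mutated version. Ties go to the lowest
#' index.
#'
#' @param variants list of [MusicScore-class] candidates.
#' @param ancestor the reference [MusicScore-class].
#' @param scheme a [musicScoringScheme()].
#' @return Integer index of the winning variant.
#' @export
selectPurifying <- function(variants, ancestor,
                            scheme = musicScoringScheme()) {
  stopifnot(is.list(variants), length(variants) >= 1L)
  sc <- vapply(variants, function(v)
    alignmentScore(alignMusic(v, ancestor, scheme)), numeric(1))
  which.max(sc)  # which.max takes the first maximum: lowest index on ties
}

#' Random (neutral) selection
#'
#' Selects a variant uniformly at random, independent of content — the
#' neutral-evolution control arm.
#'
#' @param variants list of candidates.
#' @param seed optional integer seed.
#' @return Integer index of the selected variant.
#' @export
selectRandom <- function(variants, seed = NULL) {
  stopifnot(is.list(variants), length(variants) >= 1L)
  withSeed(seed, sample.int(length(variants), 1L))
}

#' Run rounds of evolution with selection
#'
#' Repeats, for `rounds` rounds: generate `nVariants` chained noisy
#' variants of the current progenitor, select a winner (purifying
#' panel-proxy or random), and record (i) the DNA delta-score of the
#' winner against the round's progenitor and (ii) the winner's music
#' alignment score against the original ancestor. The winner becomes the
#' next round's progenitor.
#'
#' DNA sequences are produced by fresh reverse translation (as in the
#' live system, where each round's winner is re-encoded before
#' synthesis), so synonymous codon scatter contributes to the DNA
#' delta-score but never to the music score.
#'
#' @param ancestor an in-code [MusicScore-class].
#' @param rounds number of rounds (default 4).
#' @param strategy `"purifying"` or `"random"`.
#' @param nVariants variants per round (default 5).
#' @param noise a [NoiseModel-class] (default: the `"noisy"` preset).
#' @param table a [CodeTable-class].
#' @param seed optional master seed. Variant generation consumes
#'   per-round sub-seeds drawn first, and random selection a second,
#'   independent set, so runs under the two strategies with the same
#'   master seed see identical round-1 variant streams.
#' @param scheme a [musicScoringScheme()] for the panel proxy and the
#'   ancestor comparison.
#' @return A data.frame with one row per round: `round`, `strategy`,
#'   `winner` (index), `delta_dna` and `music_score_vs_ancestor`, with the
#'   winning scores attached as attribute `"winners"` (a list of
#'   [MusicScore-class]).
#' @examples
#' ct <- buildDefaultCodeTable()
#' rr <- runRounds(odeToJoyFixture(), rounds = 2, strategy = "purifying",
#'                 table = ct, seed = 1)
#' rr$music_score_vs_ancestor
#' @export
runRounds <- function(ancestor, rounds = 4L,
                      strategy = c("purifying", "random"),
                      nVariants = 5L, noise = noisePreset("noisy"),
                      table = buildDefaultCodeTable(), seed = NULL,
                      scheme = musicScoringScheme()) {
  stopifnot(is(ancestor, "MusicScore"), rounds >= 1L, nVariants >= 1L)
  strategy <- match.arg(strategy)
  withSeed(seed, {
    variantSeeds <- spawnSeeds(rounds)
    selectionSeeds <- spawnSeeds(rounds)
    rtSeeds <- spawnSeeds(rounds + 1L)
    prog <- ancestor
    progDna <- reverseTranslate(prog, table, seed = rtSeeds[1L])
    winners <- vector("list", rounds)
    out <- data.frame(round = seq_len(rounds), strategy = strategy,
                      winner = NA_integer_, delta_dna = NA_real_,
                      music_score_vs_ancestor = NA_real_)
    for (r in seq_len(rounds)) {
      variants <- generateVariantSeries(prog, nVariants, noise, table,
                                        seed = variantSeeds[r])
      w <- if (strategy == "purifying")
        selectPurifying(variants, ancestor, scheme)
      else
        selectRandom(variants, seed = selectionSeeds[r])
      winner <- variants[[w]]
      if (length(winner) == 0L)
        stop(sprintf("round %d winner is an empty score; channel too lossy",
                     r))
      winnerDna <- reverseTranslate(winner, table, seed = rtSeeds[r + 1L])
      out$winner[r] <- w
      out$delta_dna[r] <- deltaScore(progDna, winnerDna)
      out$music_score_vs_ancestor[r] <-
        alignmentScore(alignMusic(winner, ancestor, scheme))
      winners[[r]] <- winner
      prog <- winner
      progDna <- winnerDna
    }
    attr(out, "winners") <- winners
    out
  })
}
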