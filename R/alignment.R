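#' Scoring scheme for music-score alignment
#'
#' The global aligner scores each column as: exact match (same note, same
#' duration), near match (same note, different duration), mismatch
#' (different note, regardless of duration), or gap (insertion/deletion).
#' Defaults: exact 5, near 3, mismatch 0, gap -2.
#'
#' @param exact,near,mismatch numeric column scores.
#' @param gap numeric gap penalty (typically negative).
#' @return A named list of class checked by [alignMusic()].
#' @export
musicScoringScheme <- function(exact = 5, near = 3, mismatch = 0,
                               gap = -2) {
  list(exact = as.numeric(exact), near = as.numeric(near),
       mismatch = as.numeric(mismatch), gap = as.numeric(gap))
}

#' Global alignment of two music scores
#'
#' Needleman-Wunsch global alignment over note/duration elements with
#' linear gap penalties under a [musicScoringScheme()]. With the default
#' scheme, a score aligned against itself attains `5 * length` — the
#' maximum similarity score used as the self-comparison baseline.
#' Traceback ties are broken deterministically (diagonal, then gap in the
#' right score, then gap in the left score); the optimal score itself is
#' unique.
#'
#' @param a,b [MusicScore-class] objects (may be empty; elements need not
#'   be in-code).
#' @param scheme a [musicScoringScheme()].
#' @return An [AlignmentResult-class] with per-column states in
#'   `{"exact", "near", "mismatch", "gap"}`.
#' @examples
#' s <- odeToJoyFixture()
#' alignmentScore(alignMusic(s, s))  # 310 = 5 * 62
#' @export
alignMusic <- function(a, b, scheme = musicScoringScheme()) {
  stopifnot(is(a, "MusicScore"), is(b, "MusicScore"))
  stopifnot(all(c("exact", "near", "mismatch", "gap") %in% names(scheme)))
  n <- length(a); m <- length(b)
  ## column score for element i of a vs element j of b
  colScore <- function(i, j) {
    if (a@note[i] != b@note[j]) return(scheme$mismatch)
    if (a@beats[i] == b@beats[j]) scheme$exact else scheme$near
  }
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- scheme$gap * (0:n)
  S[1L, ] <- scheme$gap * (0:m)
  if (n && m) {
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        S[i + 1L, j + 1L] <- max(S[i, j] + colScore(i, j),
                                 S[i, j + 1L] + scheme$gap,
                                 S[i + 1L, j] + scheme$gap)
      }
    }
  }
  ## traceback: prefer diagonal, then up (gap in b), then left (gap in a)
  pairs <- matrix(NA_integer_, 0L, 2L)
  states <- character()
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + colScore(i, j)) {
      st <- if (a@note[i] != b@note[j]) "mismatch"
            else if (a@beats[i] == b@beats[j]) "exact" else "near"
      pairs <- rbind(c(i, j), pairs)
      states <- c(st, states)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L &&
               S[i + 1L, j + 1L] == S[i, j + 1L] + scheme$gap) {
      pairs <- rbind(c(i, NA_integer_), pairs)
      states <- c("gap", states)
      i <- i - 1L
    } else {
      pairs <- rbind(c(NA_integer_, j), pairs)
      states <- c("gap", states)
      j <- j - 1L
    }
  }
  colnames(pairs) <- c("left", "right")
  new("AlignmentResult", score = S[n + 1L, m + 1L], pairs = pairs,
      states = states)
}

#' Global alignment of two DNA sequences (needle-style)
#'
#' Affine-gap global alignment with the EMBOSS-needle default nucleotide
#' scoring: match +5, mismatch -4 (EDNAFULL), gap opening 10 and gap
#' extension 0.5 (a gap of length L costs `opening + L * extension`;
#' terminal gaps are penalised). The computation is delegated to
#' `Biostrings::pairwiseAlignment()`.
#'
#' @param a,b non-empty DNA strings (or `Biostrings::DNAString`s).
#' @param match,mismatch substitution scores.
#' @param gapOpening,gapExtension affine gap parameters.
#' @return An [AlignmentResult-class] with per-column states in
#'   `{"match", "mismatch", "gap"}`.
#' @examples
#' alignmentScore(alignDna("ACGT", "ACGA"))  # 11
#' @export
alignDna <- function(a, b, match = 5, mismatch = -4, gapOpening = 10,
                     gapExtension = 0.5) {
  a <- checkDna(a, what = "left sequence")
  b <- checkDna(b, what = "right sequence")
  if (!nchar(a) || !nchar(b))
    stop("DNA alignment requires non-empty sequences")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  pwa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = mat, gapOpening = gapOpening,
    gapExtension = gapExtension, type = "global")
  ga <- strsplit(as.character(Biostrings::pattern(pwa)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::subject(pwa)), "")[[1]]
  li <- cumsum(ga != "-"); li[ga == "-"] <- NA_integer_
  ri <- cumsum(gb != "-"); ri[gb == "-"] <- NA_integer_
  states <- ifelse(ga == "-" | gb == "-", "gap",
                   ifelse(ga == gb, "match", "mismatch"))
  pairs <- cbind(left = as.integer(li), right = as.integer(ri))
  new("AlignmentResult", score = Biostrings::score(pwa), pairs = pairs,
      states = states)
}

#' Delta-score of a round winner against its progenitor
#'
#' The drop in global DNA alignment score relative to the progenitor's
#' self-alignment: `score(progenitor, progenitor) - score(progenitor,
#' winner)`. Zero iff the winner's DNA equals the progenitor's; for an
#' equal-length winner each substituted base contributes
#' `match - mismatch` (9 under the default scheme).
#'
#' @param progenitor,winner non-empty DNA strings.
#' @param ... passed to [alignDna()].
#' @return A single number (>= 0 for substitution-only divergence).
#' @examples
#' deltaScore("ACGTACGT", "ACGTACGA")  # 9
#' @export
deltaScore <- function(progenitor, winner, ...) {
  alignmentScore(alignDna(progenitor, progenitor, ...)) -
    alignmentScore(alignDna(progenitor, winner, ...))
}

#' Render an alignment as three text rows
#'
#' Human-readable rendering: left indices/elements, a match line
#' (`|` exact/match, `:` near, `.` mismatch, space for gap), and the right
#' row. Used by the command-line alignment subcommands.
#'
#' @param result an [AlignmentResult-class].
#' @param a,b the two aligned objects ([MusicScore-class] or DNA strings).
#' @return Character vector of three lines.
#' @export
renderAlignment <- function(result, a, b) {
  stopifnot(is(result, "AlignmentResult"))
  fmt <- function(x, idx) {
    if (is(x, "MusicScore")) {
      ifelse(is.na(idx), "----",
             sprintf("%d/%s", x@note[pmax(idx, 1L)],
                     format(x@beats[pmax(idx, 1L)])))
    } else {
      chars <- strsplit(as.character(x), "")[[1]]
      ifelse(is.na(idx), "-", chars[pmax(idx, 1L)])
    }
  }
  top <- fmt(a, result@pairs[, 1L])
  bot <- fmt(b, result@pairs[, 2L])
  w <- pmax(nchar(top), nchar(bot))
  mid <- c(exact = "|", match = "|", near = ":", mismatch = ".",
           gap = " ")[result@states]
  pad <- function(s) formatC(s, width = max(w), flag = "-")
  c(paste(pad(top), collapse = " "),
    paste(pad(mid), collapse = " "),
    paste(pad(bot), collapse = " "))
}
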