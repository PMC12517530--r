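## Shared fixtures and brute-force oracles for the alignment operations.

defaultTable <- buildDefaultCodeTable()

## Random in-code score of n elements (uniform over the 64 elements).
randomScore <- function(n, table = defaultTable) {
  el <- codeElements(table)
  pick <- sample.int(64L, n, replace = TRUE)
  MusicScore(el$note[pick], el$beats[pick])
}

## Enumerate every global alignment of lengths (n, m) as a matrix of
## moves ("D" diagonal, "U" gap in right/consume left, "L" gap in left).
enumeratePaths <- function(n, m) {
  recurse <- function(i, j) {
    if (i == 0L && j == 0L) return(list(character()))
    out <- list()
    if (i > 0L && j > 0L)
      out <- c(out, lapply(recurse(i - 1L, j - 1L), c, "D"))
    if (i > 0L)
      out <- c(out, lapply(recurse(i - 1L, j), c, "U"))
    if (j > 0L)
      out <- c(out, lapply(recurse(i, j - 1L), c, "L"))
    out
  }
  recurse(n, m)
}

## Brute-force optimal music alignment score (linear gap penalty).
bruteMusicScore <- function(a, b, scheme = musicScoringScheme()) {
  an <- noteNumbers(a); ab <- durations(a)
  bn <- noteNumbers(b); bb <- durations(b)
  best <- -Inf
  for (path in enumeratePaths(length(an), length(bn))) {
    i <- 0L; j <- 0L; sc <- 0
    for (mv in path) {
      if (mv == "D") {
        i <- i + 1L; j <- j + 1L
        sc <- sc + if (an[i] != bn[j]) scheme$mismatch
                   else if (ab[i] == bb[j]) scheme$exact else scheme$near
      } else if (mv == "U") { i <- i + 1L; sc <- sc + scheme$gap }
      else { j <- j + 1L; sc <- sc + scheme$gap }
    }
    if (sc > best) best <- sc
  }
  best
}

## Brute-force optimal DNA alignment score with affine gaps: a maximal
## gap run of length L costs gapOpening + L * gapExtension (terminal
## gaps penalised; runs in left and right sequences are separate gaps).
bruteDnaScore <- function(a, b, match = 5, mismatch = -4,
                          gapOpening = 10, gapExtension = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  for (path in enumeratePaths(length(av), length(bv))) {
    i <- 0L; j <- 0L; sc <- 0; prev <- ""
    for (mv in path) {
      if (mv == "D") {
        i <- i + 1L; j <- j + 1L
        sc <- sc + if (av[i] == bv[j]) match else mismatch
      } else {
        if (mv == "U") i <- i + 1L else j <- j + 1L
        sc <- sc - gapExtension - if (mv == prev) 0 else gapOpening
      }
      prev <- mv
    }
    if (sc > best) best <- sc
  }
  best
}

## Random DNA string of length n.
randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
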