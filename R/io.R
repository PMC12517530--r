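#' Read a DNA sequence from FASTA or plain text
#'
#' Files starting with `>` are parsed as single-record FASTA (wrapped
#' lines tolerated, via Biostrings); anything else is read as a plain-text
#' sequence string (whitespace and line breaks stripped). Lowercase bases
#' are uppercased with a warning. Multi-record FASTA is rejected.
#'
#' @param path input file.
#' @return A DNA character string over A/C/G/T.
#' @export
readDna <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonEmpty <- lines[nzchar(trimws(lines))]
  if (!length(nonEmpty)) stop("file contains no sequence: ", path)
  if (startsWith(trimws(nonEmpty[1]), ">")) {
    set <- Biostrings::readBStringSet(path)
    if (length(set) != 1L)
      stop(sprintf("unsupported input: %d FASTA records (exactly 1 expected)",
                   length(set)))
    seq <- as.character(set[[1]])
  } else {
    seq <- gsub("\\s", "", paste(nonEmpty, collapse = ""))
  }
  if (grepl("[acgt]", seq)) {
    warning("lowercase bases uppercased on read")
    seq <- toupper(seq)
  }
  checkDna(seq)
}

#' Write a DNA sequence to FASTA or plain text
#'
#' FASTA output is a single record wrapped at 60 columns.
#'
#' @param dna a DNA string.
#' @param path output file.
#' @param format `"fasta"` or `"text"`.
#' @param header FASTA record name (default `"sequence"`).
#' @return `path`, invisibly.
#' @export
writeDna <- function(dna, path, format = c("fasta", "text"),
                     header = "sequence") {
  dna <- checkDna(dna)
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::DNAStringSet(dna)
    names(set) <- header
    Biostrings::writeXStringSet(set, path, width = 60L)
  } else {
    writeLines(dna, path)
  }
  invisible(path)
}

#' Read and write scores as plain-text element lists
#'
#' One `midi_note beats` pair per line; `#`-prefixed lines are comments,
#' and `# tempo=` / `# volume=` comments carry the metadata.
#'
#' @param score a [MusicScore-class].
#' @param path file path.
#' @return `readScoreText()` a [MusicScore-class]; `writeScoreText()` the
#'   path, invisibly.
#' @export
writeScoreText <- function(score, path) {
  stopifnot(is(score, "MusicScore"))
  lines <- c(sprintf("# tempo=%g", score@tempo),
             sprintf("# volume=%g", score@volume),
             sprintf("%d %g", score@note, score@beats))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeScoreText
#' @export
readScoreText <- function(path) {
  lines <- readLines(path, warn = FALSE)
  tempo <- 100; volume <- -20
  m <- regmatches(lines, regexec("^#\\s*tempo=([0-9.eE+-]+)", lines))
  hit <- which(lengths(m) == 2L)
  if (length(hit)) tempo <- as.numeric(m[[hit[1]]][2])
  m <- regmatches(lines, regexec("^#\\s*volume=([0-9.eE+-]+)", lines))
  hit <- which(lengths(m) == 2L)
  if (length(hit)) volume <- as.numeric(m[[hit[1]]][2])
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(body))
    return(MusicScore(integer(), numeric(), tempo, volume))
  parts <- strsplit(trimws(body), "\\s+")
  if (any(lengths(parts) != 2L))
    stop("score text lines must be 'midi_note beats' pairs")
  MusicScore(as.integer(vapply(parts, `[`, "", 1L)),
             as.numeric(vapply(parts, `[`, "", 2L)),
             tempo, volume)
}

#' The packaged ancestor melody
#'
#' A 62-element monophonic rendering of the Ode to Joy theme (the melody
#' from the final movement of Beethoven's Symphony No. 9), reconstructed
#' from the standard tune and constrained to the default code's domain:
#' all elements lie in the 16-note/4-duration code, so no snapping is
#' needed, and the self-alignment score under the default music scoring
#' scheme is the maximum 310 (62 elements x 5). It is a synthetic
#' reconstruction, deterministic across calls; any other in-code MIDI
#' score can be substituted as ancestor throughout the package.
#'
#' @return A [MusicScore-class] with 62 elements, 100 bpm, -20 dBFS.
#' @examples
#' s <- odeToJoyFixture()
#' length(s)                          # 62
#' alignmentScore(alignMusic(s, s))   # 310
#' @export
odeToJoyFixture <- function() {
  E <- 64L; F <- 65L; G <- 67L; D <- 62L; C <- 60L
  phraseA <- c(E, E, F, G, G, F, E, D, C, C, D, E, E, D, D)
  phraseA2 <- c(E, E, F, G, G, F, E, D, C, C, D, E, D, C, C)
  bridge <- c(D, D, E, C, D, E, F, E, C, D, E, F, E, D, C, D)
  final <- c(D, E, E, F, G, G, F, E, D, C, C, D, E, D, C, C)
  notes <- c(phraseA, phraseA2, bridge, final)
  dursA <- c(rep(1/2, 13), 1/4, 1)
  dursBridge <- c(rep(1/2, 5), 1/4, 1/4, 1/2, 1/2, 1/2, 1/4, 1/4,
                  1/2, 1/2, 1/2, 1)
  dursFinal <- c(rep(1/2, 14), 1/4, 1)
  beats <- c(dursA, dursA, dursBridge, dursFinal)
  MusicScore(notes, beats, tempo = 100, volume = -20)
}
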