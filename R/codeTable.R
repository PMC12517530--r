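#' Build the default artificial genetic code
#'
#' Constructs the packaged 256-codon code deterministically. The 64
#' elements (16 notes x 4 durations, note-major then duration-minor) are
#' indexed 0..63; each index is base-4 encoded into codon positions 1-3
#' with digit map 0→A, 1→C, 2→G, 3→T, and position 4 (the wobble position)
#' takes all four bases. This construction guarantees that the four
#' synonymous codons of every element differ pairwise at exactly one
#' nucleotide, and that codons of different elements differ somewhere in
#' the first three positions.
#'
#' @param notes integer vector of 16 distinct MIDI note numbers making up
#'   the code's note subset. Default: the 16 C-major diatonic pitches from
#'   middle C (MIDI 60) upward.
#' @return A validated [CodeTable-class].
#' @examples
#' ct <- buildDefaultCodeTable()
#' length(codons(ct))          # 256
#' nrow(codeElements(ct))      # 64
#' synonyms(ct, 60, 1)         # 4 codons differing only at position 4
#' @export
buildDefaultCodeTable <- function(notes = DEFAULT_NOTE_SET) {
  notes <- as.integer(notes)
  if (length(notes) != 16L || anyDuplicated(notes) || anyNA(notes) ||
      any(notes < 0L | notes > 127L))
    stop("the note subset must be 16 distinct MIDI note numbers in 0..127")
  idx <- 0:63
  prefix <- paste0(DNA_BASES[idx %/% 16L + 1L],
                   DNA_BASES[(idx %/% 4L) %% 4L + 1L],
                   DNA_BASES[idx %% 4L + 1L])
  codon <- paste0(rep(prefix, each = 4L), DNA_BASES)
  note <- rep(notes[idx %/% 4L + 1L], each = 4L)
  beats <- rep(CODE_DURATIONS[idx %% 4L + 1L], each = 4L)
  new("CodeTable", codon = codon, note = note, beats = beats)
}

## 1-based element index (1..64) of each codon in `codons`; NA if absent.
codonElementIndex <- function(table, cods) {
  key <- paste(table@note, table@beats)
  ekey <- unique(key)
  match(key[match(cods, table@codon)], ekey)
}

#' Decode codons into musical elements
#'
#' Maps 4-letter codons back to their note/duration elements under a code
#' table. Vectorised over codons.
#'
#' @param table a [CodeTable-class].
#' @param codon character vector of 4-letter codons.
#' @return A data.frame with columns `note` (MIDI note number) and `beats`
#'   (duration in beats), one row per codon.
#' @examples
#' ct <- buildDefaultCodeTable()
#' decodeCodon(ct, c("AAAA", "AAAC"))  # synonymous pair: same element
#' @export
decodeCodon <- function(table, codon) {
  stopifnot(is(table, "CodeTable"))
  if (!is.character(codon) || !length(codon))
    stop("codon must be a non-empty character vector")
  codon <- toupper(codon)
  for (k in seq_along(codon)) {
    if (nchar(codon[k]) != 4L)
      stop(sprintf("codon %d has length %d (must be 4)",
                   k, nchar(codon[k])))
    chars <- strsplit(codon[k], "")[[1]]
    bad <- which(!(chars %in% DNA_BASES))
    if (length(bad))
      stop(sprintf(
        "codon %d: invalid base '%s' at position %d (alphabet is A/C/G/T)",
        k, chars[bad[1]], bad[1]))
  }
  i <- match(codon, table@codon)
  if (anyNA(i))
    stop(sprintf("codon '%s' is not in the code table",
                 codon[which(is.na(i))[1]]))
  data.frame(note = table@note[i], beats = table@beats[i])
}

#' Synonymous codons of an element
#'
#' Returns the ordered set of 4 codons encoding a note/duration element,
#' sorted alphabetically (for the default wobble construction this is the
#' wobble-base order A, C, G, T), giving reproducible indexing for seeded
#' random choice.
#'
#' @param table a [CodeTable-class].
#' @param note MIDI note number of the element.
#' @param beats duration of the element in beats.
#' @return Character vector of 4 codons.
#' @examples
#' ct <- buildDefaultCodeTable()
#' synonyms(ct, 60, 1/2)
#' @export
synonyms <- function(table, note, beats) {
  stopifnot(is(table, "CodeTable"), length(note) == 1L, length(beats) == 1L)
  hit <- table@note == as.integer(note) & table@beats == as.numeric(beats)
  if (!any(hit))
    stop(sprintf(
      "element (note %s, %s beats) is not in the code", note,
      format(beats)))
  sort(table@codon[hit])
}

#' Read and write code tables as TSV
#'
#' The on-disk format has a header line and four columns: `codon`,
#' `midi_note`, `duration_numerator`, `duration_denominator`, one row per
#' codon (256 rows). The round trip is lossless.
#'
#' @param table a [CodeTable-class].
#' @param path file path.
#' @return `readCodeTable()` returns a validated [CodeTable-class];
#'   `writeCodeTable()` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeCodeTable(buildDefaultCodeTable(), tf)
#' ct <- readCodeTable(tf)
#' @export
writeCodeTable <- function(table, path) {
  stopifnot(is(table, "CodeTable"))
  den <- as.integer(round(1 / table@beats))
  df <- data.frame(codon = table@codon,
                   midi_note = table@note,
                   duration_numerator = 1L,
                   duration_denominator = den)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCodeTable
#' @export
readCodeTable <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("codon", "midi_note", "duration_numerator",
            "duration_denominator")
  if (!all(need %in% names(df)))
    stop("code-table TSV must have columns: ", paste(need, collapse = ", "))
  new("CodeTable",
      codon = toupper(as.character(df$codon)),
      note = as.integer(df$midi_note),
      beats = as.numeric(df$duration_numerator) /
        as.numeric(df$duration_denominator))
}

#' Validate a code table file
#'
#' Reads a code-table TSV and checks every structural invariant (256
#' unique codons, 64 elements with 4 synonyms each, 16 notes, 4 durations,
#' within-element Hamming distance 1).
#'
#' @param path path to a code-table TSV.
#' @return `TRUE` invisibly on success; stops with a diagnostic otherwise.
#' @export
validateCodeTableFile <- function(path) {
  ct <- readCodeTable(path)  # construction runs the validity method
  validObject(ct)
  invisible(TRUE)
}
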