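## Evaluate `code` under a temporary seed, restoring the caller's RNG
## state afterwards. seed = NULL means: use the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)  # materialise .Random.seed
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

## Draw k independent sub-seeds from the current stream (31-bit range).
spawnSeeds <- function(k) sample.int(.Machine$integer.max - 1L, k)

## Validate and canonicalise a DNA string. Accepts character scalars and
## Biostrings XString objects; returns an uppercase character scalar.
## Positions in error messages are 1-based.
checkDna <- function(dna, requireFrame = FALSE, what = "DNA sequence") {
  if (is(dna, "XString") || is(dna, "XStringSet"))
    dna <- as.character(dna)
  if (!is.character(dna) || length(dna) != 1L || is.na(dna))
    stop(what, " must be a single character string")
  dna <- toupper(dna)
  chars <- strsplit(dna, "")[[1]]
  bad <- which(!(chars %in% DNA_BASES))
  if (length(bad))
    stop(sprintf("invalid base '%s' at position %d (alphabet is A/C/G/T)",
                 chars[bad[1]], bad[1]))
  if (requireFrame && nchar(dna) %% 4L != 0L)
    stop(sprintf(
      "sequence length %d is not a multiple of 4 (frame error; %d trailing bases)",
      nchar(dna), nchar(dna) %% 4L))
  dna
}

## Split a framed DNA string into its codons.
splitCodons <- function(dna) {
  n <- nchar(dna)
  if (n == 0L) return(character())
  substring(dna, seq(1L, n, by = 4L), seq(4L, n, by = 4L))
}
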