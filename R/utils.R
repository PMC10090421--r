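# Run code under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Split a sequence string into single residues.
splitResidues <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Validate one uppercased sequence against the 20-letter alphabet.
# Returns the offending characters (empty when valid).
invalidResidues <- function(seq) {
  setdiff(unique(splitResidues(seq)), aminoAcids())
}
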