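# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never perturb the
# user's random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a secondary seed from a master seed; keeps results < 2^31 so the
# value is a valid R integer seed.
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 69069 + 12345 * as.numeric(salt)) %% 2147483647)
}

# Species names are matched after case-folding and whitespace collapsing.
normalize_species <- function(x) {
  tolower(gsub("\\s+", " ", trimws(as.character(x))))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

reverse_complement <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
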