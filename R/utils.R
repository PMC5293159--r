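# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(code)
}

# Canonical lexicographic ordering of a protein pair, vectorised.
canonical_pair <- function(a, b) {
  swap <- a > b
  tibble(
    protein_a = ifelse(swap, b, a),
    protein_b = ifelse(swap, a, b)
  )
}

# Derive a reproducible child seed from a base seed, kept inside 32-bit range.
child_seed <- function(seed, offset) {
  if (is.null(seed)) {
    return(NULL)
  }
  (as.integer(seed) + as.integer(offset) * 7919L) %% 2147483587L
}

stop_cofrac <- function(message, class) {
  abort(message, class = c(class, "cofrac_error"))
}
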