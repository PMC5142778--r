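# Run expr with a local RNG state seeded at `seed`, restoring the caller's
# stream afterwards. All package randomness flows through explicit seeds.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# sample() without the length-1 surprise: sample exactly from the given pool
samplePool <- function(pool, size) {
  pool[sample.int(length(pool), size)]
}

standardError <- function(x) stats::sd(x) / sqrt(length(x))

asCountInput <- function(counts) {
  if (is(counts, "CountMatrix")) spikeCounts(counts)
  else if (is.matrix(counts)) counts
  else stop("expected a CountMatrix or a trials x neurons matrix")
}
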