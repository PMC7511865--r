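# Internal helpers.

# Run fn() under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package randomness never perturbs user code.
withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Deterministic per-stream seed derivation from a master seed; stays within
# 32-bit integer range. Stream i is independent of how many streams exist.
deriveSeed <- function(master, index) {
  as.integer((as.double(master) + 1000003 * as.double(index)) %% 2147483647)
}

# md5 of a character scalar (config hashing); tools::md5sum works on files.
md5string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f, sep = "")
  unname(tools::md5sum(f))
}

# Locale-independent ordering used everywhere report rows are sorted.
radixOrder <- function(...) order(..., method = "radix")
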