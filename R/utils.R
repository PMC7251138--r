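# Internal helpers shared across modules.

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

## Derive n reproducible child seeds from a master seed (kept < 2^31).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## sample() a vector safely: a length-1 x must be returned as-is, not
## interpreted as sample.int(x).
resample <- function(x) {
  if (length(x) <= 1L) x else sample(x)
}

trimws2 <- function(x) trimws(x, which = "both")
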