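# Deterministic seed derivation: a master seed plus a label yields an
# independent child seed, so per-sample / per-stage random streams do not
# shift when other samples or stages are added or toggled.

# polynomial string hash mod a Mersenne prime; stays inside 32-bit integers
hash_label <- function(label) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  h
}

# all intermediate products stay below 2^53, so doubles carry them exactly
derive_seed <- function(master, label) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 48271 + hash_label(label)) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
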