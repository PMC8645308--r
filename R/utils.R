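# shared helpers

# evaluate code under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derive a per-item seed from a master seed and a counter, kept below 2^31
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) * 7919 + as.numeric(counter) * 104729) %%
               2147483647)
}
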