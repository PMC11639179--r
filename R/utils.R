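# RNG bookkeeping shared by the simulation and cross-validation code: seeded
# calls are deterministic and leave the caller's RNG stream untouched.

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}

# counter-based derived seeds (kept below 2^31 - 1) so repetitions are
# reproducible and paired across experimental arms sharing the same counter
.derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) + as.double(counter) * 1000003) %% 2147483646 + 1)
}
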