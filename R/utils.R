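# internal helpers

# let data.table's non-standard evaluation work when called via ::
.datatable.aware <- TRUE

# Evaluate expr under a fixed, platform-stable RNG state, restoring the
# caller's state afterwards. All synthetic-data generators go through this so
# a fixed seed means bit-identical output.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Deterministic child seed derivation; stays within 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset * 9973) %% 2147483629)
}
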