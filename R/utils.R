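# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Deterministic per-SNP stream seed derived from a master seed and the SNP
# identifier, so simulation-based diagnostics are invariant to row order.
snp_stream_seed <- function(master_seed, snp_id) {
  codes <- utf8ToInt(snp_id)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((as.numeric(master_seed) %% 2147483647 * 69069 + h * 1013) %% 2147483629) + 1L
}
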