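# Deterministic sub-seed for a named stage, derived from the run seed.
# Keeps every stage reproducible from a single config seed without
# sharing one RNG stream across stages; result fits a 32-bit integer.
derive_seed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 1048573
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + h * 8191) %% 2147483647)
}
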