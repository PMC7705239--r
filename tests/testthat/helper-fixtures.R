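# Shared fixtures, all built in code at test time.

# A small raw segment table with known per-set counts: n_rec records per
# set, record_length samples each, segmented into 23 chunks.
tiny_corpus <- function(n_rec = 2, sets = c("A", "B", "E"), seed = 7,
                        separability = 1, record_length = 4097) {
  spec <- synthetic_spec(n_records_per_set = n_rec,
                         record_length = record_length, seed = seed,
                         separability = separability)
  segment_records(generate_bonn_like(spec, sets = sets))
}

# Write a Bonn-style ASCII record file from a numeric vector.
write_ascii_record <- function(values, path = tempfile(fileext = ".txt")) {
  writeLines(sprintf("%.17g", values), path)
  path
}

# Deterministic small parameter set for layer oracles.
fixed_nonlocal_params <- function(c_in, c_hat, seed = 123) {
  set.seed(seed)
  init_nonlocal(c_in, c_hat)
}
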