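# Shared test fixtures, all generated in code under fixed seeds.

AA20 <- pmpred:::AA

random_sequence <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

random_records <- function(n, len_range = c(35L, 120L), prefix = "s") {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  protein_records(sprintf("%s%03d", prefix, seq_len(n)),
                  vapply(lens, random_sequence, character(1)))
}

# Deterministic, strongly separable fixture used by several model tests.
spiked_set <- function(n_pos = 25, n_neg = 25, effect = 8, seed = 3,
                       len = c(35, 80)) {
  generate_proteins(synthetic_config(n_pos = n_pos, n_neg = n_neg,
                                     length_range = len, effect = effect,
                                     mode = "motif-spike", seed = seed))
}
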