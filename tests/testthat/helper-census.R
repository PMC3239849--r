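# Small synthetic censuses used across tests
small_census <- function(n = 50, seed = 1, ...) {
  generate_census(generator_config(n_das = n, seed = seed, ...))
}

filtered_census <- function(n = 50, seed = 1, ...) {
  filter_das(small_census(n = n, seed = seed, ...))$retained
}

# Minimal single-indicator table for hand-built fixtures (divorce only,
# but carrying the labour columns the eligibility logic looks at)
tiny_table <- function(num_f, den_f, num_m, den_m) {
  n <- length(num_f)
  tibble::tibble(
    da_id = sprintf("DA%03d", seq_len(n)),
    area_type = "rural",
    pop_f = as.integer(den_f * 2), pop_m = as.integer(den_m * 2),
    divorce_num_f = as.integer(num_f), divorce_num_m = as.integer(num_m),
    divorce_den_f = as.integer(den_f), divorce_den_m = as.integer(den_m),
    labour_force_num_f = 1L, labour_force_num_m = 1L,
    labour_force_den_f = as.integer(pmax(den_f, 1)),
    labour_force_den_m = as.integer(pmax(den_m, 1))
  )
}
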