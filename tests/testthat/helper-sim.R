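# Shared fixtures: all test data are generated in code.

# draw n HWE genotype rows at the given A-allele frequencies
hwe_genotypes <- function(n, freq_a) {
  vapply(1 - freq_a, function(qb) stats::rbinom(n, 2, qb),
         numeric(n)) |> matrix(nrow = n)
}

# Mendelian offspring of row-matched parent genotype matrices
mendel_offspring <- function(GM, GF) {
  matrix(stats::rbinom(length(GM), 1, GM / 2) +
           stats::rbinom(length(GF), 1, GF / 2), nrow(GM))
}

# minimal genotype_table built by hand
make_gt <- function(calls, individual_id, panel) {
  rownames(calls) <- sprintf("s%03d", seq_len(nrow(calls)))
  out <- list(calls = calls,
              samples = data.frame(sample_id = rownames(calls),
                                   individual_id = individual_id,
                                   stringsAsFactors = FALSE),
              panel = panel)
  class(out) <- "genotype_table"
  out
}

# a small all-autosomal panel at the given A frequencies
auto_panel <- function(freq_a) {
  make_marker_panel(auto_freq_a = freq_a)
}

small_sim_config <- function(seed, ...) {
  sim_config(n_founders_f = 12, n_founders_m = 10, n_generations = 2,
             mean_offspring_per_mother = 2, prop_sampled = 1, seed = seed,
             ...)
}
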