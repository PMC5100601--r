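# shared test fixtures, all generated in code

# a rate table with one flat rate per codon, bypassing any tRNA table
flat_rates <- function(codons, k = 10, gamma = 35, beta = gamma) {
  u <- unique(codons)
  structure(list(k = stats::setNames(rep(k, length(u)), u),
                 gamma = gamma, beta = beta, scaling = k),
            class = "rate_table")
}

# rate table with explicit per-codon rates
named_rates <- function(k, gamma = 35, beta = gamma) {
  structure(list(k = k, gamma = gamma, beta = beta, scaling = NA_real_),
            class = "rate_table")
}

# quick simulation config for unit tests (coarse but fast)
fast_config <- function(target = 400, collect_density = FALSE, ...) {
  sim_config(target_terminations = target, collect_density = collect_density, ...)
}

# background codons decoded by the default complement's abundant species
bg_codons <- function() c("GAA", "GAT", "GCT", "GCC", "CAA", "AAA", "AAG", "GGT")

# hand-built single-ORF table: ATG + body
manual_cds <- function(body, orf_id = "orf1") {
  cds_table(orf_id, list(c("ATG", body)))
}
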