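# The reference mapping design used by the parameter-recovery experiments:
# one 20 Mb chromosome, causal recessive locus at 11.2 Mb, 200 F2 plants,
# bulks of 33 + 33, fixed 80x depth per pool, a marker every 10 kb.
mapping_config <- function(seed, causal = TRUE) {
  f2_sim_config(
    chrom_lengths = c(chr4 = 20e6),
    marker_spacing = 10e3,
    causal_chrom = if (causal) "chr4" else NA,
    causal_pos = 11.2e6,
    n_individuals = 200,
    bulk_size = 33,
    depth = 80,
    depth_model = "fixed",
    seed = seed
  )
}

# One seeded replicate of the full pipeline. If a phenotype class happens to
# fall below the bulk size (probability ~0.0014 per replicate at n = 200),
# the population is redrawn from the next derived seed.
run_mapping_replicate <- function(seed, thresholds, causal = TRUE) {
  s <- as.integer(seed)
  repeat {
    cfg <- mapping_config(s, causal = causal)
    pop <- simulate_f2(cfg)
    if (min(table(factor(pop$phenotype,
                         levels = c("mutant", "wildtype")))) >= 33) break
    s <- (s + 1000003L) %% .Machine$integer.max
  }
  rec <- simulate_bulk_seq(cfg)
  bsa_scan(rec, bulk_size = 33, chrom_lengths = cfg$chrom_lengths,
           thresholds = thresholds, quiet = TRUE)
}

# Shared fixed-depth thresholds for the mapping design (depth 80, bulks 33).
mapping_thresholds <- function(n_reps = 10000, seed = 2024) {
  null_thresholds(80, bulk_size = 33, n_reps = n_reps, seed = seed)
}
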