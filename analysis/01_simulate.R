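# Generate the synthetic study: structured genotypes, gene catalog,
# zero-inflated polygenic expression with known per-condition heritability,
# and compartment/pericentromere tracks. Writes standard-format files that
# the later stages read back, exactly as they would read deposited data.

source("analysis/00_config.R")

sim <- simulate_dataset(SIM_SPEC)
write_dataset(sim, DATA_DIR)

cat("genotypes:", nrow(sim$geno$dosages), "x", ncol(sim$geno$dosages),
    "markers\n")
cat("genes:", nrow(sim$catalog), "on",
    length(unique(sim$catalog$chrom)), "chromosomes\n")
print(sim$expr)
cat("planted hotspot genes:", sum(sim$truth$hotspot), "\n")
cat("truth class mix (control):\n")
print(table(sim$truth$class_control))
cat("wrote", DATA_DIR, "\n")
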